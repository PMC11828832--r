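#' Language marker tables for WhatsApp exports
#'
#' WhatsApp renders "media omitted" placeholders and system lines (subject
#' changes, end-to-end-encryption notices) in the language of the exporting
#' device.  Both are table-driven so that adding a locale is a configuration
#' change, not a code change.  The five languages covered are the ones the
#' donation platform itself ships in: English, German, Ukrainian, Armenian
#' and Russian.
#'
#' @format A named list, one entry per ISO 639-1 language code, each with
#'   elements `media_markers` (character vector of literal placeholder
#'   strings) and `system_patterns` (character vector of regular expressions
#'   matched against the text of a header line that carries no "Sender: "
#'   prefix).
#' @keywords internal
whatsapp_language_table <- function() {
  list(
    en = list(
      media_markers = c("<Media omitted>", "<media omitted>"),
      system_patterns = c(
        "end-to-end encrypted",
        "created group",
        "changed the subject",
        "added you",
        "You joined",
        "security code changed"
      )
    ),
    de = list(
      media_markers = c("<Medien ausgeschlossen>"),
      system_patterns = c(
        "Ende-zu-Ende-verschl",
        "Gruppe erstellt",
        "Betreff geändert",
        "hinzugefügt",
        "Sicherheitsnummer"
      )
    ),
    uk = list(
      media_markers = c("<Медіа пропущено>"),
      system_patterns = c(
        "наскрізним шифруванням",
        "створив групу",
        "змінив тему"
      )
    ),
    hy = list(
      media_markers = c("<Մեդիան բաց է թողնված>"),
      system_patterns = c(
        "ծայրից ծայր գաղտնագրված",
        "ստեղծեց խումբ"
      )
    ),
    ru = list(
      media_markers = c("<Без медиафайлов>", "<Медиа опущено>"),
      system_patterns = c(
        "сквозным шифрованием",
        "создал группу",
        "изменил тему"
      )
    )
  )
}

#' All media markers / system patterns across supported languages
#' @keywords internal
#' @noRd
all_media_markers <- function() {
  unique(unlist(lapply(whatsapp_language_table(), `[[`, "media_markers"),
                use.names = FALSE))
}

#' @noRd
all_system_patterns <- function() {
  unique(unlist(lapply(whatsapp_language_table(), `[[`, "system_patterns"),
                use.names = FALSE))
}
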