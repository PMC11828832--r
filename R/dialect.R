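#' WhatsApp export dialects
#'
#' WhatsApp writes its per-chat `.txt` export in a locale- and
#' device-dependent line grammar.  The two big families are the
#' "plain-dash" form
#'
#' ```
#' 15.03.22, 14:32 - Alice: hello
#' ```
#'
#' and the "bracketed" form
#'
#' ```
#' [3/15/22, 2:32:10 PM] Alice: hello
#' ```
#'
#' crossed with day-month-year vs month-day-year ordering, 12- vs 24-hour
#' clocks, optional seconds, and 2- vs 4-digit years.  A
#' `whatsapp_dialect` object pins down one cell of that grid together with
#' the language-specific media markers and system-line patterns.
#'
#' @param bracket_style `"plain-dash"` or `"bracketed"`.
#' @param date_order `"dmy"` or `"mdy"`.
#' @param hour12 logical; `TRUE` for a 12-hour clock with AM/PM marker.
#' @param seconds logical; `TRUE` if the timestamp carries seconds.
#' @param year_digits 2 or 4.
#' @param date_sep separator between date components (`"."`, `"/"` or `"-"`).
#' @param language ISO 639-1 code of the marker language; one of
#'   `"en"`, `"de"`, `"uk"`, `"hy"`, `"ru"`.
#' @return An object of class `whatsapp_dialect`.
#' @export
whatsapp_dialect <- function(bracket_style = c("plain-dash", "bracketed"),
                             date_order = c("dmy", "mdy"),
                             hour12 = FALSE,
                             seconds = FALSE,
                             year_digits = 2L,
                             date_sep = NULL,
                             language = "en") {
  bracket_style <- match.arg(bracket_style)
  date_order <- match.arg(date_order)
  stopifnot(year_digits %in% c(2L, 4L))
  if (is.null(date_sep)) date_sep <- if (date_order == "dmy") "." else "/"
  lt <- whatsapp_language_table()
  if (!language %in% names(lt)) {
    cm_error(sprintf("unsupported marker language '%s'", language),
             "chatmetrics_bad_language")
  }
  structure(
    list(
      bracket_style = bracket_style,
      date_order = date_order,
      hour12 = isTRUE(hour12),
      seconds = isTRUE(seconds),
      year_digits = as.integer(year_digits),
      date_sep = date_sep,
      header_separator = if (bracket_style == "plain-dash") " - " else "] ",
      language = language,
      media_markers = all_media_markers(),
      system_patterns = all_system_patterns()
    ),
    class = "whatsapp_dialect"
  )
}

#' @export
print.whatsapp_dialect <- function(x, ...) {
  cat(sprintf(
    "<whatsapp_dialect %s %s %s%s sep='%s' %dy lang=%s>\n",
    x$bracket_style, toupper(x$date_order),
    if (x$hour12) "12h" else "24h",
    if (x$seconds) "+sec" else "", x$date_sep, x$year_digits, x$language))
  invisible(x)
}

# The candidate grid scanned by dialect detection.  Order matters: ties in
# header-match counts are broken by position, so DMY precedes MDY and 24h
# precedes 12h (the most common combinations in the study's locales).
candidate_dialects <- function() {
  grid <- expand.grid(
    hour12 = c(FALSE, TRUE),
    date_order = c("dmy", "mdy"),
    seconds = c(FALSE, TRUE),
    bracket_style = c("plain-dash", "bracketed"),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$bracket_style == "bracketed", grid$date_order == "mdy",
                     grid$hour12, grid$seconds), ]
  lapply(seq_len(nrow(grid)), function(i) {
    whatsapp_dialect(grid$bracket_style[i], grid$date_order[i],
                     hour12 = grid$hour12[i], seconds = grid$seconds[i])
  })
}

# Regex for one header line under a dialect.  Capture groups, in order:
# day1, sep, day2, year, hour, minute, [second], [am/pm letter], rest.
# Year and separator are matched flexibly; the dialect records the variant
# actually seen so the renderer can reproduce it.
header_regex <- function(d) {
  date <- "(\\d{1,2})([./-])(\\d{1,2})\\2(\\d{2}|\\d{4})"
  time <- "(\\d{1,2}):(\\d{2})"
  sec <- if (d$seconds) ":(\\d{2})" else ""
  # WhatsApp uses plain space, NBSP or narrow NBSP before the AM/PM marker
  ampm <- if (d$hour12) {
    sprintf("[ %s%s]?([APap])\\.?[Mm]\\.?", intToUtf8(0xA0L), intToUtf8(0x202FL))
  } else ""
  if (d$bracket_style == "plain-dash") {
    paste0("^", date, ",? ", time, sec, ampm, " - (.*)$")
  } else {
    paste0("^\\[", date, ",? ", time, sec, ampm, "\\] (.*)$")
  }
}

# Try to read `line` as a message header under dialect `d`.
# Returns NULL if the line is not a header; otherwise a list with the
# parsed local timestamp (POSIXct, tz UTC used as "naive local"),
# the remainder of the line, and the observed year width / separator.
# A header that matches structurally but has an impossible date yields
# timestamp = NA (caller decides whether to warn and skip).
match_header <- function(line, d) {
  m <- regexec(header_regex(d), line, perl = TRUE)
  g <- regmatches(line, m)[[1]]
  if (length(g) == 0) return(NULL)
  i <- 2L
  d1 <- as.integer(g[i]); sep <- g[i + 1L]
  d2 <- as.integer(g[i + 2L]); yr_s <- g[i + 3L]
  hh <- as.integer(g[i + 4L]); mm <- as.integer(g[i + 5L])
  i <- i + 6L
  ss <- 0L
  if (d$seconds) { ss <- as.integer(g[i]); i <- i + 1L }
  if (d$hour12) {
    ap <- toupper(g[i]); i <- i + 1L
    if (hh < 1L || hh > 12L) return(list(timestamp = as.POSIXct(NA), rest = NULL))
    if (ap == "A") { if (hh == 12L) hh <- 0L } else if (hh != 12L) hh <- hh + 12L
  }
  rest <- g[i]
  if (d$date_order == "dmy") { day <- d1; mon <- d2 } else { day <- d2; mon <- d1 }
  yr <- as.integer(yr_s)
  if (nchar(yr_s) == 2L) yr <- if (yr >= 70L) 1900L + yr else 2000L + yr
  bad <- mon < 1L || mon > 12L || day < 1L || day > 31L ||
    hh > 23L || mm > 59L || ss > 59L
  ts <- if (bad) as.POSIXct(NA) else
    ISOdatetime(yr, mon, day, hh, mm, ss, tz = "UTC")
  list(timestamp = ts, rest = rest,
       year_digits = nchar(yr_s), date_sep = sep)
}

#' Detect the dialect of a WhatsApp export
#'
#' Scans the candidate dialect grid and returns the dialect under which the
#' largest number of lines parse as message headers (with a valid calendar
#' date).  Ties are broken by preferring plain-dash over bracketed, DMY over
#' MDY, and a 24-hour over a 12-hour clock.  The year width and date
#' separator actually observed are copied into the returned dialect, and the
#' marker language is inferred from any media marker or system pattern seen
#' in the text.
#'
#' @param lines Character vector of export lines.
#' @return A [whatsapp_dialect()] object.
#' @examples
#' detect_whatsapp_dialect("15.03.22, 14:32 - Alice: hi")
#' @export
detect_whatsapp_dialect <- function(lines) {
  cands <- candidate_dialects()
  best <- NULL; best_n <- 0L; best_hit <- NULL
  for (d in cands) {
    rx <- header_regex(d)
    hits <- grepl(rx, lines, perl = TRUE)
    n <- 0L; first_hit <- NULL
    for (ln in lines[hits]) {
      h <- match_header(ln, d)
      if (!is.null(h) && !is.na(h$timestamp)) {
        n <- n + 1L
        if (is.null(first_hit)) first_hit <- h
      }
    }
    if (n > best_n) { best <- d; best_n <- n; best_hit <- first_hit }
  }
  if (is.null(best)) {
    cm_error("no line matches any known WhatsApp header grammar",
             "chatmetrics_no_dialect")
  }
  best$year_digits <- as.integer(best_hit$year_digits)
  best$date_sep <- best_hit$date_sep
  best$language <- infer_marker_language(lines)
  best
}

# Pick the marker language by looking for any known media marker or system
# pattern; defaults to English when nothing matches.
infer_marker_language <- function(lines) {
  lt <- whatsapp_language_table()
  txt <- paste(lines, collapse = "\n")
  for (lang in names(lt)) {
    pats <- c(vapply(lt[[lang]]$media_markers, function(m)
      grepl(m, txt, fixed = TRUE), logical(1)),
      vapply(lt[[lang]]$system_patterns, function(p)
        grepl(p, txt), logical(1)))
    if (any(pats)) return(lang)
  }
  "en"
}

# Render a timestamp header prefix in dialect `d` (inverse of match_header).
format_whatsapp_timestamp <- function(ts, d) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  day <- lt$mday; mon <- lt$mon + 1L; yr <- lt$year + 1900L
  yr_s <- if (d$year_digits == 2L) sprintf("%02d", yr %% 100L) else
    sprintf("%04d", yr)
  dpart <- if (d$date_order == "dmy")
    paste(sprintf("%02d", day), sprintf("%02d", mon), yr_s, sep = d$date_sep)
  else
    paste(sprintf("%d", mon), sprintf("%d", day), yr_s, sep = d$date_sep)
  hh <- lt$hour
  ap <- ""
  if (d$hour12) {
    ap <- if (hh < 12L) " AM" else " PM"
    hh <- hh %% 12L
    if (hh == 0L) hh <- 12L
  }
  tpart <- paste0(sprintf(if (d$hour12) "%d" else "%02d", hh), ":",
                  sprintf("%02d", lt$min),
                  if (d$seconds) sprintf(":%02d", lt$sec) else "", ap)
  paste0(dpart, ", ", tpart)
}
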