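#' Count whitespace-delimited words
#'
#' The only content-derived quantity retained by the minimizer.  Tokens are
#' maximal runs of non-whitespace characters, counted after mojibake repair
#' so that non-ASCII text is tokenized on real word boundaries.
#'
#' @param content Character vector.
#' @return Integer vector of token counts; empty or `NA` strings count 0.
#' @examples
#' count_words(c("hello world", "", "a  b\tc\nd"))  # 2 0 4
#' @export
count_words <- function(content) {
  content <- repair_text_encoding(content)
  vapply(content, function(x) {
    if (is.na(x) || !nzchar(x)) return(0L)
    m <- gregexpr("\\S+", x, perl = TRUE)[[1]]
    if (m[1] < 0) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Pseudonym map
#'
#' Maps every display name appearing in a donation to an opaque random hex
#' ID.  All donor aliases share one ID (the donor is the only party linkable
#' across the chats of a donation); every other name gets its own ID.  IDs
#' are fixed-width hex tokens from a seeded generator, so they are
#' reproducible, order-independent, and share no substring with any source
#' name.
#'
#' @param donor A [donor_profile()].
#' @param convs List of [raw_conversation()].
#' @param seed Integer seed for ID generation.
#' @return Object of class `pseudonym_map`: list with `map` (named character
#'   vector, names = display names) and `donor_id`.
#' @export
build_pseudonym_map <- function(donor, convs, seed = 1L) {
  stopifnot(inherits(donor, "donor_profile"))
  names_all <- unique(c(
    donor$display_names,
    unlist(lapply(convs, function(cv) cv$participants), use.names = FALSE)
  ))
  names_all <- sort(names_all[nzchar(names_all)])
  if (!any(donor$display_names %in% names_all) ||
      !any(vapply(convs, function(cv)
        any(donor$display_names %in% cv$participants), logical(1)))) {
    cm_warn("donor display name not found in any conversation",
            "chatmetrics_donor_absent")
  }
  non_donor <- setdiff(names_all, donor$display_names)
  n_ids <- length(non_donor) + 1L
  ids <- with_seed(seed, draw_hex_ids(n_ids, names_all))
  map <- character(0)
  donor_id <- ids[1]
  map[donor$display_names] <- donor_id
  if (length(non_donor)) map[non_donor] <- ids[-1]
  structure(list(map = map, donor_id = donor_id), class = "pseudonym_map")
}

# 12-hex-digit IDs, re-drawn until they are pairwise distinct and no source
# name occurs in any ID (vanishingly rare, but the contract is absolute).
draw_hex_ids <- function(n, forbidden_names) {
  repeat {
    ids <- vapply(seq_len(n), function(i)
      paste(sample(c(0:9, letters[1:6]), 12, replace = TRUE), collapse = ""),
      character(1))
    clash <- anyDuplicated(ids) > 0 ||
      any(vapply(tolower(forbidden_names), function(nm)
        any(grepl(nm, ids, fixed = TRUE)), logical(1)))
    if (!clash) return(ids)
  }
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Minimize a raw conversation
#'
#' The de-identification step: every message is reduced to (pseudonymous
#' sender ID, timestamp, word count, optional voice duration).  Content and
#' display names are dropped.  System messages are dropped entirely (they
#' are not interactions); media and voice messages are kept with word count
#' 0 and flagged, because they carry timing information used by burstiness
#' and active-hours analyses while contributing nothing to word-based
#' metrics.
#'
#' @param conv A [raw_conversation()].
#' @param pmap A [build_pseudonym_map()] result covering all senders.
#' @param conversation_id Opaque ID; a deterministic position-independent
#'   default is derived from the pseudonym of the first participant plus a
#'   running index by the caller.
#' @return Object of class `minimized_conversation`.
#' @export
minimize_conversation <- function(conv, pmap, conversation_id) {
  stopifnot(inherits(conv, "raw_conversation"),
            inherits(pmap, "pseudonym_map"))
  m <- conv$messages[conv$messages$kind != "system", , drop = FALSE]
  unmapped <- setdiff(unique(m$sender_name), names(pmap$map))
  if (length(unmapped) > 0) {
    cm_error(sprintf("%d sender(s) lack a pseudonym", length(unmapped)),
             "chatmetrics_unmapped_sender")
  }
  wc <- integer(nrow(m))
  txt <- m$kind == "text"
  wc[txt] <- count_words(m$content[txt])
  out <- data.frame(
    sender_id = unname(pmap$map[m$sender_name]),
    timestamp = m$timestamp,
    word_count = wc,
    voice_duration_s = m$voice_duration_s,
    is_media = m$kind %in% c("media", "voice"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(conversation_id = conversation_id,
         platform = conv$platform,
         is_group = conv$is_group,
         participant_ids = sort(unique(unname(pmap$map[conv$participants]))),
         messages = out),
    class = "minimized_conversation"
  )
}

#' Assemble a donation
#'
#' Builds the complete de-identified donation from raw conversations: one
#' pseudonym map per donation (donor linkable across chats, partners not),
#' one minimized conversation per raw conversation.  Conversation IDs are
#' random hex tokens from the same seeded stream.
#'
#' @param donor A [donor_profile()].
#' @param convs List of [raw_conversation()].
#' @param platform Donation platform; defaults to the first conversation's.
#' @param external_donor_id Optional opaque researcher-issued token.
#' @param seed Integer seed for pseudonym/ID generation.
#' @param donation_timestamp Time of donation (default: now).
#' @return Object of class `donation`.
#' @export
build_donation <- function(donor, convs, platform = NULL,
                           external_donor_id = NULL, seed = 1L,
                           donation_timestamp = Sys.time()) {
  stopifnot(length(convs) >= 1)
  if (is.null(platform)) platform <- convs[[1]]$platform
  pmap <- build_pseudonym_map(donor, convs, seed = seed)
  conv_ids <- with_seed(seed + 1L, draw_hex_ids(length(convs), names(pmap$map)))
  conversations <- lapply(seq_along(convs), function(i)
    minimize_conversation(convs[[i]], pmap, conv_ids[i]))
  structure(
    list(donor_id = pmap$donor_id,
         external_donor_id = external_donor_id,
         platform = platform,
         donation_timestamp = donation_timestamp,
         conversations = conversations),
    class = "donation"
  )
}

#' @export
print.donation <- function(x, ...) {
  cat(sprintf("<donation %s: %d conversation(s), %d message(s)>\n",
              x$platform, length(x$conversations),
              sum(vapply(x$conversations, function(cv) nrow(cv$messages),
                         integer(1)))))
  invisible(x)
}

#' Restrict a donation to a date range
#'
#' WhatsApp has no built-in export range limit, so the pipeline offers one:
#' only messages whose calendar date falls in `[start, end]` are kept, and
#' conversations left empty are removed.
#'
#' @param d A [build_donation()] result.
#' @param start,end `Date` (or coercible); inclusive bounds.
#' @return A `donation` with filtered messages.
#' @export
restrict_period <- function(d, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) {
    cm_error("start date after end date", "chatmetrics_invalid_range")
  }
  keep <- lapply(d$conversations, function(cv) {
    dt <- as.Date(cv$messages$timestamp, tz = "UTC")
    cv$messages <- cv$messages[dt >= start & dt <= end, , drop = FALSE]
    rownames(cv$messages) <- NULL
    cv
  })
  d$conversations <- Filter(function(cv) nrow(cv$messages) > 0, keep)
  d
}

#' Audit a donation for content leakage
#'
#' Machine-checkable form of the minimization contract: serializes every
#' field of the donation and reports any field whose value contains a
#' sentinel string (a name or content token planted by the fixture
#' generator) as a substring.  An empty report is a pass.
#'
#' @param d A `donation`.
#' @param sentinel_vocabulary Character vector of planted names/tokens.
#' @return Data frame with columns `field` and `sentinel`; zero rows = pass.
#' @export
audit_no_leakage <- function(d, sentinel_vocabulary) {
  fields <- donation_field_values(d)
  hits <- list()
  for (sv in unique(sentinel_vocabulary)) {
    if (!nzchar(sv)) next
    hit <- vapply(fields, function(v) grepl(sv, v, fixed = TRUE), logical(1))
    if (any(hit)) {
      hits[[length(hits) + 1L]] <- data.frame(
        field = names(fields)[hit], sentinel = sv, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    data.frame(field = character(0), sentinel = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, hits)
  }
}

# Flatten every serialized field of a donation to named character values.
donation_field_values <- function(d) {
  out <- c(donor_id = d$donor_id,
           external_donor_id = d$external_donor_id %||% "",
           platform = d$platform,
           donation_timestamp = format(d$donation_timestamp))
  for (i in seq_along(d$conversations)) {
    cv <- d$conversations[[i]]
    pre <- sprintf("conversations[%d].", i)
    out[paste0(pre, "conversation_id")] <- cv$conversation_id
    out[paste0(pre, "platform")] <- cv$platform
    out[paste0(pre, "is_group")] <- as.character(cv$is_group)
    out[paste0(pre, "participant_ids")] <-
      paste(cv$participant_ids, collapse = ",")
    m <- cv$messages
    for (col in names(m)) {
      out[paste0(pre, "messages.", col)] <-
        paste(format(m[[col]]), collapse = ",")
    }
  }
  out
}

#' Write / read a donation as JSON
#'
#' One self-contained JSON document: donor, conversations, messages.
#' Timestamps are written as ISO-8601 strings at second resolution, in the
#' naive local clock of the export.  The JSON round trip is lossless at the
#' metadata level.
#'
#' @param d A `donation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_donation_json <- function(d, path) {
  doc <- list(
    donor_id = d$donor_id,
    external_donor_id = d$external_donor_id,
    platform = d$platform,
    donation_timestamp = format(d$donation_timestamp, "%Y-%m-%dT%H:%M:%S"),
    conversations = lapply(d$conversations, function(cv) {
      list(
        conversation_id = cv$conversation_id,
        platform = cv$platform,
        is_group = cv$is_group,
        participant_ids = as.list(cv$participant_ids),
        messages = lapply(seq_len(nrow(cv$messages)), function(i) {
          m <- cv$messages[i, ]
          rec <- list(
            sender_id = m$sender_id,
            datetime = format(m$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
            word_count = m$word_count,
            is_media = m$is_media
          )
          if (!is.na(m$voice_duration_s))
            rec$voice_duration_s <- m$voice_duration_s
          rec
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_donation_json
#' @export
read_donation_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  conversations <- lapply(doc$conversations, function(cv) {
    msgs <- cv$messages
    mdf <- data.frame(
      sender_id = vapply(msgs, `[[`, character(1), "sender_id"),
      timestamp = as.POSIXct(vapply(msgs, `[[`, character(1), "datetime"),
                             format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      word_count = vapply(msgs, function(m) as.integer(m$word_count),
                          integer(1)),
      voice_duration_s = vapply(msgs, function(m)
        as.numeric(m$voice_duration_s %||% NA_real_), numeric(1)),
      is_media = vapply(msgs, function(m) isTRUE(m$is_media), logical(1)),
      stringsAsFactors = FALSE
    )
    structure(
      list(conversation_id = cv$conversation_id,
           platform = cv$platform,
           is_group = isTRUE(cv$is_group),
           participant_ids = sort(unlist(cv$participant_ids)),
           messages = mdf),
      class = "minimized_conversation"
    )
  })
  structure(
    list(donor_id = doc$donor_id,
         external_donor_id = doc$external_donor_id,
         platform = doc$platform,
         donation_timestamp = as.POSIXct(doc$donation_timestamp,
                                         format = "%Y-%m-%dT%H:%M:%S",
                                         tz = "UTC"),
         conversations = conversations),
    class = "donation"
  )
}

#' Write a donation as two relational CSV tables
#'
#' Mirrors a conversations/messages relational schema:
#' `conversations.csv` (donor_id, external_donor_id, conversation_id,
#' platform, is_group) and `messages.csv` (conversation_id, sender_id,
#' datetime, word_count, voice_duration_s, is_media).
#'
#' @param d A `donation`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_donation_csv <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  convs <- data.frame(
    donor_id = d$donor_id,
    external_donor_id = d$external_donor_id %||% "",
    conversation_id = vapply(d$conversations, `[[`, character(1),
                             "conversation_id"),
    platform = vapply(d$conversations, `[[`, character(1), "platform"),
    is_group = vapply(d$conversations, `[[`, logical(1), "is_group"),
    stringsAsFactors = FALSE
  )
  msgs <- do.call(rbind, lapply(d$conversations, function(cv) {
    data.frame(
      conversation_id = cv$conversation_id,
      sender_id = cv$messages$sender_id,
      datetime = format(cv$messages$timestamp, "%Y-%m-%dT%H:%M:%S",
                        tz = "UTC"),
      word_count = cv$messages$word_count,
      voice_duration_s = cv$messages$voice_duration_s,
      is_media = cv$messages$is_media,
      stringsAsFactors = FALSE
    )
  }))
  f1 <- file.path(dir, "conversations.csv")
  f2 <- file.path(dir, "messages.csv")
  utils::write.csv(convs, f1, row.names = FALSE)
  utils::write.csv(msgs, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read donations from the relational CSV schema
#'
#' Inverse of [write_donation_csv()].  The two tables may contain several
#' donors; one `donation` object is returned per distinct
#' (`donor_id`, `platform`) pair.  External datasets with different column
#' names can be ingested by renaming columns to this schema first (the
#' documented column-mapping step); only `donor_id`, `conversation_id`,
#' `sender_id`, `datetime` and `word_count` are required.
#'
#' @param dir Directory containing `conversations.csv` and `messages.csv`.
#' @return List of `donation` objects.
#' @export
read_donation_csv <- function(dir) {
  convs <- utils::read.csv(file.path(dir, "conversations.csv"),
                           stringsAsFactors = FALSE)
  msgs <- utils::read.csv(file.path(dir, "messages.csv"),
                          stringsAsFactors = FALSE)
  req_c <- c("donor_id", "conversation_id")
  req_m <- c("conversation_id", "sender_id", "datetime", "word_count")
  missing <- c(setdiff(req_c, names(convs)), setdiff(req_m, names(msgs)))
  if (length(missing)) {
    cm_error(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
             "chatmetrics_schema_mismatch")
  }
  if (is.null(convs$platform)) convs$platform <- "whatsapp"
  if (is.null(convs$is_group)) convs$is_group <- FALSE
  if (is.null(msgs$voice_duration_s)) msgs$voice_duration_s <- NA_real_
  if (is.null(msgs$is_media)) msgs$is_media <- msgs$word_count == 0
  keys <- unique(convs[, c("donor_id", "platform")])
  lapply(seq_len(nrow(keys)), function(i) {
    cset <- convs[convs$donor_id == keys$donor_id[i] &
                    convs$platform == keys$platform[i], , drop = FALSE]
    conversations <- lapply(seq_len(nrow(cset)), function(j) {
      cid <- cset$conversation_id[j]
      m <- msgs[msgs$conversation_id == cid, , drop = FALSE]
      mdf <- data.frame(
        sender_id = as.character(m$sender_id),
        timestamp = as.POSIXct(m$datetime, format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC"),
        word_count = as.integer(m$word_count),
        voice_duration_s = as.numeric(m$voice_duration_s),
        is_media = as.logical(m$is_media),
        stringsAsFactors = FALSE
      )
      mdf <- mdf[order(mdf$timestamp), , drop = FALSE]
      rownames(mdf) <- NULL
      structure(
        list(conversation_id = as.character(cid),
             platform = cset$platform[j],
             is_group = isTRUE(as.logical(cset$is_group[j])),
             participant_ids = sort(unique(mdf$sender_id)),
             messages = mdf),
        class = "minimized_conversation"
      )
    })
    structure(
      list(donor_id = as.character(keys$donor_id[i]),
           external_donor_id = NULL,
           platform = keys$platform[i],
           donation_timestamp = as.POSIXct(NA),
           conversations = conversations),
      class = "donation"
    )
  })
}
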