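#' Raw conversation model
#'
#' A `raw_conversation` holds parsed chat content exactly as exported by a
#' platform, before de-identification.  It is an in-memory object only: the
#' pipeline never serializes raw content to disk or to logs.
#'
#' Messages are kept in a data frame with columns `timestamp` (POSIXct,
#' naive local time stored as UTC), `sender_name` (empty for system
#' messages), `content`, `kind` (one of `"text"`, `"media"`, `"voice"`,
#' `"system"`) and `voice_duration_s` (seconds; `NA` unless `kind ==
#' "voice"`).
#'
#' @param platform `"whatsapp"`, `"facebook"` or `"instagram"`.
#' @param thread_name Display name of the chat or thread.
#' @param messages Data frame as described above.
#' @param is_group Logical; derived from the participant count when `NULL`.
#' @param participants Character vector of display names; derived from the
#'   senders when `NULL`.
#' @return An object of class `raw_conversation`.
#' @export
raw_conversation <- function(platform, thread_name, messages,
                             is_group = NULL, participants = NULL) {
  stopifnot(platform %in% c("whatsapp", "facebook", "instagram"))
  req <- c("timestamp", "sender_name", "content", "kind", "voice_duration_s")
  stopifnot(all(req %in% names(messages)))
  messages <- messages[order(messages$timestamp), req, drop = FALSE]
  rownames(messages) <- NULL
  if (is.null(participants)) {
    participants <- sort(unique(messages$sender_name[
      messages$kind != "system" & nzchar(messages$sender_name)]))
  }
  if (is.null(is_group)) is_group <- length(participants) > 2L
  validate_raw_messages(messages)
  structure(
    list(platform = platform, thread_name = thread_name,
         participants = participants, is_group = isTRUE(is_group),
         messages = messages),
    class = "raw_conversation"
  )
}

validate_raw_messages <- function(m) {
  stopifnot(
    all(m$kind %in% c("text", "media", "voice", "system")),
    all(!nzchar(m$sender_name[m$kind == "system"])),
    all(!is.na(m$voice_duration_s[m$kind == "voice"])),
    all(is.na(m$voice_duration_s[m$kind != "voice"]))
  )
  ts <- m$timestamp
  lo <- as.POSIXct("1990-01-01", tz = "UTC")
  hi <- Sys.time() + 86400
  if (any(is.na(ts)) || any(ts < lo) || any(ts > hi)) {
    cm_error("message timestamps out of plausible range",
             "chatmetrics_bad_timestamp")
  }
  invisible(m)
}

#' @export
print.raw_conversation <- function(x, ...) {
  cat(sprintf("<raw_conversation %s '%s': %d messages, %d participants%s>\n",
              x$platform, x$thread_name, nrow(x$messages),
              length(x$participants), if (x$is_group) ", group" else ""))
  invisible(x)
}

#' Donor profile
#'
#' The set of display names under which the donor appears in their own
#' exports.  Meta archives may contain several (name changes); WhatsApp
#' usually one.
#'
#' @param display_names Non-empty character vector.
#' @return Object of class `donor_profile`.
#' @export
donor_profile <- function(display_names) {
  display_names <- unique(display_names[nzchar(display_names)])
  if (length(display_names) == 0) {
    cm_error("donor profile needs at least one non-empty display name",
             "chatmetrics_bad_profile")
  }
  structure(list(display_names = display_names), class = "donor_profile")
}

#' Repair Latin-1-mojibake text
#'
#' Meta archives escape raw UTF-8 bytes as Latin-1 code points (the JSON
#' contains `Ã¼` where `ü` is meant).  After ordinary JSON
#' decoding such strings come out as mojibake.  This function re-encodes a
#' mis-decoded string to its intended characters and leaves already-valid
#' text untouched; it is idempotent and best-effort (undecodable byte
#' sequences are returned unchanged).
#'
#' @param s Character vector.
#' @return Character vector of the same length, UTF-8 encoded.
#' @examples
#' repair_text_encoding("GrÃ¼Ãe")  # "Grüße"
#' @export
repair_text_encoding <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) return(NA_character_)
    x <- enc2utf8(x)
    # iterate to a fixed point so doubly mis-decoded text also repairs,
    # which keeps the function idempotent
    for (i in 1:4) {
      y <- repair_once(x)
      if (identical(y, x)) break
      x <- y
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

repair_once <- function(x) {
  cp <- utf8ToInt(x)
  if (length(cp) == 0 || anyNA(cp) || any(cp > 255L)) return(x)
  if (all(cp < 128L)) return(x)       # pure ASCII: nothing to repair
  bytes <- as.raw(cp)                 # chars were really Latin-1 bytes
  y <- rawToChar(bytes)
  Encoding(y) <- "UTF-8"
  if (validUTF8(y)) y else x
}

strip_bom <- function(x) sub(paste0("^", intToUtf8(0xFEFF)), "", x)

#' Parse a WhatsApp chat export
#'
#' Turns the content of a per-chat WhatsApp `.txt` export into a
#' [raw_conversation()].  Each line matching the dialect's header grammar
#' starts a message; following non-header lines are appended to that
#' message's content (multi-line messages).  Header lines without a
#' `Sender: ` part, or whose text matches a known system pattern, become
#' system messages; content equal to a media marker becomes a media message
#' with empty effective text.  Lines before the first valid header
#' (export preambles) are discarded with a warning, as are headers whose
#' timestamp fails to parse.
#'
#' @param text Either a single string (whole file), a character vector of
#'   lines, or a path to a `.txt` or `.zip` file (a zip must contain exactly
#'   one `.txt`).
#' @param dialect A [whatsapp_dialect()]; auto-detected when `NULL`.
#' @param thread_name Optional chat name; defaults to the file name or
#'   `"whatsapp chat"`.
#' @return A [raw_conversation()] with `platform = "whatsapp"`.
#' @examples
#' conv <- parse_whatsapp("15.03.22, 14:32 - Alice: hello world")
#' conv$messages$content
#' @export
parse_whatsapp <- function(text, dialect = NULL, thread_name = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    path <- text
    if (grepl("\\.zip$", path, ignore.case = TRUE)) {
      exdir <- tempfile("wazip")
      utils::unzip(path, exdir = exdir)
      txts <- list.files(exdir, pattern = "\\.txt$", recursive = TRUE,
                         full.names = TRUE)
      if (length(txts) != 1) {
        cm_error("zip must contain exactly one .txt chat export",
                 "chatmetrics_bad_archive")
      }
      path <- txts[1]
    }
    if (is.null(thread_name)) {
      thread_name <- sub("\\.txt$", "", basename(path), ignore.case = TRUE)
    }
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(thread_name)) thread_name <- "whatsapp chat"
  lines <- sub("\r$", "", lines)
  if (length(lines)) lines[1] <- strip_bom(lines[1])

  if (is.null(dialect)) dialect <- detect_whatsapp_dialect(lines)
  rx <- header_regex(dialect)
  is_header <- grepl(rx, lines, perl = TRUE)
  if (!any(is_header)) {
    cm_error("no line matches the dialect header grammar",
             "chatmetrics_no_dialect")
  }

  ts <- list(); sender <- character(); content <- character()
  kind <- character(); n_pre <- 0L; n_bad_ts <- 0L
  skipping <- TRUE   # before first valid header, or after a bad timestamp
  cur <- 0L
  for (idx in seq_along(lines)) {
    ln <- lines[idx]
    if (is_header[idx]) {
      h <- match_header(ln, dialect)
      if (is.null(h) || is.na(h$timestamp)) {
        n_bad_ts <- n_bad_ts + 1L
        skipping <- TRUE
        next
      }
      parsed <- split_sender(h$rest, dialect)
      cur <- cur + 1L
      ts[[cur]] <- h$timestamp
      sender[cur] <- parsed$sender
      content[cur] <- parsed$content
      kind[cur] <- parsed$kind
      skipping <- FALSE
    } else {
      if (skipping || cur == 0L) { n_pre <- n_pre + 1L; next }
      content[cur] <- paste(content[cur], ln, sep = "\n")
    }
  }
  if (n_pre > 0) {
    cm_warn(sprintf("discarded %d non-message line(s) outside any message",
                    n_pre), "chatmetrics_preamble_dropped")
  }
  if (n_bad_ts > 0) {
    cm_warn(sprintf("skipped %d header(s) with malformed timestamps",
                    n_bad_ts), "chatmetrics_malformed_timestamp")
  }
  msgs <- data.frame(
    timestamp = as.POSIXct(unlist(ts), origin = "1970-01-01", tz = "UTC"),
    sender_name = sender, content = content, kind = kind,
    voice_duration_s = NA_real_, stringsAsFactors = FALSE
  )
  raw_conversation("whatsapp", thread_name, msgs)
}

# Split the post-timestamp remainder of a header into sender / content and
# classify the message kind.  WhatsApp system lines carry no "Sender: ".
split_sender <- function(rest, dialect) {
  m <- regexpr(": ", rest, fixed = TRUE)
  if (m < 0) {
    return(list(sender = "", content = rest, kind = "system"))
  }
  sender <- substr(rest, 1L, m - 1L)
  content <- substr(rest, m + 2L, nchar(rest))
  if (any(vapply(dialect$system_patterns, function(p) grepl(p, content),
                 logical(1))) && !nzchar(sender)) {
    return(list(sender = "", content = content, kind = "system"))
  }
  if (content %in% dialect$media_markers) {
    return(list(sender = sender, content = "", kind = "media"))
  }
  list(sender = sender, content = content, kind = "text")
}

#' Parse a Facebook/Instagram data-download archive
#'
#' Reads a Meta "Download Your Information" export — an unpacked directory
#' tree or a `.zip` — and returns the donor profile plus one
#' [raw_conversation()] per message thread.  A thread's numbered JSON parts
#' (`message_1.json`, `message_2.json`, ...) are merged and time-sorted.
#' Voice messages are recognized from audio attachment entries; their
#' duration is taken from attachment metadata when present.  All other
#' archive sections (posts, comments, reactions, ...) are ignored.
#'
#' @param root Path to the archive directory or `.zip` file.
#' @param platform `"facebook"` or `"instagram"`.
#' @return A list with elements `profile` ([donor_profile()] or `NULL` when
#'   not inferable) and `conversations` (list of [raw_conversation()]).
#' @export
parse_meta_archive <- function(root, platform = c("facebook", "instagram")) {
  platform <- match.arg(platform)
  if (grepl("\\.zip$", root, ignore.case = TRUE) && file.exists(root)) {
    exdir <- tempfile("metazip")
    utils::unzip(root, exdir = exdir)
    root <- exdir
  }
  if (!dir.exists(root)) {
    cm_error("archive root does not exist", "chatmetrics_bad_archive")
  }
  files <- list.files(root, pattern = "^message_\\d+\\.json$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0) {
    cm_error("no message JSON files found in archive",
             "chatmetrics_empty_archive")
  }
  threads <- split(files, dirname(files))
  convs <- list(); n_skipped <- 0L
  for (td in names(threads)) {
    conv <- tryCatch(parse_meta_thread(threads[[td]], platform),
                     error = function(e) e)
    if (inherits(conv, "error")) {
      n_skipped <- n_skipped + 1L
    } else {
      convs[[length(convs) + 1L]] <- conv
    }
  }
  if (n_skipped > 0) {
    cm_warn(sprintf("skipped %d malformed thread(s)", n_skipped),
            "chatmetrics_malformed_thread")
  }
  if (length(convs) == 0) {
    cm_error("archive contained no parseable threads",
             "chatmetrics_empty_archive")
  }
  profile <- read_meta_profile(root)
  if (is.null(profile)) profile <- infer_meta_donor(convs)
  list(profile = profile, conversations = convs)
}

parse_meta_thread <- function(part_files, platform) {
  parts <- lapply(sort(part_files), function(f)
    jsonlite::fromJSON(f, simplifyVector = FALSE))
  first <- parts[[1]]
  if (is.null(first$messages) || is.null(first$participants)) {
    cm_error("thread JSON lacks required fields", "chatmetrics_malformed_thread")
  }
  participants <- repair_text_encoding(vapply(
    first$participants, function(p) p$name %||% "", character(1)))
  title <- repair_text_encoding(first$title %||% "meta thread")
  msgs <- do.call(c, lapply(parts, function(p) p$messages))

  n <- length(msgs)
  ts <- numeric(n); sender <- character(n); content <- character(n)
  kind <- character(n); dur <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- msgs[[i]]
    if (is.null(m$timestamp_ms) || is.null(m$sender_name)) {
      cm_error("message lacks required fields", "chatmetrics_malformed_thread")
    }
    ts[i] <- as.numeric(m$timestamp_ms) / 1000
    sender[i] <- repair_text_encoding(m$sender_name)
    if (!is.null(m$audio_files) && length(m$audio_files) > 0) {
      kind[i] <- "voice"
      d <- m$audio_files[[1]]$duration_seconds %||% 0
      dur[i] <- as.numeric(d)
      content[i] <- ""
    } else if (!is.null(m$content)) {
      kind[i] <- "text"
      content[i] <- repair_text_encoding(m$content)
    } else {
      # photos, videos, stickers, shares: metadata-only media event
      kind[i] <- "media"
      content[i] <- ""
    }
  }
  # Meta epoch timestamps are converted without timezone shifting: the
  # pipeline treats all times as naive local clock readings.
  msgs_df <- data.frame(
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
    sender_name = sender, content = content, kind = kind,
    voice_duration_s = dur, stringsAsFactors = FALSE
  )
  raw_conversation(platform, title, msgs_df,
                   is_group = length(participants) > 2L,
                   participants = sort(unique(participants)))
}

read_meta_profile <- function(root) {
  cand <- list.files(root, pattern = "profile_information\\.json$|personal_information\\.json$",
                     recursive = TRUE, full.names = TRUE)
  for (f in cand) {
    j <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                  error = function(e) NULL)
    nm <- j$profile_v2$name$full_name %||% j$profile_user[[1]]$string_map_data$Name$value %||% NULL
    if (!is.null(nm) && nzchar(nm)) {
      return(donor_profile(repair_text_encoding(nm)))
    }
  }
  NULL
}

# Donor inference when the archive lacks a profile file: the donor is a
# participant of every thread, so pick the sender present in the largest
# number of threads.
infer_meta_donor <- function(convs) {
  per_thread <- lapply(convs, function(cv)
    unique(cv$messages$sender_name[cv$messages$kind != "system"]))
  tab <- sort(table(unlist(per_thread)), decreasing = TRUE)
  tab <- tab[nzchar(names(tab))]
  if (length(tab) == 0) return(NULL)
  donor_profile(names(tab)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
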