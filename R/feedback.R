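#' Messaging intensity over time
#'
#' Per time bin (calendar month by default, ISO week optionally): total
#' words sent by the donor across all chats, and total words received from
#' all contacts in aggregate.  The privacy rule: if a bin contains messages
#' from fewer than `min_contacts` distinct contacts, the received side is
#' suppressed for that bin — no statistic derived from a single partner's
#' behavior is ever shown.  The donor side is never suppressed.
#'
#' @param d A `donation`.
#' @param bin `"month"` or `"week"`.
#' @param min_contacts Minimum distinct active contacts for the received
#'   side to be shown (default 2; raise for stricter aggregation).
#' @return Data frame with columns `bin`, `words_sent`, `words_received`
#'   (`NA` where suppressed) and `received_suppressed`.
#' @export
intensity_series <- function(d, bin = c("month", "week"), min_contacts = 2L) {
  bin <- match.arg(bin)
  msgs <- donation_messages(d)
  stopifnot(nrow(msgs) > 0)
  dt <- as.Date(msgs$timestamp, tz = "UTC")
  if (bin == "month") {
    msgs$bin <- format(dt, "%Y-%m")
    first <- as.Date(paste0(format(min(dt), "%Y-%m"), "-01"))
    last <- as.Date(paste0(format(max(dt), "%Y-%m"), "-01"))
    bins <- format(seq(first, last, by = "month"), "%Y-%m")
  } else {
    # ISO weeks, enumerated from the Monday of the first week
    monday <- function(x) x - (as.integer(format(x, "%u")) - 1L)
    msgs$bin <- format(dt, "%G-W%V")
    bins <- format(seq(monday(min(dt)), monday(max(dt)), by = 7), "%G-W%V")
  }
  donor <- msgs$sender_id == d$donor_id
  out <- do.call(rbind, lapply(bins, function(b) {
    in_bin <- msgs$bin == b
    sent <- sum(msgs$word_count[in_bin & donor])
    contacts <- unique(msgs$sender_id[in_bin & !donor])
    suppressed <- length(contacts) < min_contacts
    data.frame(
      bin = b,
      words_sent = sent,
      words_received = if (suppressed) NA_real_ else
        sum(msgs$word_count[in_bin & !donor]),
      received_suppressed = suppressed,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Active hours histogram
#'
#' Hour-of-day (0-23, local clock of the export) histogram of messages the
#' donor sent.  Media and voice messages count: they are interactions.
#'
#' @param d A `donation`.
#' @return Integer vector of length 24, named `"0"`..`"23"`; sums to the
#'   number of donor-sent messages.
#' @export
active_hours <- function(d) {
  msgs <- donation_messages(d)
  counts <- integer(24)
  names(counts) <- as.character(0:23)
  if (nrow(msgs) == 0) return(counts)
  hrs <- as.integer(format(msgs$timestamp[msgs$sender_id == d$donor_id],
                           "%H", tz = "UTC"))
  tab <- table(factor(hrs, levels = 0:23))
  counts[] <- as.integer(tab)
  counts
}

#' Donor response times
#'
#' For every donor message that directly follows one or more contact
#' messages within the same chat, the latency is the time from the latest
#' preceding contact message to the donor message.  Consecutive donor
#' messages contribute a single latency (the first).  Latencies above `cap`
#' are treated as conversation restarts and discarded, as are zero
#' latencies (same-second bursts carry no response information).
#'
#' @param d A `donation`.
#' @param cap Maximum latency in seconds (default 7 days).
#' @return List with `latencies` (seconds), `median`, `q1`, `q3`, `n`.
#' @export
response_times <- function(d, cap = 7 * 86400) {
  lat <- numeric(0)
  for (cv in d$conversations) {
    m <- cv$messages
    if (nrow(m) < 2) next
    donor <- m$sender_id == d$donor_id
    prev_contact <- c(FALSE, !donor[-nrow(m)])
    idx <- which(donor & prev_contact)
    if (length(idx) == 0) next
    lat <- c(lat, as.numeric(m$timestamp[idx]) - as.numeric(m$timestamp[idx - 1L]))
  }
  lat <- lat[lat > 0 & lat <= cap]
  if (length(lat) == 0) {
    return(list(latencies = numeric(0), median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, n = 0L))
  }
  q <- stats::quantile(lat, c(0.25, 0.5, 0.75), names = FALSE)
  list(latencies = lat, median = q[2], q1 = q[1], q3 = q[3],
       n = length(lat))
}

# All messages of a donation in one frame (adds conversation_id).
donation_messages <- function(d) {
  do.call(rbind, lapply(d$conversations, function(cv) {
    m <- cv$messages
    m$conversation_id <- cv$conversation_id
    m
  }))
}

#' Export feedback panels as plot-ready files
#'
#' Writes one CSV per panel (intensity, active hours, response-time
#' summary) plus a combined JSON document.  Static files only.
#'
#' @param d A `donation`.
#' @param dir Output directory.
#' @param bin Passed to [intensity_series()].
#' @param cap Passed to [response_times()].
#' @return Paths of the written files, invisibly.
#' @export
write_feedback <- function(d, dir, bin = "month", cap = 7 * 86400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inten <- intensity_series(d, bin)
  hours <- active_hours(d)
  rt <- response_times(d, cap)
  f1 <- file.path(dir, "intensity.csv")
  f2 <- file.path(dir, "active_hours.csv")
  f3 <- file.path(dir, "response_times.csv")
  f4 <- file.path(dir, "feedback.json")
  utils::write.csv(inten, f1, row.names = FALSE)
  utils::write.csv(data.frame(hour = 0:23, messages = as.integer(hours)),
                   f2, row.names = FALSE)
  utils::write.csv(data.frame(n = rt$n, q1_s = rt$q1, median_s = rt$median,
                              q3_s = rt$q3),
                   f3, row.names = FALSE)
  jsonlite::write_json(
    list(intensity = inten,
         active_hours = data.frame(hour = 0:23,
                                   messages = as.integer(hours)),
         response_times = list(n = rt$n, q1_s = rt$q1,
                               median_s = rt$median, q3_s = rt$q3)),
    f4, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(c(f1, f2, f3, f4))
}
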