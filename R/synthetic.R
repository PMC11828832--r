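#' Simulation parameters for one synthetic chat
#'
#' The generator produces a dyadic (or group) conversation whose statistical
#' structure is controllable along exactly the axes the metrics measure:
#' the day-gap process sets burstiness (fixed gaps -> B1 = -1, geometric
#' gaps -> B1 near 0, Pareto gaps -> B1 > 0), `balance` sets the expected
#' donor word share (hence interaction bias ~ 0.5 - balance), and the
#' per-message word law sets intensity.  All content is drawn from a closed
#' sentinel vocabulary so leakage audits are complete rather than
#' heuristic.
#'
#' @param n_interaction_days Number of distinct calendar days with
#'   messages.
#' @param day_gap One of [gap_fixed()], [gap_geometric()], [gap_pareto()].
#' @param messages_per_day Either a fixed positive integer or
#'   `list(kind = "poisson", lambda = )` (shifted by 1 so every
#'   interaction day has a message).
#' @param balance Target donor share of words in `[0, 1]` (0.5 = balanced).
#' @param words_per_message Fixed positive integer or
#'   `list(kind = "lognormal", meanlog = , sdlog = )`, rounded, minimum 1.
#' @param media_rate Fraction of messages that are media placeholders.
#' @param voice_rate Fraction of messages that are voice messages (only
#'   meaningful for Meta-rendered fixtures; WhatsApp cannot export them).
#' @param language Marker language for WhatsApp rendering.
#' @param start_date First interaction day.
#' @param seed Integer seed.
#' @return Object of class `chat_sim_params`.
#' @export
chat_sim_params <- function(n_interaction_days = 60L,
                            day_gap = gap_geometric(0.2),
                            messages_per_day = list(kind = "poisson",
                                                    lambda = 4),
                            balance = 0.5,
                            words_per_message = list(kind = "lognormal",
                                                     meanlog = 1.6,
                                                     sdlog = 0.7),
                            media_rate = 0.05,
                            voice_rate = 0,
                            language = "en",
                            start_date = as.Date("2021-01-04"),
                            seed = 1L) {
  if (n_interaction_days < 1 || balance < 0 || balance > 1 ||
      media_rate < 0 || media_rate > 1 || voice_rate < 0 || voice_rate > 1 ||
      media_rate + voice_rate > 1) {
    cm_error("invalid simulation parameters", "chatmetrics_invalid_params")
  }
  structure(
    list(n_interaction_days = as.integer(n_interaction_days),
         day_gap = day_gap, messages_per_day = messages_per_day,
         balance = balance, words_per_message = words_per_message,
         media_rate = media_rate, voice_rate = voice_rate,
         language = language, start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "chat_sim_params"
  )
}

#' Day-gap processes
#'
#' The three inter-event-day laws span the burstiness range: `gap_fixed(g)`
#' gives perfectly regular interaction days (population CV 0, B1 = -1);
#' `gap_geometric(p)` gives memoryless day gaps (`P(gap = g) = p (1-p)^(g-1)`,
#' CV `sqrt(1 - p)`, so B1 approaches 0 for small `p`); `gap_pareto(alpha,
#' xmin)` gives heavy-tailed gaps (`gap = ceiling(xmin * U^(-1/alpha))`),
#' infinite-variance for `alpha <= 2`, hence B1 > 0.
#'
#' @param g Fixed gap in days.
#' @param p Geometric success probability in `(0, 1]`.
#' @param alpha Pareto tail exponent (> 0).
#' @param xmin Pareto scale (minimum gap).
#' @return A day-gap process description.
#' @export
gap_fixed <- function(g = 1L) {
  stopifnot(g >= 1)
  list(kind = "fixed", g = as.integer(g))
}

#' @rdname gap_fixed
#' @export
gap_geometric <- function(p = 0.2) {
  stopifnot(p > 0, p <= 1)
  list(kind = "geometric", p = p)
}

#' @rdname gap_fixed
#' @export
gap_pareto <- function(alpha = 1.5, xmin = 1) {
  stopifnot(alpha > 0, xmin >= 1)
  list(kind = "pareto", alpha = alpha, xmin = xmin)
}

draw_gaps <- function(proc, n) {
  if (n <= 0) return(integer(0))
  switch(proc$kind,
    fixed = rep(proc$g, n),
    geometric = stats::rgeom(n, proc$p) + 1L,
    pareto = as.integer(ceiling(proc$xmin * stats::runif(n)^(-1 / proc$alpha))),
    cm_error("unknown day-gap process", "chatmetrics_invalid_params"))
}

draw_counts <- function(law, n) {
  if (is.numeric(law)) return(rep(as.integer(law), n))
  switch(law$kind,
    poisson = stats::rpois(n, law$lambda) + 1L,
    fixed = rep(as.integer(law$value), n),
    cm_error("unknown count law", "chatmetrics_invalid_params"))
}

draw_words <- function(law, n) {
  if (n == 0) return(integer(0))
  if (is.numeric(law)) return(rep(as.integer(law), n))
  switch(law$kind,
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(n, law$meanlog, law$sdlog)))),
    fixed = rep(as.integer(law$value), n),
    cm_error("unknown word law", "chatmetrics_invalid_params"))
}

# Closed sentinel vocabulary: every name and content token a fixture can
# emit comes from here, which makes audit_no_leakage() complete.
sentinel_words <- function() sprintf("sentw%03d", 1:40)

sentinel_donor_name <- function() "SentinelDonor"

sentinel_contact_names <- function(k) sprintf("SentinelContact%02d", seq_len(k))

#' The sentinel vocabulary of the fixture generator
#'
#' All names and content tokens that [simulate_conversation()] /
#' [simulate_donation()] can plant.  Feed this to [audit_no_leakage()].
#'
#' @param k Maximum number of contacts to cover.
#' @return Character vector.
#' @export
sentinel_vocabulary <- function(k = 99L) {
  c(sentinel_words(), sentinel_donor_name(), sentinel_contact_names(k))
}

#' Simulate one raw conversation
#'
#' Messages fall on exactly `n_interaction_days` distinct days whose gaps
#' follow the configured day-gap process; within a day, message times are
#' distinct whole minutes (so every WhatsApp dialect, with or without
#' seconds, round-trips the timestamps exactly).  Each message's sender is
#' the donor with probability `balance`, and word counts follow the word
#' law independently of the sender, so the expected donor word share equals
#' `balance`.  Deterministic under `p$seed`.
#'
#' @param p A [chat_sim_params()].
#' @param donor_name,contact_names Display names; defaults use the sentinel
#'   names.
#' @param thread_name Chat title.
#' @return A [raw_conversation()] (`platform = "whatsapp"`; re-render as
#'   Meta JSON with [render_meta_json()] if needed).
#' @export
simulate_conversation <- function(p, donor_name = sentinel_donor_name(),
                                  contact_names = sentinel_contact_names(1),
                                  thread_name = paste0("chat-",
                                                       contact_names[1])) {
  stopifnot(inherits(p, "chat_sim_params"))
  with_seed(p$seed, {
    nd <- p$n_interaction_days
    gaps <- draw_gaps(p$day_gap, nd - 1L)
    days <- p$start_date + cumsum(c(0L, gaps))
    # keep timestamps inside the plausible window: shift long series back
    # so they end in the past (every metric is shift-invariant)
    overshoot <- as.integer(days[nd] - (Sys.Date() - 7L))
    if (overshoot > 0) days <- days - overshoot
    m_per_day <- pmin(draw_counts(p$messages_per_day, nd), 1440L)
    n <- sum(m_per_day)
    ts <- do.call(c, lapply(seq_len(nd), function(i) {
      mins <- sort(sample.int(1440L, m_per_day[i]) - 1L)
      as.POSIXct(days[i], tz = "UTC") + mins * 60
    }))
    donor <- stats::runif(n) < p$balance
    people <- ifelse(donor, donor_name,
                     sample(contact_names, n, replace = TRUE))
    u <- stats::runif(n)
    kind <- ifelse(u < p$media_rate, "media",
                   ifelse(u < p$media_rate + p$voice_rate, "voice", "text"))
    words <- draw_words(p$words_per_message, n)
    vocab <- sentinel_words()
    content <- character(n)
    for (i in seq_len(n)) {
      content[i] <- if (kind[i] == "text")
        paste(sample(vocab, words[i], replace = TRUE), collapse = " ")
      else ""
    }
    dur <- ifelse(kind == "voice",
                  as.numeric(sample.int(60L, n, replace = TRUE)), NA_real_)
    msgs <- data.frame(
      timestamp = ts, sender_name = people, content = content,
      kind = kind, voice_duration_s = dur, stringsAsFactors = FALSE
    )
    raw_conversation("whatsapp", thread_name, msgs,
                     participants = sort(unique(c(donor_name, contact_names))))
  })
}

#' Simulation parameters for a donor's whole network
#'
#' @param k Number of contacts (dyadic chats).
#' @param contact_weights `list(kind = "equal")` (donor word totals forced
#'   exactly equal, downstream Gini exactly 0),
#'   `list(kind = "lognormal", meanlog = , sdlog = )` (heterogeneous
#'   per-contact intensity), or `list(kind = "single_dominant")` (the donor
#'   writes to one contact only; downstream Gini `(k-1)/k`).
#' @param chat Base [chat_sim_params()] applied to every chat.
#' @param seed Integer seed.
#' @return Object of class `network_sim_params`.
#' @export
network_sim_params <- function(k = 6L,
                               contact_weights = list(kind = "lognormal",
                                                      meanlog = 0,
                                                      sdlog = 1),
                               chat = chat_sim_params(),
                               seed = 1L) {
  if (k < 1) cm_error("k must be >= 1", "chatmetrics_invalid_params")
  structure(list(k = as.integer(k), contact_weights = contact_weights,
                 chat = chat, seed = as.integer(seed)),
            class = "network_sim_params")
}

#' Simulate a donor's network of chats
#'
#' `k` dyadic conversations sharing one donor name.  Contact-weight law
#' `"equal"` forces identical deterministic chats (fixed word counts,
#' strict sender alternation) so realized donor word totals are exactly
#' equal; `"lognormal"` scales each chat's message intensity by a lognormal
#' weight; `"single_dominant"` sets `balance = 0` (the donor silent) in all
#' chats but the first.
#'
#' @param np A [network_sim_params()].
#' @return List with `profile` ([donor_profile()]), `conversations` (list
#'   of [raw_conversation()]) and `sentinels` (the planted vocabulary).
#' @export
simulate_donation <- function(np) {
  stopifnot(inherits(np, "network_sim_params"))
  contacts <- sentinel_contact_names(np$k)
  base <- np$chat
  law <- np$contact_weights
  weights <- with_seed(np$seed, switch(law$kind,
    equal = rep(1, np$k),
    lognormal = stats::rlnorm(np$k, law$meanlog, law$sdlog),
    single_dominant = c(1, rep(0, np$k - 1L)),
    cm_error("unknown contact-weight law", "chatmetrics_invalid_params")))
  convs <- lapply(seq_len(np$k), function(j) {
    pj <- base
    pj$seed <- base$seed + 1000L * j + np$seed
    if (law$kind == "equal") {
      # force identical realized totals: deterministic counts and strict
      # alternation donor/contact (donor first)
      pj$messages_per_day <- list(kind = "fixed", value = 4L)
      pj$words_per_message <- list(kind = "fixed", value = 6L)
      pj$media_rate <- 0; pj$voice_rate <- 0
      conv <- simulate_conversation(pj, contact_names = contacts[j])
      n <- nrow(conv$messages)
      conv$messages$sender_name <- rep(c(sentinel_donor_name(), contacts[j]),
                                       length.out = n)
      return(conv)
    }
    if (law$kind == "single_dominant" && weights[j] == 0) pj$balance <- 0
    if (law$kind == "lognormal") {
      lam <- if (is.numeric(base$messages_per_day)) base$messages_per_day
             else base$messages_per_day$lambda
      pj$messages_per_day <- list(kind = "poisson",
                                  lambda = max(0.2, lam * weights[j]))
    }
    simulate_conversation(pj, contact_names = contacts[j])
  })
  list(profile = donor_profile(sentinel_donor_name()),
       conversations = convs,
       sentinels = sentinel_vocabulary(np$k))
}

#' Render a conversation as a WhatsApp text export
#'
#' Inverse of [parse_whatsapp()] for a given dialect: one header line per
#' message, multi-line contents emitted verbatim (continuation lines),
#' media and voice messages rendered as the dialect language's media
#' marker, system messages as headers without a sender.
#'
#' @param conv A [raw_conversation()].
#' @param dialect A [whatsapp_dialect()].
#' @return A single string (the file content).
#' @export
render_whatsapp <- function(conv, dialect = whatsapp_dialect()) {
  lt <- whatsapp_language_table()
  marker <- lt[[dialect$language]]$media_markers[1]
  lines <- vapply(seq_len(nrow(conv$messages)), function(i) {
    m <- conv$messages[i, ]
    prefix <- format_whatsapp_timestamp(m$timestamp, dialect)
    if (dialect$bracket_style == "bracketed") prefix <- paste0("[", prefix, "]")
    sep <- if (dialect$bracket_style == "bracketed") " " else " - "
    if (m$kind == "system") {
      paste0(prefix, sep, m$content)
    } else if (m$kind %in% c("media", "voice")) {
      paste0(prefix, sep, m$sender_name, ": ", marker)
    } else {
      paste0(prefix, sep, m$sender_name, ": ", m$content)
    }
  }, character(1))
  paste(lines, collapse = "\n")
}

# UTF-8 bytes reinterpreted as Latin-1 code points: the mojibake convention
# of Meta JSON exports.  Inverse of repair_text_encoding() on its image.
mojibake_encode <- function(s) {
  vapply(s, function(x) {
    b <- charToRaw(enc2utf8(x))
    y <- rawToChar(b)
    Encoding(y) <- "latin1"
    iconv(y, "latin1", "UTF-8")
  }, character(1), USE.NAMES = FALSE)
}

#' Render conversations as a Meta JSON archive
#'
#' Writes an inbox-style directory tree (`messages/inbox/<thread>/
#' message_<k>.json`) with each thread split into `parts_per_thread`
#' numbered parts, newest messages first (as Meta exports do), plus a
#' profile-information file.  Voice messages become audio attachment
#' entries carrying `duration_seconds`; media messages become photo
#' entries.  All text fields are written with the Latin-1-escaped mojibake
#' convention so that parsing exercises [repair_text_encoding()].
#'
#' @param profile A [donor_profile()].
#' @param convs List of [raw_conversation()].
#' @param dir Output directory (created).
#' @param parts_per_thread Number of JSON parts per thread.
#' @param zipfile Optional path; when given (and the `zip` package is
#'   available) the tree is also packed into this `.zip`.
#' @return `dir`, invisibly.
#' @export
render_meta_json <- function(profile, convs, dir, parts_per_thread = 1L,
                             zipfile = NULL) {
  stopifnot(parts_per_thread >= 1)
  inbox <- file.path(dir, "messages", "inbox")
  dir.create(inbox, showWarnings = FALSE, recursive = TRUE)
  for (ti in seq_along(convs)) {
    cv <- convs[[ti]]
    slug <- sprintf("%s_%d", gsub("[^a-z0-9]+", "", tolower(cv$thread_name)), ti)
    tdir <- file.path(inbox, slug)
    dir.create(tdir, showWarnings = FALSE)
    m <- cv$messages[cv$messages$kind != "system", , drop = FALSE]
    m <- m[order(m$timestamp, decreasing = TRUE), , drop = FALSE]
    recs <- lapply(seq_len(nrow(m)), function(i) {
      r <- list(sender_name = mojibake_encode(m$sender_name[i]),
                timestamp_ms = as.numeric(m$timestamp[i]) * 1000)
      if (m$kind[i] == "voice") {
        r$audio_files <- list(list(
          uri = sprintf("messages/inbox/%s/audio/clip_%d.aac", slug, i),
          duration_seconds = m$voice_duration_s[i]))
      } else if (m$kind[i] == "media") {
        r$photos <- list(list(
          uri = sprintf("messages/inbox/%s/photos/img_%d.jpg", slug, i)))
      } else {
        r$content <- mojibake_encode(m$content[i])
      }
      r
    })
    parts <- split(recs, ceiling(seq_along(recs) /
                                   max(1, ceiling(length(recs) /
                                                    parts_per_thread))))
    if (length(parts) == 0) parts <- list(list())
    for (k in seq_along(parts)) {
      doc <- list(
        participants = lapply(cv$participants, function(nm)
          list(name = mojibake_encode(nm))),
        messages = unname(parts[[k]]),
        title = mojibake_encode(cv$thread_name),
        thread_path = paste0("inbox/", slug)
      )
      jsonlite::write_json(doc, file.path(tdir, sprintf("message_%d.json", k)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  pdir <- file.path(dir, "profile_information")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(profile_v2 = list(name = list(
      full_name = mojibake_encode(profile$display_names[1])))),
    file.path(pdir, "profile_information.json"),
    auto_unbox = TRUE)
  if (!is.null(zipfile) && requireNamespace("zip", quietly = TRUE)) {
    zip::zip(zipfile, files = list.files(dir, recursive = TRUE),
             root = dir, mode = "mirror")
  }
  invisible(dir)
}
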