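#' Per-participant word shares in a chat
#'
#' Fraction of the chat's total word count contributed by each participant.
#' Media/voice messages carry word count 0 and therefore contribute nothing.
#'
#' @param conv A `minimized_conversation`.
#' @return Named numeric vector of shares summing to 1.
#' @export
word_shares <- function(conv) {
  tot <- tapply(conv$messages$word_count, conv$messages$sender_id, sum)
  tot <- tot[!is.na(tot)]
  total <- sum(tot)
  if (total <= 0) {
    cm_error("chat has no words (media-only); excluded from word-based metrics",
             "chatmetrics_empty_chat")
  }
  shares <- as.numeric(tot) / total
  names(shares) <- names(tot)
  shares
}

#' Interactivity filter
#'
#' A chat is interactive when no single conversation partner contributed
#' more than `threshold` (default 90%) of the words.  "More than" is strict:
#' a share of exactly 0.9 still counts as interactive.  Screens out
#' one-sided artifacts such as ads or unanswered requests from strangers.
#'
#' @param conv A `minimized_conversation`.
#' @param threshold Maximum allowed word share (default 0.9).
#' @return List with `interactive` (logical) and `max_share`.
#' @export
is_interactive <- function(conv, threshold = 0.9) {
  shares <- word_shares(conv)
  mx <- max(shares)
  list(interactive = mx <= threshold, max_share = mx)
}

#' Directed interaction bias of a dyad
#'
#' `0.5 - w_ij / (w_ij + w_ji)` where `w_ij` is the number of words the
#' donor sent to the contact and `w_ji` the reverse.  Zero means balance;
#' -0.5 means the donor sent everything; +0.5 means the contact did.
#'
#' @param w_ij Words sent donor -> contact.
#' @param w_ji Words sent contact -> donor.
#' @return Bias in `[-0.5, 0.5]`.
#' @examples
#' interaction_bias(300, 100)  # -0.25
#' @export
interaction_bias <- function(w_ij, w_ji) {
  stopifnot(w_ij >= 0, w_ji >= 0)
  if (w_ij + w_ji <= 0) {
    cm_error("degenerate tally: no words in either direction",
             "chatmetrics_degenerate_tally")
  }
  0.5 - w_ij / (w_ij + w_ji)
}

#' Gini index of interaction heterogeneity
#'
#' How unevenly a donor's words are spread over their `k` contacts.  With
#' `V` the per-contact word totals sorted ascending and `j` the rank:
#'
#' \deqn{g = \frac{2 \sum_j j V_j}{k \sum_j V_j} - \frac{k+1}{k}}
#'
#' 0 for equal weights, `(k-1)/k` when one contact receives everything.
#' Input order does not matter; the vector is sorted internally.
#'
#' @param v Non-negative per-contact word totals, any order.
#' @return Gini index in `[0, (k-1)/k]`.
#' @examples
#' gini_index(c(5, 5, 5, 5))    # 0
#' gini_index(c(0, 0, 0, 12))   # 0.75
#' @export
gini_index <- function(v) {
  stopifnot(length(v) >= 1, all(v >= 0))
  if (sum(v) <= 0) {
    cm_error("all contact weights zero", "chatmetrics_zero_total")
  }
  v <- sort(v)
  k <- length(v)
  j <- seq_len(k)
  2 * sum(j * v) / (k * sum(v)) - (k + 1) / k
}

#' Inter-event day series of a chat
#'
#' Interactions are counted at day resolution: an interaction day is a
#' calendar day with at least one message from either partner (media and
#' voice messages included — they are interactions).  Inter-event times are
#' the day differences between consecutive interaction days, so they are
#' integers >= 1.  A chat is eligible for burstiness analysis with at least
#' `min_days` (default 10) interaction days.
#'
#' @param conv A `minimized_conversation`.
#' @param min_days Eligibility threshold on the number of interaction days.
#' @return List with `interaction_days` (Date), `inter_event_times`
#'   (integer), `n_days` and `eligible`.
#' @export
interevent_series <- function(conv, min_days = 10L) {
  stopifnot(nrow(conv$messages) > 0)
  days <- sort(unique(as.Date(conv$messages$timestamp, tz = "UTC")))
  iet <- if (length(days) > 1) as.integer(diff(days)) else integer(0)
  structure(
    list(interaction_days = days, inter_event_times = iet,
         n_days = length(days), eligible = length(days) >= min_days),
    class = "interevent_series"
  )
}

#' Burstiness of an inter-event series
#'
#' Coefficient of variation `r = sigma / mu` of the inter-event times (with
#' `sigma` the population standard deviation, the convention under which a
#' perfectly regular series gives exactly -1), mapped to
#' `B1 = (r - 1) / (r + 1)`: -1 regular, 0 Poisson-like, towards 1
#' extremely bursty.
#'
#' @param s An [interevent_series()], or a numeric vector of inter-event
#'   times directly.
#' @param check_eligibility Enforce the `>= 10` interaction-day rule
#'   (default `TRUE`; unit tests on tiny series may waive it).
#' @return List with `mu`, `sigma`, `r`, `b1`.
#' @examples
#' burstiness(c(1, 3), check_eligibility = FALSE)$b1  # -1/3
#' @export
burstiness <- function(s, check_eligibility = TRUE) {
  if (inherits(s, "interevent_series")) {
    if (check_eligibility && !s$eligible) {
      cm_error("chat has fewer than the minimum interaction days",
               "chatmetrics_ineligible_chat")
    }
    x <- as.numeric(s$inter_event_times)
  } else {
    x <- as.numeric(s)
  }
  if (length(x) < 1) {
    cm_error("no inter-event times", "chatmetrics_ineligible_chat")
  }
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population SD: B1 = -1 iff constant
  r <- sigma / mu
  list(mu = mu, sigma = sigma, r = r, b1 = (r - 1) / (r + 1))
}

#' Per-chat metric table for a set of donations
#'
#' One row per conversation: platform, group flag, interactivity decision
#' and max word share, dyadic interaction bias (donor perspective; `NA` for
#' group or word-empty chats), interaction-day count and burstiness `B1`
#' (`NA` when ineligible).
#'
#' @param donations List of `donation` objects.
#' @param threshold Interactivity threshold (default 0.9).
#' @param min_days Burstiness eligibility threshold (default 10).
#' @return Data frame, one row per chat.
#' @export
per_chat_metrics <- function(donations, threshold = 0.9, min_days = 10L) {
  rows <- list()
  for (di in seq_along(donations)) {
    d <- donations[[di]]
    for (cv in d$conversations) {
      words <- tapply(cv$messages$word_count, cv$messages$sender_id, sum)
      total <- sum(words)
      interactive <- NA; max_share <- NA_real_; bias <- NA_real_
      if (total > 0) {
        fl <- is_interactive(cv, threshold)
        interactive <- fl$interactive
        max_share <- fl$max_share
        if (!cv$is_group) {
          w_ij <- if (d$donor_id %in% names(words))
            words[[d$donor_id]] else 0
          bias <- interaction_bias(w_ij, total - w_ij)
        }
      }
      s <- interevent_series(cv, min_days)
      b1 <- if (s$eligible) burstiness(s)$b1 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        donation = di, donor_id = d$donor_id,
        conversation_id = cv$conversation_id, platform = cv$platform,
        is_group = cv$is_group, n_messages = nrow(cv$messages),
        total_words = total, interactive = interactive,
        max_share = max_share, bias = bias,
        n_days = s$n_days, b1 = b1, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant (per-donation) summary metrics
#'
#' For each donation: the median interaction bias over its interactive
#' dyadic chats, and the Gini index of donor-sent word totals over its
#' interactive chats.
#'
#' @inheritParams per_chat_metrics
#' @return Data frame with one row per donation.
#' @export
per_participant_metrics <- function(donations, threshold = 0.9) {
  rows <- lapply(seq_along(donations), function(di) {
    d <- donations[[di]]
    chats <- per_chat_metrics(list(d), threshold)
    ia <- chats$interactive %in% TRUE
    biases <- chats$bias[ia & !chats$is_group & !is.na(chats$bias)]
    v <- donor_word_vector(d, interactive_only = TRUE, threshold = threshold)
    data.frame(
      donation = di, donor_id = d$donor_id, platform = d$platform,
      n_chats = length(d$conversations),
      n_interactive = sum(ia),
      median_bias = if (length(biases)) stats::median(biases) else NA_real_,
      gini = if (length(v) >= 1 && sum(v) > 0) gini_index(v) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Donor-sent word totals per contact/chat
#'
#' The contact weight vector feeding the Gini index: for each conversation,
#' the number of words the donor sent in it.
#'
#' @param d A `donation`.
#' @param interactive_only Keep only interactive chats (default `TRUE`).
#' @param threshold Interactivity threshold.
#' @return Numeric vector, one entry per (kept) conversation.
#' @export
donor_word_vector <- function(d, interactive_only = TRUE, threshold = 0.9) {
  v <- numeric(0)
  for (cv in d$conversations) {
    words <- tapply(cv$messages$word_count, cv$messages$sender_id, sum)
    total <- sum(words)
    if (interactive_only) {
      if (total <= 0) next
      if (!is_interactive(cv, threshold)$interactive) next
    }
    w_d <- if (d$donor_id %in% names(words)) words[[d$donor_id]] else 0
    v <- c(v, w_d)
  }
  v
}

#' Platform-level donation summary
#'
#' Descriptive statistics per platform in the layout of a donation-study
#' summary table: number of donations, chats (with group-chat percentage),
#' interactive chats, chats per person, group chats per person, donation
#' timespan in days, and donation message counts — each with
#' median/mean/SD/range where applicable.  Also returns pooled medians of
#' the per-participant bias and Gini and the per-chat burstiness.
#'
#' @inheritParams per_chat_metrics
#' @return List with `per_platform` (data frame), `per_participant`,
#'   `per_chat`, and `pooled` (named list of medians and shares).
#' @export
summarize_donations <- function(donations, threshold = 0.9, min_days = 10L) {
  chats <- per_chat_metrics(donations, threshold, min_days)
  parts <- per_participant_metrics(donations, threshold)

  don_stats <- do.call(rbind, lapply(seq_along(donations), function(di) {
    d <- donations[[di]]
    ts <- do.call(c, lapply(d$conversations, function(cv) cv$messages$timestamp))
    data.frame(
      donation = di, platform = d$platform,
      n_chats = length(d$conversations),
      n_group = sum(vapply(d$conversations, `[[`, logical(1), "is_group")),
      n_messages = sum(vapply(d$conversations, function(cv)
        nrow(cv$messages), integer(1))),
      timespan_days = as.numeric(difftime(max(ts), min(ts), units = "days")),
      stringsAsFactors = FALSE
    )
  }))

  rng <- function(x) sprintf("%s-%s", format(min(x), trim = TRUE),
                             format(max(x), trim = TRUE))
  per_platform <- do.call(rbind, lapply(split(don_stats, don_stats$platform),
                                        function(g) {
    pf <- g$platform[1]
    ch <- chats[chats$platform == pf, ]
    ia <- ch[ch$interactive %in% TRUE, ]
    data.frame(
      platform = pf,
      n_donations = nrow(g),
      n_chats = sum(g$n_chats),
      pct_group_chats = 100 * mean(ch$is_group),
      n_interactive_chats = nrow(ia),
      pct_group_interactive = if (nrow(ia)) 100 * mean(ia$is_group) else NA_real_,
      chats_per_person_median = stats::median(g$n_chats),
      chats_per_person_mean = mean(g$n_chats),
      chats_per_person_sd = stats::sd(g$n_chats),
      chats_per_person_range = rng(g$n_chats),
      group_chats_per_person_median = stats::median(g$n_group),
      group_chats_per_person_mean = mean(g$n_group),
      group_chats_per_person_sd = stats::sd(g$n_group),
      group_chats_per_person_range = rng(g$n_group),
      timespan_days_median = stats::median(g$timespan_days),
      timespan_days_sd = stats::sd(g$timespan_days),
      timespan_days_range = rng(round(g$timespan_days)),
      message_count_median = stats::median(g$n_messages),
      message_count_sd = stats::sd(g$n_messages),
      message_count_range = rng(g$n_messages),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_platform) <- NULL

  eligible_b1 <- chats$b1[!is.na(chats$b1)]
  pooled <- list(
    median_bias = stats::median(parts$median_bias, na.rm = TRUE),
    median_gini = stats::median(parts$gini, na.rm = TRUE),
    median_b1 = if (length(eligible_b1)) stats::median(eligible_b1) else NA_real_,
    share_positive_b1 = if (length(eligible_b1))
      mean(eligible_b1 > 0) else NA_real_,
    n_eligible_chats = length(eligible_b1)
  )
  list(per_platform = per_platform, per_participant = parts,
       per_chat = chats, pooled = pooled)
}

#' Gini under contact resampling
#'
#' Emulates restricted donations: from a full contact-weight vector, sample
#' either `n` random contacts or the top `n` contacts by word count, and
#' compute the Gini index of each sub-network.  Top-`n` selection is
#' deterministic, so it uses a single replicate.
#'
#' @param weights Full per-contact donor word totals.
#' @param n Sub-network size, `1 <= n <= length(weights)`.
#' @param mode `"random"` or `"top"`.
#' @param reps Number of replicates for random mode (default 200).
#' @param seed Seed for random mode.
#' @return Numeric vector of Gini values (length `reps`, or 1 for top mode).
#' @export
resample_gini <- function(weights, n, mode = c("random", "top"),
                          reps = 200L, seed = 1L) {
  mode <- match.arg(mode)
  k <- length(weights)
  if (n < 1 || n > k) {
    cm_error("sub-network size out of range", "chatmetrics_invalid_sample")
  }
  stopifnot(reps >= 1)
  if (mode == "top") {
    return(gini_index(sort(weights, decreasing = TRUE)[seq_len(n)]))
  }
  with_seed(seed, vapply(seq_len(reps), function(i)
    gini_index(sample(weights, n)), numeric(1)))
}

#' Contact-resampling analysis over a grid of sizes
#'
#' Runs [resample_gini()] for each size in `grid` in both modes and returns
#' a tidy table of means (random mode averaged over `reps` replicates).
#'
#' @param weights Full per-contact donor word totals.
#' @param grid Sub-network sizes (defaults to `c(3, 5, 7, 10, 15, 20)`,
#'   clipped to the network size).
#' @param reps Replicates for random mode.
#' @param seed Seed.
#' @return Data frame with columns `n`, `mode`, `mean_gini`, `reps`, `seed`.
#' @export
resampling_analysis <- function(weights, grid = c(3L, 5L, 7L, 10L, 15L, 20L),
                                reps = 200L, seed = 1L) {
  grid <- grid[grid <= length(weights)]
  rows <- lapply(grid, function(n) {
    rand <- resample_gini(weights, n, "random", reps = reps, seed = seed + n)
    top <- resample_gini(weights, n, "top")
    data.frame(
      n = c(n, n), mode = c("random", "top"),
      mean_gini = c(mean(rand), top),
      reps = c(reps, 1L), seed = c(seed + n, NA_integer_),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
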