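# Fixture builders used across the suite.  Everything is constructed in
# code; no stored data files.

# A minimized conversation built directly from per-message vectors.
min_conv <- function(sender_id, word_count,
                     timestamp = NULL, id = "conv01",
                     platform = "whatsapp", is_group = NULL,
                     voice_duration_s = NULL, is_media = NULL) {
  n <- length(sender_id)
  if (is.null(timestamp)) {
    timestamp <- as.POSIXct("2022-01-01 10:00:00", tz = "UTC") +
      seq_len(n) * 3600
  }
  msgs <- data.frame(
    sender_id = sender_id,
    timestamp = timestamp,
    word_count = as.integer(word_count),
    voice_duration_s = if (is.null(voice_duration_s)) NA_real_
                       else voice_duration_s,
    is_media = if (is.null(is_media)) word_count == 0 else is_media,
    stringsAsFactors = FALSE
  )
  msgs <- msgs[order(msgs$timestamp), ]
  rownames(msgs) <- NULL
  ids <- sort(unique(sender_id))
  structure(
    list(conversation_id = id, platform = platform,
         is_group = if (is.null(is_group)) length(ids) > 2 else is_group,
         participant_ids = ids, messages = msgs),
    class = "minimized_conversation"
  )
}

# A donation assembled from minimized conversations.
min_donation <- function(convs, donor_id = "donor0000001",
                         platform = NULL, external_donor_id = NULL) {
  structure(
    list(donor_id = donor_id, external_donor_id = external_donor_id,
         platform = platform %||% convs[[1]]$platform,
         donation_timestamp = as.POSIXct("2023-06-01 12:00:00", tz = "UTC"),
         conversations = convs),
    class = "donation"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A dyadic chat with exact word totals for donor and contact, one message
# per side per day, used for hand-computable metric fixtures.
tally_conv <- function(w_donor, w_contact, donor_id = "donor0000001",
                       contact_id = "contact00001", id = "conv01",
                       n_days = 2L) {
  # spread the totals over 2 messages (one each); metrics only see totals
  min_conv(
    sender_id = c(donor_id, contact_id),
    word_count = c(w_donor, w_contact),
    timestamp = as.POSIXct("2022-01-01 09:00:00", tz = "UTC") +
      c(0, 86400 * (n_days - 1L)),
    id = id
  )
}

# Mojibake a string the way Meta archives do (UTF-8 bytes read as Latin-1).
mojibake <- function(s) chatmetrics:::mojibake_encode(s)

# Tiny deterministic simulation presets to keep the suite fast.
tiny_chat_params <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    n_interaction_days = 6L, day_gap = gap_fixed(2),
    messages_per_day = 2L,
    words_per_message = list(kind = "lognormal", meanlog = 1.2, sdlog = 0.5),
    media_rate = 0.1, balance = 0.5, seed = seed
  )
  defaults[names(args)] <- args
  do.call(chat_sim_params, defaults)
}
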