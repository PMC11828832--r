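test_that("count_words matches a token-run oracle", {
  expect_identical(count_words(c("hello world", "", "a  b\tc\nd")),
                   c(2L, 0L, 4L))
  # oracle: number of non-space runs found independently
  set.seed(7)
  vocab <- c("ab", "cde", "f", "längere", "слово")
  for (i in 1:25) {
    words <- sample(vocab, sample(0:8, 1), replace = TRUE)
    gaps <- sample(c(" ", "  ", "\t", "\n"), length(words), replace = TRUE)
    s <- paste0(paste0(words, gaps[seq_along(words)]), collapse = "")
    oracle <- length(regmatches(s, gregexpr("[^[:space:]]+", s))[[1]])
    expect_equal(count_words(s), oracle, info = s)
  }
  # counting happens after mojibake repair: one word stays one word
  expect_equal(count_words(mojibake("Grüße aus Köln")), 3L)
})

test_that("pseudonym map links the donor across chats and nothing else", {
  mk <- function(names) {
    msgs <- data.frame(
      timestamp = as.POSIXct("2022-01-01 10:00", tz = "UTC") +
        seq_along(names) * 60,
      sender_name = names, content = "x", kind = "text",
      voice_duration_s = NA_real_, stringsAsFactors = FALSE)
    raw_conversation("whatsapp", "t", msgs)
  }
  donor <- donor_profile("Alice")
  convs <- list(mk(c("Alice", "Bob")), mk(c("Alice", "Carol")))
  pm <- build_pseudonym_map(donor, convs, seed = 5)
  expect_equal(unname(pm$map[["Alice"]]), pm$donor_id)
  expect_false(pm$map[["Bob"]] == pm$map[["Carol"]])
  expect_equal(anyDuplicated(pm$map), 0L)
  # IDs are opaque: no display name appears inside any ID
  expect_false(any(vapply(c("Alice", "Bob", "Carol"), function(nm)
    any(grepl(tolower(nm), pm$map, fixed = TRUE)), logical(1))))
  expect_match(pm$map, "^[0-9a-f]{12}$")

  # determinism under the seed
  pm2 <- build_pseudonym_map(donor, convs, seed = 5)
  expect_identical(pm, pm2)
  pm3 <- build_pseudonym_map(donor, convs, seed = 6)
  expect_false(identical(pm$map, pm3$map))

  # donor aliases share one ID
  pma <- build_pseudonym_map(donor_profile(c("Alice", "Alice Smith")),
                             list(mk(c("Alice", "Bob")),
                                  mk(c("Alice Smith", "Bob"))), seed = 1)
  expect_equal(unname(pma$map[["Alice"]]), unname(pma$map[["Alice Smith"]]))

  expect_warning(build_pseudonym_map(donor_profile("Nobody"), convs, 1),
                 class = "chatmetrics_donor_absent")
})

test_that("minimize drops system messages, keeps timing of media, counts words", {
  msgs <- data.frame(
    timestamp = as.POSIXct("2022-01-01 10:00", tz = "UTC") + (1:5) * 60,
    sender_name = c("", "Alice", "Bob", "Alice", "Bob"),
    content = c("subject changed", "one two three", "just one four five",
                "", ""),
    kind = c("system", "text", "text", "media", "voice"),
    voice_duration_s = c(NA, NA, NA, NA, 12),
    stringsAsFactors = FALSE)
  conv <- raw_conversation("facebook", "t", msgs)
  pm <- build_pseudonym_map(donor_profile("Alice"), list(conv), 3)
  mc <- minimize_conversation(conv, pm, "conv-a")

  # |minimized| = |raw| - |system|
  expect_equal(nrow(mc$messages), 4L)
  # per-sender word sums survive minimization
  alice <- pm$map[["Alice"]]; bob <- pm$map[["Bob"]]
  sums <- tapply(mc$messages$word_count, mc$messages$sender_id, sum)
  expect_equal(unname(sums[alice]), 3)
  expect_equal(unname(sums[bob]), 4)
  # voice metadata: word count 0, duration preserved
  v <- mc$messages[mc$messages$is_media & !is.na(mc$messages$voice_duration_s), ]
  expect_equal(v$word_count, 0L)
  expect_equal(v$voice_duration_s, 12)
  # the only text-typed payload is the opaque ID
  expect_named(mc$messages, c("sender_id", "timestamp", "word_count",
                              "voice_duration_s", "is_media"))

  pm_bad <- build_pseudonym_map(donor_profile("Alice"),
                                list(raw_conversation("whatsapp", "o",
                                                      msgs[2, ])), 1)
  expect_error(minimize_conversation(conv, pm_bad, "x"),
               class = "chatmetrics_unmapped_sender")
})

test_that("restrict_period filters by calendar date and drops empty chats", {
  c1 <- min_conv(c("a", "b", "a"), c(3, 4, 5),
                 timestamp = as.POSIXct(c("2019-05-01 10:00",
                                          "2022-06-01 10:00",
                                          "2023-01-01 10:00"), tz = "UTC"))
  c2 <- min_conv(c("a", "c"), c(1, 2),
                 timestamp = as.POSIXct(c("2019-01-01 10:00",
                                          "2019-02-01 10:00"), tz = "UTC"),
                 id = "conv02")
  d <- min_donation(list(c1, c2), donor_id = "a")

  r <- restrict_period(d, "2022-01-01", "2022-12-31")
  expect_length(r$conversations, 1L)
  expect_equal(nrow(r$conversations[[1]]$messages), 1L)

  full <- restrict_period(d, "2018-01-01", "2024-01-01")
  expect_equal(vapply(full$conversations, function(cv) nrow(cv$messages), 1L),
               c(3L, 2L))

  none <- restrict_period(d, "2020-01-01", "2020-12-31")
  expect_length(none$conversations, 0L)

  expect_error(restrict_period(d, "2022-01-01", "2021-01-01"),
               class = "chatmetrics_invalid_range")
})

test_that("audit_no_leakage flags planted sentinels and passes clean donations", {
  d <- min_donation(list(min_conv(c("aaa111", "bbb222"), c(2, 3))),
                    donor_id = "aaa111")
  sent <- c("Alice", "Bob", "secretword")
  expect_equal(nrow(audit_no_leakage(d, sent)), 0L)

  d_bad <- d
  d_bad$conversations[[1]]$conversation_id <- "chat-with-Alice"
  rep <- audit_no_leakage(d_bad, sent)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$field, "conversation_id")
  expect_equal(rep$sentinel, "Alice")

  # a raw-style leak in a message field is caught per field
  d_bad2 <- d
  d_bad2$conversations[[1]]$messages$sender_id[1] <- "Bob"
  expect_gt(nrow(audit_no_leakage(d_bad2, sent)), 0L)
})

test_that("JSON round trip is lossless at the metadata level", {
  p <- tiny_chat_params(11, voice_rate = 0.1)
  sim <- simulate_donation(network_sim_params(k = 3, chat = p, seed = 2))
  d <- build_donation(sim$profile, sim$conversations, platform = "facebook",
                      external_donor_id = "EXT-42", seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_donation_json(d, f)
  d2 <- read_donation_json(f)
  expect_equal(d2$donor_id, d$donor_id)
  expect_equal(d2$external_donor_id, "EXT-42")
  s1 <- summarize_donations(list(d), min_days = 3)
  s2 <- summarize_donations(list(d2), min_days = 3)
  expect_equal(s2$pooled, s1$pooled)
  expect_equal(s2$per_chat$max_share, s1$per_chat$max_share)
  # and re-serializing the reloaded donation is byte-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_donation_json(d2, f2)
  expect_identical(readLines(f2, warn = FALSE), readLines(f, warn = FALSE))
})

test_that("CSV export mirrors the relational schema", {
  d <- min_donation(list(min_conv(c("a", "b"), c(2, 3)),
                         min_conv(c("a", "c"), c(1, 4), id = "conv02")),
                    donor_id = "a", external_donor_id = "EXT-1")
  dir <- withr::local_tempdir()
  write_donation_csv(d, dir)
  convs <- read.csv(file.path(dir, "conversations.csv"))
  msgs <- read.csv(file.path(dir, "messages.csv"))
  expect_equal(nrow(convs), 2L)
  expect_equal(nrow(msgs), 4L)
  expect_true(all(c("donor_id", "external_donor_id", "conversation_id",
                    "platform", "is_group") %in% names(convs)))
  expect_true(all(c("conversation_id", "sender_id", "datetime",
                    "word_count", "voice_duration_s", "is_media")
                  %in% names(msgs)))
})
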