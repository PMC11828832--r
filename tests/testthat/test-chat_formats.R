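test_that("dialect detection identifies the header grammar", {
  d <- detect_whatsapp_dialect("15.03.22, 14:32 - Alice: hi")
  expect_equal(d$bracket_style, "plain-dash")
  expect_equal(d$date_order, "dmy")
  expect_false(d$hour12)
  expect_false(d$seconds)
  expect_equal(d$year_digits, 2L)

  d2 <- detect_whatsapp_dialect("[3/15/22, 2:32:10 PM] Alice: hi")
  expect_equal(d2$bracket_style, "bracketed")
  expect_equal(d2$date_order, "mdy")
  expect_true(d2$hour12)
  expect_true(d2$seconds)

  expect_error(detect_whatsapp_dialect(c("random prose", "no headers")),
               class = "chatmetrics_no_dialect")
})

test_that("dialect detection resolves day/month ambiguity toward DMY and 24h", {
  # 03.04.22 parses under both orders; the tie must go to DMY
  d <- detect_whatsapp_dialect("03.04.22, 09:15 - Alice: hi")
  expect_equal(d$date_order, "dmy")
  # a day > 12 later in the file disambiguates toward MDY
  d2 <- detect_whatsapp_dialect(c("3/4/22, 9:15 - Alice: hi",
                                  "4/25/22, 9:16 - Alice: again"))
  expect_equal(d2$date_order, "mdy")
})

test_that("every candidate dialect round-trips its own header format", {
  ts <- as.POSIXct("2022-03-15 14:32:10", tz = "UTC")
  for (d in chatmetrics:::candidate_dialects()) {
    prefix <- chatmetrics:::format_whatsapp_timestamp(ts, d)
    line <- if (d$bracket_style == "bracketed") {
      paste0("[", prefix, "] Alice: hi")
    } else {
      paste0(prefix, " - Alice: hi")
    }
    h <- chatmetrics:::match_header(line, d)
    expect_false(is.null(h), info = format(d))
    want <- if (d$seconds) ts else as.POSIXct("2022-03-15 14:32:00", "UTC")
    expect_equal(h$timestamp, want, info = format(d))
    expect_equal(h$rest, "Alice: hi")
  }
})

test_that("dialect detection is stable under extra non-header lines", {
  headers <- sprintf("15.03.22, 14:%02d - Alice: msg", 1:5)
  prose <- c("just a continuation", "another one", "and more")
  set.seed(1)
  for (i in 1:5) {
    lines <- sample(c(headers, prose))
    d <- detect_whatsapp_dialect(lines)
    expect_equal(d$bracket_style, "plain-dash")
    expect_equal(d$date_order, "dmy")
    expect_false(d$hour12)
  }
})

test_that("parse_whatsapp builds messages, continuations, media and system", {
  conv <- parse_whatsapp(paste(
    "15.03.22, 14:32 - Alice: hello world",
    "15.03.22, 14:33 - Bob: hey", sep = "\n"))
  expect_s3_class(conv, "raw_conversation")
  expect_equal(nrow(conv$messages), 2L)
  expect_setequal(conv$participants, c("Alice", "Bob"))
  expect_equal(conv$platform, "whatsapp")
  expect_false(conv$is_group)

  multi <- parse_whatsapp("15.03.22, 14:32 - Alice: line one\ncontinued line")
  expect_equal(nrow(multi$messages), 1L)
  expect_equal(multi$messages$content, "line one\ncontinued line")

  media <- parse_whatsapp("15.03.22, 14:32 - Alice: <Media omitted>")
  expect_equal(media$messages$kind, "media")
  expect_equal(media$messages$content, "")

  sys <- parse_whatsapp(paste(
    "15.03.22, 14:30 - Messages and calls are end-to-end encrypted.",
    "15.03.22, 14:32 - Alice: hi", sep = "\n"))
  expect_equal(sys$messages$kind, c("system", "text"))
  expect_equal(sys$messages$sender_name[1], "")
  expect_setequal(sys$participants, "Alice")
})

test_that("parse_whatsapp discards preambles and malformed timestamps with warnings", {
  expect_warning(
    conv <- parse_whatsapp(paste(
      "export preamble line",
      "15.03.22, 14:32 - Alice: hi", sep = "\n")),
    class = "chatmetrics_preamble_dropped")
  expect_equal(nrow(conv$messages), 1L)

  # 31.02 is structurally a header but not a real date: skipped, and its
  # continuation line must not leak into the previous message
  expect_warning(expect_warning(
    conv2 <- parse_whatsapp(paste(
      "15.03.22, 14:32 - Alice: ok",
      "31.02.22, 14:40 - Bob: broken",
      "dangling continuation",
      "16.03.22, 09:00 - Alice: fine", sep = "\n")),
    class = "chatmetrics_malformed_timestamp"),
    class = "chatmetrics_preamble_dropped")
  expect_equal(nrow(conv2$messages), 2L)
  expect_equal(conv2$messages$content, c("ok", "fine"))
})

test_that("messages are time-sorted and group flag follows participant count", {
  conv <- parse_whatsapp(paste(
    "15.03.22, 14:35 - Carol: late header first",
    "15.03.22, 14:31 - Alice: early",
    "15.03.22, 14:33 - Bob: middle", sep = "\n"))
  expect_true(!is.unsorted(conv$messages$timestamp))
  expect_true(conv$is_group)
})

test_that("repair_text_encoding fixes mojibake and is idempotent", {
  # oracle: encode as Latin-1 code points, decode as UTF-8
  orig <- c("Grüße", "Привіт", "Բարեւ", "naïve café", "hello")
  for (s in orig) {
    bad <- mojibake(s)
    expect_equal(repair_text_encoding(bad), s)
    expect_equal(repair_text_encoding(s), s)
  }
  # doubly mis-decoded text still lands on the original
  expect_equal(repair_text_encoding(mojibake(mojibake("Grüße"))), "Grüße")
  # idempotence on arbitrary strings
  set.seed(42)
  rand <- vapply(1:30, function(i)
    intToUtf8(sample(c(32:126, 192:255, 1040:1103), sample(3:12, 1),
                     replace = TRUE)), character(1))
  once <- repair_text_encoding(rand)
  expect_equal(repair_text_encoding(once), once)
})

test_that("parse_whatsapp accepts files and zips", {
  txt <- "15.03.22, 14:32 - Alice: hello\n15.03.22, 14:33 - Bob: hi"
  f <- file.path(tempdir(), "Chat with Bob.txt")
  writeLines(txt, f)
  conv <- parse_whatsapp(f)
  expect_equal(nrow(conv$messages), 2L)
  expect_equal(conv$thread_name, "Chat with Bob")

  skip_if_not_installed("zip")
  zf <- file.path(tempdir(), "chat.zip")
  zip::zip(zf, files = basename(f), root = dirname(f), mode = "cherry-pick")
  conv2 <- parse_whatsapp(zf)
  expect_equal(conv2$messages$content, conv$messages$content)
})

test_that("meta archives merge thread parts and recover voice durations", {
  root <- withr::local_tempdir()
  tdir <- file.path(root, "messages", "inbox", "thread_a")
  dir.create(tdir, recursive = TRUE)
  ts0 <- 1647352320  # 2022-03-15 14:32:00 UTC
  part <- function(msgs) list(
    participants = list(list(name = "Donor X"), list(name = "Friend Y")),
    messages = msgs, title = "Friend Y", thread_path = "inbox/thread_a")
  jsonlite::write_json(part(list(
    list(sender_name = "Friend Y", timestamp_ms = (ts0 + 120) * 1000,
         content = "later part one"),
    list(sender_name = "Donor X", timestamp_ms = (ts0 + 60) * 1000,
         audio_files = list(list(uri = "audio/a.aac", duration_seconds = 12)))
  )), file.path(tdir, "message_1.json"), auto_unbox = TRUE)
  jsonlite::write_json(part(list(
    list(sender_name = "Donor X", timestamp_ms = ts0 * 1000,
         content = "first message")
  )), file.path(tdir, "message_2.json"), auto_unbox = TRUE)

  arch <- parse_meta_archive(root, "facebook")
  expect_length(arch$conversations, 1L)
  m <- arch$conversations[[1]]$messages
  expect_equal(nrow(m), 3L)
  expect_true(!is.unsorted(m$timestamp))
  expect_equal(m$kind, c("text", "voice", "text"))
  expect_equal(m$voice_duration_s[2], 12)
  # no profile file: donor inferred as the most widespread sender
  expect_s3_class(arch$profile, "donor_profile")
})

test_that("meta archives without an inbox raise EmptyArchive", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "posts"), recursive = TRUE)
  jsonlite::write_json(list(posts = list()),
                       file.path(root, "posts", "your_posts_1.json"))
  expect_error(parse_meta_archive(root), class = "chatmetrics_empty_archive")
})

test_that("malformed threads are skipped with a warning, good ones kept", {
  root <- withr::local_tempdir()
  good <- file.path(root, "messages", "inbox", "ok")
  bad <- file.path(root, "messages", "inbox", "broken")
  dir.create(good, recursive = TRUE); dir.create(bad, recursive = TRUE)
  jsonlite::write_json(
    list(participants = list(list(name = "A"), list(name = "B")),
         messages = list(list(sender_name = "A",
                              timestamp_ms = 1647352320000,
                              content = "hi")),
         title = "B"),
    file.path(good, "message_1.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(not_a_thread = TRUE),
                       file.path(bad, "message_1.json"), auto_unbox = TRUE)
  expect_warning(arch <- parse_meta_archive(root),
                 class = "chatmetrics_malformed_thread")
  expect_length(arch$conversations, 1L)
})
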