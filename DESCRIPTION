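Package: chatmetrics
Title: Privacy-Preserving Minimization and Analysis of Messaging-Data Donations
Version: 0.1.0
Authors@R:
    person("chatmetrics", "developers", email = "chatmetrics@example.org",
           role = c("aut", "cre"))
Description: Parses WhatsApp plain-text chat exports (multiple locale
    dialects) and Facebook/Instagram "Download Your Information" JSON
    archives, reduces them to fully de-identified metadata (pseudonymous
    sender IDs, timestamps, word counts, voice-message durations), and
    computes social-interaction statistics on the minimized data: an
    interactivity filter, directed interaction bias, Gini-index interaction
    heterogeneity across contacts, and inter-event burstiness.  Includes a
    synthetic chat generator with controllable balance, heterogeneity and
    burstiness for end-to-end round-trip and privacy-leakage testing, donor
    feedback summaries (intensity over time, active hours, response times)
    with a small-cell suppression rule, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    zip
Config/testthat/edition: 3
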