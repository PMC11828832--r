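---
title: "chatmetrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chatmetrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatmetrics)
```

## The model: metadata-only measurement of social interaction

`chatmetrics` operationalizes a simple but strong claim: the *metadata* of
private messaging — who (pseudonymously), when, and how many words — is
sufficient to measure core structural features of a person's social
interactions, while the content, the names, and anything linkable can be
destroyed before a donation ever leaves the participant's side.

The pipeline has a single trust boundary. Everything upstream of
`minimize_conversation()` (`raw_conversation`, display names, text) exists
only in memory and is never serialized or logged; everything downstream is
the *donation*: per message a pseudonymous `sender_id`, a timestamp, a
word count, an `is_media` flag, and (Meta only) a voice duration in
seconds. Within one donation all of the donor's aliases map to one ID —
the donor is the only party linkable across their own chats — while each
chat partner receives an independent random ID, so no cross-donation
partner linkage is even representable.

Because "no leakage" is a falsifiable claim rather than a hope, the
synthetic generator draws every name and content token from a closed
sentinel vocabulary, and `audit_no_leakage()` greps every serialized field
of a donation for every sentinel. On generated data this audit is
*complete*: a single surviving token anywhere fails the build.

## The interaction statistics and their assumptions

**Interactivity filter.** A chat is interactive when no partner
contributed more than 90% of its words; the comparison is strict, so a
share of exactly 0.9 passes. The filter assumes word count is a fair proxy
for conversational participation; media-only chats carry no words and are
excluded from word-based metrics entirely (classed error
`chatmetrics_empty_chat`).

**Interaction bias.** `b = 0.5 − w_ij/(w_ij + w_ji)` for a dyad. The
statistic is antisymmetric under role swap and bounded in `[−0.5, 0.5]`,
with the endpoints attained only by one-sided tallies. Group chats pass
through the interactivity filter like dyads (max per-partner share) but
are excluded from bias, which is intrinsically pairwise. A donor's summary
bias is the *median* over their interactive dyadic chats.

**Heterogeneity.** The Gini index of donor-*sent* word totals across
contacts, in its rank form on the ascending-sorted vector. Received words
deliberately play no role: heterogeneity here means how the donor
allocates their own attention. The rank form is algebraically identical to
the mean-absolute-pairwise-difference Gini, which the test suite exploits
as an independent oracle (exhaustively for all integer 3-vectors with
total ≤ 12). Note the attainable maximum is `(k−1)/k`, not 1, so values
from small networks are structurally compressed — this is exactly the
size effect the resampling analysis quantifies.

**Burstiness.** Interactions are counted at *day* resolution: an
interaction day is a calendar day with at least one message from either
side, media included. Inter-event times are the gaps (in whole days,
≥ 1) between consecutive interaction days; chats need at least ten
interaction days to be eligible. With `r = σ/μ`,
`B1 = (r − 1)/(r + 1)`. σ is the *population* standard deviation
(divide by n): under the sample convention a perfectly regular series
would not reach the defining anchor `B1 = −1` exactly, and the metric's
originating literature uses the population form. Day-level resolution
(rather than per-message inter-event times) follows from the eligibility
rule being stated in interaction days; per-message analysis would mix
within-conversation response dynamics into a statistic meant to describe
the long-run rhythm of a relationship.

**Feedback.** Three panels computed purely from the minimized donation:
word-count intensity per calendar month (weekly optional), an hour-of-day
histogram of donor-sent messages, and donor response latencies. The
response-time definition — nowhere standardized — is: for each donor
message directly preceded in its chat by a contact message, the time since
the latest such contact message; consecutive donor messages contribute
once; latencies above a 7-day cap (configurable) are treated as
conversation restarts, not responses, and zero latencies are dropped. The
privacy rule on the received side is small-cell suppression: any time bin
with fewer than two distinct active contacts shows no received-word
information at all (threshold configurable upward).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| interactivity threshold | 0.9 | word share | strict "more than 90%" rule |
| burstiness eligibility `min_days` | 10 | interaction days | stability of σ/μ on short series |
| response-time cap | 604 800 (7 d) | seconds | separates replies from restarts |
| feedback bin | month | — | donations span years |
| suppression threshold | 2 | distinct contacts | minimal aggregation rule |
| resampling grid | 3, 5, 7, 10, 15, 20 | contacts | spans restricted-export sizes |
| resampling reps | 200 | replicates | MC error ≪ the effects measured |
| pseudonym width | 12 | hex digits | collision-free at donation scale |

## The synthetic world

`simulate_conversation()` generates exactly what the metrics measure, and
nothing more:

* **Timing** — messages fall on `n_interaction_days` distinct days whose
  gaps follow one of three laws chosen to span the burstiness range:
  `gap_fixed(g)` (σ = 0, hence B1 = −1 exactly), `gap_geometric(p)`
  (memoryless days; CV = √(1−p), so B1 → 0 as p → 0), and
  `gap_pareto(α, xmin)` (heavy tails; B1 > 0). The geometric default
  p = 0.2 (mean gap 5 days) keeps the theoretical B1 at ≈ −0.056,
  within the ±0.1 band expected of a "random-timing" fixture, and reads
  as a realistic cadence for a close contact.
* **Balance** — each message's sender is the donor with probability
  `balance`, independent of the word law, so the expected donor word
  share equals `balance` and downstream bias ≈ `0.5 − balance`.
* **Intensity** — words per message are rounded lognormal (default
  meanlog 1.6, sdlog 0.7: median ≈ 5 words, occasional long messages),
  minimum 1; a `media_rate` fraction of messages are media placeholders
  and a `voice_rate` fraction voice messages (Meta renders them as audio
  attachments with durations; WhatsApp cannot, mirroring the platforms).
* **Network** — `simulate_donation()` builds `k` dyadic chats. The
  `equal` weight law forces deterministic, identical word totals (so the
  downstream Gini is exactly 0, not approximately); `lognormal` scales
  each chat's message rate by a lognormal weight; `single_dominant`
  silences the donor in all chats but one (Gini exactly `(k−1)/k`).
* Within a day, message times are distinct whole minutes, so every
  supported WhatsApp dialect — with or without seconds — round-trips
  timestamps exactly.

What the generator does **not** emulate: real conversational turn-taking
(senders are i.i.d., so response-time distributions are structureless),
circadian rhythm (times are uniform over the day), content semantics
(tokens are sentinel filler by design), reactions/edits/deletions, and
group-chat dynamics beyond the participant count. A green round-trip or
parameter-recovery test therefore establishes the *pipeline's*
correctness — parsing, minimization, metric algebra — not the realism of
any behavioral model.

One empirical caveat surfaced while validating the heavy-tail anchor: for
Pareto gaps with α = 1.5 the sampling distribution of the CV approaches
its asymptotic regime slowly, and the "B1 > 0 in ≥ 95% of replicates"
recovery property holds at series lengths around 1000 interaction days but
genuinely fails at 50–100. The acceptance test uses 1000-day series (the
same scale the geometric recovery clause states); heavier tails at short
observation windows are under-detected, which is a property of the
statistic, not of the implementation.

## Numerical and parsing choices

* **Dialect detection** scans a 16-cell grammar grid ({plain-dash,
  bracketed} × {DMY, MDY} × {12h, 24h} × {seconds, none}, with year width
  and separator inferred from the data) and picks the dialect parsing the
  most header lines with valid calendar dates. Ties — typically files in
  which every day-of-month is ≤ 12, which no detector can disambiguate —
  go to DMY, then 24h, the common combination in the platform's locales.
* **Two-digit years** pivot at 70 (00–69 → 2000s, 70–99 → 1900s);
  messaging predates 1970 never.
* **Malformed headers** (structurally valid, impossible date) are skipped
  with a warning, together with their continuation lines; lines before
  the first valid header (export preambles, encryption notices) are
  dropped with a warning.
* **Mojibake repair** re-decodes Latin-1-mis-read UTF-8 byte sequences,
  iterated to a fixed point (≤ 4 rounds) so doubly mis-encoded input also
  lands correctly and the function is idempotent; strings that are not
  valid UTF-8 after reinterpretation are returned unchanged (best
  effort). Word counting happens after repair, so non-ASCII words count
  as single tokens.
* **Meta timestamps** (epoch milliseconds) are converted without timezone
  shifting, and WhatsApp times are taken as naive local clock readings;
  the export formats simply carry no zone information, and all metrics
  are either zone-invariant or deliberately "local" (active hours).
* **Media handling**: WhatsApp "media omitted" placeholders and Meta
  photo/sticker/share messages are retained with `word_count = 0` and
  flagged `is_media` — they are interactions and carry timing information
  for burstiness and active hours, while contributing nothing to
  word-based metrics. System messages (subject changes, encryption
  notices) are not interactions and are dropped entirely.
* **Pseudonyms** are fixed-width seeded hex tokens, re-drawn wholesale in
  the vanishingly rare event of a duplicate or of a source name occurring
  inside a token; assignment order is alphabetical, so the map is
  independent of conversation order.

## Known limitations

* The WhatsApp dialect inventory is an engineering superset of the
  grammars the platform emits; exotic locales may still fail detection
  (they fail loudly, with `chatmetrics_no_dialect`).
* Voice durations exist only for Meta donations; WhatsApp media are
  timing-only events.
* The deposited-study reproduction path (`read_donation_csv()` after
  column mapping) is exercised only when the external dataset is present;
  the offline test suite states this failure honestly rather than
  skipping it.
* Group chats are summarized (counts, interactivity, burstiness) but
  excluded from bias and from the dyadic balance analysis.
* No emoji, reaction, or sentiment extraction: the minimization contract
  admits counts and times only.
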