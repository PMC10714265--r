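---
title: "Methods: flag definitions, windowed z scores, and the synthetic-paradata world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flag definitions, windowed z scores, and the synthetic-paradata world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`catiqc` implements a quality-control indicator system for telephone surveys
administering long clinical instruments. This vignette is the package's
account of its science: the reconstruction and flagging model, every tunable
parameter, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. From audit events to visits and timelines

The interviewing software logs one event per field action: `ENTER`, `EXIT`,
`VALUE_SET` (and raw `KEYSTROKE`s, which the engine ignores for timing).
Fields are modal — one question is on screen at a time — so reconstruction
uses a **single-open-visit state machine** per case:

* `ENTER` opens a visit; if a visit is still open it is closed at the new
  `ENTER`'s timestamp and marked `synthetic_exit` (the only way a second
  `ENTER` can appear is a lost `EXIT`, e.g. a dropped connection).
* the first later `EXIT` carrying the open question closes it normally; any
  other `EXIT` is an orphan, discarded and counted.
* a visit still open at the end of the log closes at the last event time.

At identical timestamps `EXIT` sorts before `VALUE_SET` before `ENTER`, so an
abutting close/open at one instant resolves deterministically. Dropping
unclosed visits instead would undercount field time exactly where long-pause
behavior hides, which is why they are closed synthetically rather than
discarded. Equivalence with a naive event-walk implementation is asserted on
1,000 random messy logs in the acceptance suite.

Per case the timeline records total survey time (first `ENTER` to last
`EXIT`) and an **adjusted** total in which within-case gaps — spans covered
by no visit — longer than `pause_threshold_seconds` are excised. All
intervals in the package are half-open `[start, end)`, which makes abutting
intervals disjoint and interval sums exact; durations are `end − start`
seconds; timestamps are ISO-8601 with explicit offset, normalized to UTC.

## 2. Flags and their cutoffs

All cutoffs live in `qc_config()`. Published cutoffs are defaults verbatim;
unpublished ones are declared package choices:

| parameter | default | unit | status |
|---|---|---|---|
| `short_question_seconds` | 3 | s | published (questions faster than this by design are excluded via the catalog) |
| `long_question_seconds` | 420 | s | published (the 7-minute break rule; prayer breaks are the canonical benign cause) |
| `stem_visit_cutoff` / `nonstem_visit_cutoff` | 1 / 3 | visits | published |
| `short_field_pct` | 30 | % | published |
| `short_interview_minutes` | LONG 47, SHORT 32 | min | declared: 50 % of the published mean lengths (94 / 64 min) |
| `long_interview_minutes` | LONG 188, SHORT 128 | min | declared: 200 % of the published means |
| `negative_stem_rule` | `"all"` (≥ 10 administered) | — | declared; a fixed count is configurable |
| `treatment_length_minutes` | 30 | min | declared |
| `completes_zscore_cutoff` | +2 | z | declared (see §3) |
| `prevalence_z_cutoff` | 1.5 | \|z\| | published |
| `short_avg_interview_z_cutoff` | −2 | z | published |
| `window_days` | 14 | days | published |
| `min_completes_per_window` | 5 | cases | declared |
| `pause_threshold_seconds` | 420 | s | reuses the 7-minute rule |

Threshold comparisons are **strict** (`<`, `>`), following the cutoffs'
wording ("<3 seconds", ">30%"): boundary values do not flag. Two deliberate
exceptions follow their own quoted operators: the short-average-interview
flag fires at `z ≤ −2`, and the high-completes rule at `z ≥ +2`.

Open points resolved as package decisions:

* **Treatment time** is nowhere defined in the source system; here it is
  total field time in the catalog module labelled `"treatment"`.
* **High negative stems** has no published cutoff. The default flags a
  completed case whose administered stems are *all* negative (with at least
  10 administered) — the signature of steering every diagnostic gateway to
  "no". Note the base rate of this pattern equals one minus the disorder
  prevalence, so in a population with prevalence 0.43 roughly half of honest
  completes show it too; the flag is a signal for investigation, not an
  accusation.
* The **timeout bug** flag is operationalized as an internal consistency
  check (a visit with negative duration or longer than its session span),
  since the production semantics were never documented.

## 3. Windowed z scores and the exposure-adjusted completes rate

Windows are **tumbling**, `window_days` wide, aligned to the study start date
and half-open on dates — "every 2 weeks" reads as a reporting period, and
tumbling windows keep flags non-duplicative. Within each (window, statistic)
pair, interviewers with at least `min_completes_per_window` completed cases
form the standardization population; `z = (x − mean)/sd` with the sample SD.
A z score on one or two interviews is noise, hence the eligibility floor.
When the SD is zero or fewer than two interviewers are eligible, z is
undefined and nothing can flag. Whether the production system standardized
across interviewers or within interviewer over time is unknowable from the
source; cross-interviewer is this package's decision, because falsification
detection is a between-interviewer comparison at heart.

The high-completes flag deliberately never uses raw completes: the fielded
episode in which 85 flags collapsed to 18 once extra working hours were
accounted for shows raw counts mislead. The rate is completes per logged
CALLING hour, standardized across all interviewer-days of the same calendar
day.

A structural caveat the acceptance suite measures rather than hides:
cross-interviewer z scores are *self-normalized*. Among ~18 eligible
interviewers the empirical z values have sample SD 1 by construction, so with
a `|z| > 1.5` trigger some compliant interviewer exceeds the cutoff in a
substantial share of windows no matter how well-behaved the population is.
The detection study's false-positive bound (criterion 4b) is therefore
expected to fail, and is left failing with this analysis rather than
loosened; the fielded system showed the same behavior (prevalence flags fired
regularly and were resolved by investigation, not by tightening the cutoff).

## 4. The synthetic-paradata world

The generator emulates the fielding conditions the source system reports:
two six-hour shifts (09–15, 15–21), a 42-interviewer-style roster scaled to
`n_interviewers` (default 20) over `n_days` (default 30), long/short
instrument versions with target mean adjusted lengths 94 / 64 minutes, and a
per-stem positive probability calibrated so completed-case disorder
prevalence has cross-interviewer mean ≈ 0.43 and SD ≈ 0.11 (the published
values). The between-interviewer spread comes from a log-normal propensity
multiplier (σ = 0.20 on the log scale) combined with binomial sampling noise.

A **visit** is read time plus answer time. Read times are log-normal
(σ = 0.4) around the catalog baseline (≈ 8 s mean, with ~8 % of questions
legitimately under 3 s and excluded from the short flag) times the
archetype's `question_time_scale`. Answer times are log-normal (σ = 0.5)
around a per-question mean solved in closed form so that the expected
long-version total hits its target, times `answer_time_scale`. The split
matters: a speeding interviewer reads fast *and* records the option before
the respondent finishes, so the SPEEDER archetype has read scale 0.3 and
answer scale 0 — which is what makes its visits drop under the 3-second rule
while honest visits (tens of seconds) never do. Other defaults: dispositions
per dial complete 0.08 / partial 0.05 / refusal 0.12 / noncontact 0.70 /
other 0.05 (plausible CATI rates; none were published), 15 expected dials
per interviewer-day, monitoring on 8 % of long calls, a 0.08 base revisit
probability, occasional within-question pauses (log-normal around 5 min,
driving long-question flags) and between-question gaps (around 8 min, driving
pause excision).

Determinism and locality: the catalog and calibration constants derive from a
stream seeded by `(seed, "catalog")`; each interviewer's entire paradata from
`(seed, interviewer_id)`. `inject_archetype()` regenerates exactly one
interviewer, leaving all other rows bit-identical — which is what makes the
detection experiments clean.

What the generator does **not** emulate: real instrument content and skip
logic, respondent-side behavior beyond timing, callbacks and appointment
scheduling, interviewer learning over time, and any correlation between
archetypes and shift assignment. A green detection test therefore
establishes that the *flags* separate the modelled behaviors at realistic
volumes — not that the generator is a behavioral model of interviewers.

## 5. Reporting conventions

Flag-summary percentages are rounded **half-up** at 2 decimals by default.
The source study's published table, however, matches **truncation** toward
zero in every cell (checked against all printed numerator/denominator pairs),
so `flag_summary(..., rounding = "truncate")` exists and is what the
worked-example acceptance test uses; the package default stays half-up as the
conventional choice. One published monitoring ratio (586/9767 printed as
6.01 %) is arithmetically 6.00 % under any rounding; the test asserts the
correct 6.00. The published flag total (11,035) equals the 12 table rows
(11,021) plus the 14 short-average-interview flags reported only in the text;
the fixture reconstructs the total that way.

Case attribution: case-level flags carry their case id; window-level flags
are attributed to the flagged interviewer's completed cases inside the
window, mirroring how the published table reports more flagged cases than
flags for the prevalence row.

Task queue priority (HIGH on any window-level flag or ≥ 10 case flags,
MEDIUM at ≥ 3) is a declared rule set — the production "level of gravity"
was never specified — and is configurable via `qc_config()`.

## 6. Known limitations

* Flags are screening signals with deliberately high sensitivity; several
  (negative stems, prevalence) have high base rates among honest interviewers
  and exist to rank investigation effort, not to classify.
* The engine is batch-oriented; scheduling/cadence is the caller's concern.
* Time-log entries are attributed to their start date; activity blocks
  crossing midnight would be credited to one day (the simulated world has
  none).
* `REPORTED_TIME_DISCREPANCY` counts idle time between dials inside a
  CALLING block as unobserved, so small positive discrepancies are normal;
  the metric is informative in comparison across interviewers, not as an
  absolute.
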