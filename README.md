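# catiqc — quality-control indicators for telephone-survey paradata

Large interviewer-administered surveys fail quietly: an interviewer who reads
questions too fast, steers diagnostic gateway questions to "no" to shorten the
interview, or pads reported working hours corrupts data in ways no single
record reveals. `catiqc` is a batch engine for the paradata such surveys
already produce — keystroke audit trails from the interviewing software, call
detail records, case dispositions, and interviewer activity logs — and turns
them into the quality-control signals a monitoring team acts on. It targets
computer-assisted telephone interviewing (CATI) operations running long
clinical instruments (e.g. psychiatric diagnostic interviews with stem /
follow-up structure), where interviewers work remotely and cannot be observed
directly.

## What it computes

**Field visits and timelines.** Audit events (`ENTER`, `EXIT`, `VALUE_SET`
per question field) are reconstructed into visits with a single-open-visit
state machine (lost exits are closed synthetically, orphan exits counted).
Per case this yields total survey time, an *adjusted* total with within-case
pauses longer than 7 minutes excised, per-module times, and visit counts.

**Case-level flags**, each against a configurable cutoff (strict comparisons):
question field time `< 3 s` (stem and nonstem variants, with a per-question
exclusion list for items that legitimately take under 3 s), field time
`> 420 s`, more than 1 visit to a stem / 3 to a nonstem question, `> 30 %`
short visits within one interview, version-specific short/long interview
length on adjusted minutes, all-negative stem answers, and treatment-section
time.

**Windowed interviewer flags.** Per interviewer and tumbling 14-day window,
the disorder prevalence p̂ᵢ (share of completed cases screening positive) and
mean adjusted interview length are standardized across interviewers,

    zᵢ = (xᵢ − x̄) / s      (sample SD over interviewers with ≥ 5 completes)

and flagged at `|z| > 1.5` (prevalence, both signs) or `z ≤ −2` (short
average interview length). Daily completes per *worked calling hour* are
standardized the same way (`z ≥ +2`), so working extra hours no longer
masquerades as suspicious productivity.

**Verification metrics** (14): monitoring time per case/interviewer with
overlapping monitoring sessions merged, Cisco calling time, dials and
completes per hour (raw and exposure-adjusted), average after-call work time,
the signed discrepancy between logged calling hours and observed activity,
and per-case interview-time measures.

**Reporting**: a flag-summary table (counts, shares of all flags, distinct
cases flagged against completed-case or touched-case denominators),
monitoring-coverage ratios, per-interviewer profiles, and a prioritized
per-interviewer investigation task queue with a minimal OPEN →
ASSIGNED_MONITORING → RESOLVED lifecycle.

**Simulator.** `sim_config()` / `generate_bundle()` produce seeded, fully
consistent synthetic paradata with interviewer archetypes (COMPLIANT,
SPEEDER, FABRICATOR, REVISITER, SLOWPOKE). Each interviewer draws from an
independent RNG stream, so `inject_archetype()` perturbs exactly one
interviewer. See the methods vignette for what the generator does and does
not emulate.

## Worked example

```r
library(catiqc)

sim <- sim_config(n_interviewers = 8, n_days = 14, seed = 19,
                  archetypes = list(I01 = "SPEEDER", I02 = "FABRICATOR"))
bundle <- generate_bundle(sim)
res <- run_qc(bundle, qc_config())

res$summary[, .(flag_type, n_flags, pct_of_total_flags, n_cases_flagged)]
#>                    flag_type n_flags pct_of_total_flags n_cases_flagged
#>  1:           HIGH_COMPLETES       3               0.17              10
#>  2:      HIGH_NEGATIVE_STEMS      74               4.08              74
#>  3:      HIGH_PCT_SHORT_TIME      15               0.83              15
#>  4:       LONG_QUESTION_TIME      16               0.88              15
#>  5:  MULTI_STEM_FIELD_VISITS     146               8.06              99
#>  6:          PREVALENCE_RATE       1               0.06              16
#>  7:      SHORT_AVG_INTERVIEW       1               0.06              15
#>  8:          SHORT_INTERVIEW      15               0.83              15
#>  9:      SHORT_QUESTION_TIME    1370              75.61             175
#> 10: SHORT_STEM_QUESTION_TIME     171               9.44              66

res$flags[level == "INTERVIEWER_WINDOW" & flag_type != "HIGH_COMPLETES",
          .(flag_type, interviewer_id, z = round(observed_value, 2))]
#>              flag_type interviewer_id     z
#> 1:     PREVALENCE_RATE            I02 -2.00
#> 2: SHORT_AVG_INTERVIEW            I01 -2.45
```

The speeder (I01) dominates the short-question flags and is the only
interviewer whose windowed mean interview length reaches `z ≤ −2`; the
fabricator (I02) is caught by the negative prevalence z score: its completed
cases almost never screen positive. `res$tasks` turns this into one
investigation task per flagged interviewer, HIGH priority first;
`write_qc_outputs(res, "reports/", bundle)` exports everything as CSV/JSON.

A command-line wrapper covers the same flow:

```sh
Rscript exec/catiqc simulate --seed 19 --out bundle/
Rscript exec/catiqc run --bundle bundle/ --out reports/
Rscript exec/catiqc validate --bundle bundle/   # exit 0 ok, 2 invalid
```

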