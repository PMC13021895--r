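---
title: "Disproportionality signal detection: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdispro)
```

# The problem

Spontaneous adverse-event reporting systems (FAERS and its peers) have no
exposure denominator, so drug safety screening works on *reporting
disproportionality*: is an event reported more often with a drug than the
rest of the database would predict? The unit of analysis is the cleaned
report, and for each drug–event pair a 2×2 table is formed — `a` cohort
reports with the event, `b` cohort reports without it, `c` background
reports with it, `d` the rest, `N = a+b+c+d`.

This vignette records the models implemented, every convention the field
leaves open and the choice made here, what the synthetic validation does
and does not establish, and the known limitations.

# The four algorithms

**ROR.** `ad/(bc)`, the odds ratio of the table, with the log-symmetric
Woolf interval `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Sensitive, not
specific; undefined below three reports, so it carries the global `a ≥ 3`
applicability gate.

**PRR.** `[a/(a+b)] / [c/(c+d)]`, the ratio of event proportions, with
interval `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`.

**BCPNN.** The information component `IC = log₂(aN/((a+b)(a+c)))`
compares the joint reporting probability with the product of its margins.
Its posterior under Dirichlet (joint) and Beta (margin) priors has the
standard closed form: with `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))`,

- `E(IC) = log₂[(a+γ₁₁)(N+α)(N+β) / ((N+γ)(a+b+α₁)(a+c+β₁))]`
- `V(IC) = (1/ln²2)·[(N−a+γ−γ₁₁)/((a+γ₁₁)(1+N+γ)) +
  (N−(a+b)+α−α₁)/((a+b+α₁)(1+N+α)) + (N−(a+c)+β−β₁)/((a+c+β₁)(1+N+β))]`
- `IC025 = E(IC) − 2·√V(IC)`.

Priors are not standardized across published analyses; the defaults here
are the usual single-drug/single-event choice `γ₁₁ = α₁ = β₁ = 1`,
`α = β = 2`, under which an exactly independent table gives `E(IC) = 0`
(the prior terms cancel: `26·102² = 104·51²` on the uniform 25/25/25/25
table). All five parameters are arguments of `bcpnn_priors()`. The factor
in IC025 is 2 (not 1.96), the convention for this closed form.

**EBGM.** As implemented, the *relative reporting ratio*
`aN/((a+b)(a+c))` — identical to `2^IC`, and the package tests assert that
identity to machine precision — with a log-symmetric interval using the
ROR's standard error, whose lower bound is EBGM05. True MGPS EBGM applies
Gamma–Poisson shrinkage toward the prior mixture; that shrinkage is
deliberately **not** implemented (a non-goal), because the closed-form
ratio is what the joint criterion here consumes and what the
reported thresholds (EBGM05 > 2) are calibrated against. With shrinkage,
small-count estimates would be pulled toward 1 and the criterion would be
slightly more conservative.

**χ².** Pearson's statistic `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` is
computed and reported (with an optional Yates correction flag, the
deviation floored at zero before squaring) but is **not** part of the
signal criterion: the published threshold sets for PRR-style screening
sometimes include `χ² ≥ 4`, sometimes not, and the threshold set
implemented here pairs each point estimate with its interval bound
instead. A degenerate table (any zero margin) reports `χ² = 0`.

**The joint criterion.** A pair is a signal iff `a ≥ 3` and ROR ≥ 2 with
CI lower limit > 1 and PRR ≥ 2 with CI lower limit > 1 and IC025 > 0 and
EBGM05 > 2. Point thresholds are inclusive, interval-bound thresholds
strict; a statistic marked not-applicable fails its criterion. Requiring
all four simultaneously is the analysis's false-positive control; no
multiple-testing adjustment is applied on top of it.

**Zero cells.** `b`, `c` or `d` equal to zero marks the frequentist
statistics not-applicable rather than applying a Haldane/continuity
correction: corrections are another unstandardized convention, and the
minimum-count rule makes the dominant case (`a = 0`) unreachable anyway.

# Cleaning conventions

The cleaning order is deduplicate → remove deleted cases → assemble →
chronology filter.

- **Deduplication** keeps, per CASEID, the record with the latest FDA_DT,
  breaking ties by the largest PRIMARYID compared numerically; a
  non-numeric id falls back to zero-padded string order and is logged.
  The operation is idempotent, and commutes with deleted-case removal
  (both are per-case; the tests check commutation on random fixtures).
- **Chronology.** A report is excluded when a drug start date lies
  strictly *after* the event onset date, evaluated only when both dates
  have full day precision: a partial date (YYYYMM or YYYY) cannot
  demonstrate an inconsistency, so it does not exclude the report here —
  partial dates are instead handled by the time-to-onset statuses.
  "Missing critical date information" is read as a missing or unparseable
  FDA_DT only, since the receipt date is the one field every analysis
  (deduplication, yearly trends) needs; EVENT_DT may be absent for
  non-onset analyses.
- **Cohorts.** A report joins a drug cohort when at least one drug record
  matches the lexicon *and* that record carries the Primary Suspect role.
  Other suspect drugs on the report are tolerated by default (the common
  convention); `strict_single_suspect = TRUE` additionally requires every
  suspect-role record to match. Lexicon matching is exact after
  normalization (case-folding, punctuation → space, whitespace collapse)
  on both DRUGNAME and PROD_AI — never substring, so combination-product
  names do not leak into a monotherapy cohort, and explicit exclusion
  lists veto a match on either field. Which FAERS field published
  analyses match on is typically unstated; matching both, with exact
  normalized equality, is the most auditable choice.

# Counting conventions

The counting unit is the **report**, not the reaction row: FAERS REAC
tables may repeat a PT within a report, and a case either exhibits an
event or it does not. At SOC level a report counts once toward a SOC when
at least one of its PTs maps there; PTs absent from the user-supplied
mapping are tallied (`n_unmapped_pts`) and excluded rather than guessed. A
row-level mode (`row_level = TRUE`) exists solely for sensitivity
analysis, because published PT counts cannot always be identified as one
or the other.

The minimum-count rule (`a ≥ 3`) filters PT-level tables *before*
statistics; no count filter applies at SOC level, where summary tables
conventionally show signal and non-signal rows alike.

The background for every table is **all** non-cohort reports, including
reports of a paired comparator drug. For subgroup analyses both cohort and
background are restricted to the stratum (female cohort vs female
background) — the standard subgroup-disproportionality convention; a flag
(`restrict_background = FALSE`) switches to a full-database background.
The sex strata (F/M/unknown) partition the database, so the stratum tables
sum cell-wise to the global table — an invariant under test. The age cut
is exactly 60 years: age ≥ 60.0 is "elderly", missing or unparseable age
is its own stratum. Ages are normalized to years (decades ×10, months /12,
weeks /52, days /365.25).

# Time-to-onset

Onset is `EVENT_DT − START_DT` in whole days; when several rows carry the
cohort drug, the earliest day-precision start is used. Exclusion statuses
follow a fixed precedence: missing date → event before start → partial or
unparseable date → interval beyond `max_days`. The default `max_days` of
3,650 (ten years) operationalizes "implausible interval suggestive of data
entry error", which published analyses rarely quantify; it is an argument.

Bins follow the conventional 0–7 / 7–28 / 28–60 / ≥60 day labels, which
are ambiguous at their shared endpoints; here the first bin is closed on
both ends (same-day onset is day 0) and later edges are upper-inclusive,
so the bins are exhaustive and mutually exclusive over the nonnegative
integers. Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7, the mainstream default), fixed for
reproducibility and cross-checked against a sort-and-interpolate oracle.

# The synthetic generator

`generate_faers()` emulates the structure the pipeline consumes: one
Primary-Suspect drug per report drawn from a prevalence mixture (leftover
mass split over anonymous background drugs), each PT an independent
Bernoulli with probability `min(1, RR·p₀)`, duplicates as exact clones
with a later FDA_DT and larger PRIMARYID (deterministically exercising
both tie rules), a DELETED table, missing and month-truncated dates,
configurable sex/age margins, and geometric onset intervals (default mean
10 days; median ≈ 7, matching the week-scale onset typical of antibiotic
reactions). Everything is deterministic given the seed; identical configs
produce byte-identical files.

Two modelling notes:

- Reports that draw zero events are redrawn (then, after capped retries,
  forced to one background event), because an empty report is not
  analyzable. This conditioning inflates every event probability by the
  same per-drug factor `1/P(≥1 event)`; with the default PT panel (base
  probabilities summing to ≈ 1.4, so reports carry one to three events as
  real ones do) the factor is close to 1 and nearly identical across
  drugs, leaving disproportionality essentially untouched. Validation
  configs keep total event mass at this realistic level for that reason —
  a sparse panel would make the redraw dominate.
- A planted rate ratio multiplies the *reporting probability*; the
  quantity the ROR estimates is the induced *odds ratio*
  `[p₁/(1−p₁)]/[p₀/(1−p₀)]`, which `truth_table()` computes analytically.
  Recovery and coverage tests compare against that induced value, not RR.

What passing these tests shows: the formulas, filters and counting rules
are implemented correctly, the joint criterion is conservative under a
true null, and planted effects of the stated size are recovered. What
they do not show: robustness to the correlations of real reporting data —
within-report PT clustering, drug co-prescription, masking by competing
signals, reporting waves, country/reporter confounding. The generator is
intentionally an independence model; those biases are out of scope.

# Validation conditions

The acceptance suite fixes its study conditions once:

- *Formula oracle*: 1,000 random tables with `a ∈ [3, 1000]` and the other
  cells up to 10⁶, compared against an independent scalar log-space
  evaluation; maximum relative error < 10⁻¹².
- *Null calibration*: 50,000 reports, one drug at 10% prevalence, 200 null
  PTs with base probabilities 0.4–1.6% (expected cohort counts 20–80);
  the joint flag rate must be ≤ 5% and never exceed the ROR-only rate.
- *Recovery*: RR = 10 on a 1% PT at 10% prevalence and n = 50,000
  (E[a] = 500), flagged in 20/20 seeds; 19 background PTs carry the
  realistic event mass.
- *Coverage*: RR = 5 on a 0.5% PT, n = 100,000, 50 seeds; the 95% ROR
  interval covers the induced odds ratio in ≥ 90% of seeds.
- *Cleaning oracle*: 1,000 random 12-record fixtures with case
  collisions, date ties, deleted cases and partial dates, against a
  brute-force group-sort-filter oracle.

These sizes keep the full test run in single-digit minutes on one CPU
while leaving the binomial noise small relative to the margins being
asserted.

# Known limitations

- EBGM is the unshrunk relative reporting ratio (above); rare-event
  estimates are noisier than MGPS would give.
- The BCPNN interval is the closed-form normal approximation, not
  Monte-Carlo posterior sampling; for very small `a` the approximation is
  rough (the `a ≥ 3` gate limits exposure).
- No probabilistic record linkage: deduplication is exact on CASEID.
- HLT/HLGT MedDRA levels and SMQs are not modelled; only PT and SOC.
- The signal criterion treats the four algorithms as a conjunction; no
  calibration of an overall false-discovery rate is attempted, mirroring
  screening practice.
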