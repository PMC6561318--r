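---
title: "Methods: odds-ratio analysis of pooled memory-biosensor screens"
author: "htmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odds-ratio analysis of pooled memory-biosensor screens}
  %\VignetteEncoding{UTF-8}
---

## The measurement

Engineered biosensor strains couple a candidate trigger promoter to a
bistable memory switch. When the trigger fires, the switch flips to the
memory-on state and stays there; memory-on cells express an antibiotic
resistance marker (and a LacZ reporter for plate assays). A pooled library
of such strains is exposed to a condition of interest — growth in the mouse
gut, with or without chemically induced colitis — and recovered from fecal
samples over a time course. Each recovered sample is processed the same
way:

1. a constitutively memory-on **positive normalization strain (PNS)** is
   spiked in at 1:1,000 relative abundance;
2. the culture is split into two halves, one grown with spectinomycin
   (which only memory-on cells survive) and one without;
3. the trigger regions of both halves are amplified and sequenced, and
   reads are counted per trigger.

For one trigger in one sample pair, with `a` = trigger reads in the
selected half, `b` = PNS reads in the selected half, `c` = trigger reads in
the untreated half and `d` = PNS reads in the untreated half, the statistic
is the odds ratio

    OR = (a / b) / (c / d)

Each trigger is compared only with itself between the two culture halves,
so per-trigger amplification and length biases cancel; both halves are
normalized to the same PNS, so depth differences between cultures cancel.
Under ideal selection (every memory-on cell survives with the same
probability `s`, no memory-off cell escapes), the survival factor `s` is
shared by the trigger's on-cells and the PNS and cancels too, leaving the
OR as a direct estimate of the strain's memory-on fraction. This
cancellation structure is what the package's invariance tests verify
exactly.

## The exact test against a shifted null

Plate calibration of pooled in vitro cultures against per-strain indicator
plating places the on/off boundary at an odds ratio of about 0.02, so the
screen does not test the usual "no association" null. Instead each table is
tested one-tailed against H0: OR = 0.02 versus Ha: OR > 0.02.

Conditional on both margins of the 2x2 table, the count `a` follows
Fisher's noncentral hypergeometric distribution with noncentrality `psi`
equal to the odds ratio:

    P(X = x | psi)  proportional to  C(n1, x) C(N - n1, m1 - x) psi^x

over the support `max(0, m1 + n1 - N) <= x <= min(m1, n1)`, with
`m1 = a + b` (selected-half total), `n1 = a + c` (trigger total) and `N`
the grand total. The p-value is the upper tail `P(X >= a | psi = 0.02)`.
This is the unique conditional exact test that generalizes Fisher's exact
test to a non-unity null: at `psi = 1` it reduces exactly to the classical
one-sided test, which the test suite checks against `stats::fisher.test`
on grids of small tables, and at `psi = 0.02` it is cross-checked against
`stats::fisher.test(or = 0.02)` as an independent implementation of the
same conditional family.

Numerics: all weights are computed as `lchoose` sums in log space and
normalized with a running-max (log-sum-exp) shift, so tables with margins
in the millions of reads neither overflow nor underflow. Odds ratios are
computed in double precision (integer counts at realistic depths overflow
32-bit products). No pseudocounts are used anywhere: `a = 0` gives
`OR = 0` with a p-value near 1; a zero PNS count in either half marks the
whole sample pair as failed (`PNS_FAILURE`) rather than penalizing
individual triggers, because the PNS is a spiked control whose absence
indicates a failed sample, not a trigger state.

## Filters and hit calling

* **Coverage filter.** A trigger is evaluable in a sample pair only with
  at least 5 reads in the untreated half (boundary inclusive). Cells
  failing this are `INSUFFICIENT_COVERAGE` and appear blank in heat maps;
  they are excluded from both numerator and denominator of every fraction.
  The untreated-arm-only wording is implemented as stated, even when the
  selected half is shallow.
* **Gavage filter.** Triggers with fewer than 5 untreated reads in the
  gavage (t = 0) suspension are dropped from the screen unless they
  register strictly more than 20 untreated reads at some later time point.
  The asymmetry (>= 5 inclusive at gavage, > 20 strict rescue) is
  deliberate and unit-tested at the boundaries.
* **Hit.** A cell is positive when `OR >= 0.02` **and** `p < 0.05`. The
  cutoff and the test are applied conjunctively even though the test's
  null already encodes the 0.02 boundary; the redundancy is intentional
  and mirrors how screen figures are scored.
* **Multiple testing.** No correction is applied by default, matching the
  screen's scoring; `evaluate_screen(p_adjust = TRUE)` adds a
  Benjamini-Hochberg column for users who want it.

## Aggregation choices

"Percent positive time points" pools evaluable mouse x time point cells
within a group rather than averaging per-mouse fractions; this matches the
heat-map layout in which every mouse x day cell is one column. Rankings
break ties by mean odds ratio and then trigger id, purely for determinism.

An **in-vivo responder** is a trigger that is off when administered and on
in the gut: every evaluable gavage cell below the 0.02 cutoff, plus at
least one positive post-gavage cell. The wet protocol sequences a single
gavage suspension; the simulator emits one gavage pair per mouse, and the
classifier requires all evaluable gavage cells to be sub-cutoff, which
coincides with the single-suspension rule when only one exists.

The **disease-differential score** is the positive fraction in the treated
(colitis) group minus the positive fraction in the control group, each
pooled over that group's evaluable post-gavage cells; it is antisymmetric
under swapping the group labels, and a trigger responding only under
disease scores near +1.

**ROC calibration** sweeps thresholds over `{-Inf}`, the sorted distinct
odds ratios, and `{+Inf}` with the positive-call convention
`OR >= threshold` (so 0.02 always lies on the sweep), integrates the
trapezoidal AUC, and reports the Youden-optimal threshold alongside, since
"approximately 0.02" leaves the exact selection rule open. The AUC equals
the Mann-Whitney pair-counting statistic, which the tests verify by brute
force and against pROC.

## What the simulator emulates

`simulate_screen()` reproduces the generative structure of the protocol,
not its biochemistry:

* **Library composition.** Per-mouse baseline strain abundances are
  Dirichlet-distributed (concentration 5 by default: uneven but not
  degenerate, as expected for a pooled colony scrape).
* **Gut passage.** Strains drop out per mouse as a cumulative per-day
  Bernoulli process. The default rate of 0.03/day reproduces the observed
  week-scale retention of roughly four strains in five (0.97^7 ~ 0.81);
  observed one-day retention is somewhat lower than this model predicts,
  so the default anchors the week endpoint. Dropout is permanent; there is
  no recolonization.
* **Memory switching** is encoded directly as a per-condition memory-on
  fraction (off before gavage for gut- and disease-responsive triggers; a
  configured fraction afterwards), not as switch kinetics — no rate
  constants are available for the underlying bistable switch, and the
  analysis only sees the resulting fractions.
* **Selection.** The spectinomycin half reweights each strain by
  `f * 0.93 + (1 - f) * 0`: memory-on cells are recovered at 93% and
  memory-off cells never escape, the measured plate-selection performance.
  Overnight post-selection growth is modeled as composition-preserving
  (equal growth rates); shared factors cancel in the OR anyway.
* **Sequencing** is a single multinomial draw per culture half (no PCR
  duplicate structure), with an optional per-strain multiplicative length
  bias used to exercise the OR's bias-cancellation property, and an
  optional substring-read emitter (uniform start, either strand,
  independent substitution errors) for end-to-end tests of the counter.

Default scale: 150 library strains plus the PNS, 5 planted in-vivo
responders (memory-on fraction 0.3), one disease-only responder (0.5),
3 mice per group, a gavage baseline plus 5 daily time points, and 5x10^5
reads per culture half. These sizes make a full simulated screen and its
analysis run in about a minute while leaving per-trigger untreated
coverage (~3,000 reads) far above the eligibility threshold.

What the simulator does **not** model — and what passing tests therefore
do not establish about real data: colony-level drift during the 4-hour
outgrowth at the fecal bottleneck, strain-specific fitness differences in
culture, PCR chimeras/duplicates, quality-dependent sequencing errors, and
alignment artifacts of real short-read mappers. The read counter is a
deterministic exact-substring assigner that stands in for unique-mapping
alignment; it is adequate for amplicon-like reads and for synthetic data,
but users with real sequencing data should enter the pipeline at the
count-table stage with counts from their preferred aligner.

## Problem sizes used in verification

The test suite checks the noncentral pmf against the central
hypergeometric on every table with `N <= 60`, the shifted-null p-value
against an independent conditional-test implementation on tables with
margins to ~10^4, type-I error on 10,000 simulated trigger-samples with a
true OR of 0.02 (hit rate stays below 0.05 plus three Monte Carlo standard
errors; the conditional test is conservative), parameter recovery at depth
10^6 (median OR within 10% of planted fractions 0.05/0.5/0.9 over 200
replicates), and full-screen responder recovery on the default
configuration above. Sub-seeds are fixed in the tests; the acceptance
script recomputes the same quantities from a user-supplied seed.

## Known limitations

* The exact test conditions on both margins; whether the original analysis
  did so or used an asymptotic OR test is not documented, and the
  conditional choice is the only one that reduces to Fisher's test at
  `psi = 1`.
* Ambiguous and unmapped reads are discarded, never redistributed.
* The OR is undefined (not zero) when the trigger is absent from the
  untreated half; such cells are blanked by the coverage filter in
  practice.
* `assign_read` is quadratic in read length in its fallback path; it is
  intended for amplicon-scale reads (tens to a few hundred nt), not long
  reads.
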