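---
title: "Methods: calling coordinated thyroid-hormone and glucocorticoid regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling coordinated thyroid-hormone and glucocorticoid regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormsynergy)
```

## The experimental design and the data model

hormsynergy analyses a four-arm expression experiment: vehicle (VEH),
3,5,3'-triiodothyronine (T3), corticosterone (CORT), and the combined
treatment (T3CORT), each with replicated normalized hybridization signals
per probe (the study design is triplicate). Signals are treated as
analysis-ready: normalization is upstream and out of scope. Because ratios
of means are the working effect measure, signals at or below zero (possible
after background subtraction) are raised to a configurable floor
(`signal_floor`, default 0.1 signal units) on import; missing cells are
rejected rather than imputed, since n = 3 leaves no room for imputation.

All stages speak tibbles: a wide expression table (`probe_id` plus one
column per sample), a design table (`sample_id`, `treatment`, `replicate`),
per-probe statistics, and per-gene interval classes.

## Differential expression

For each probe and each hormone arm the pipeline computes the fold change

$$\mathrm{FC} = \frac{\bar{x}_{\text{hormone}}}{\bar{x}_{\text{VEH}}}$$

as a ratio of raw-signal arithmetic means, and a two-sided Welch *t*-test of
the log2-transformed signals against vehicle. A probe is called up-regulated
when FC ≥ 1.5 (log2 = 0.58496) and p < 0.02, down-regulated when
FC ≤ 1/1.5 with the same p condition — the down threshold is symmetric on
the log2 scale. No multiple-testing correction enters the calls (the raw
p < 0.02 filter is deliberately conservative in combination with the FC
cut-off); a Benjamini–Hochberg column is emitted for information only.

Two numerical choices matter at n = 3. First, testing on log2 signals makes
p-values invariant to rescaling every intensity by a positive constant.
Second, when all replicates are identical in both groups the test is
degenerate: p is set to 1 when the means agree, and a variance floor of
1e-12 keeps the statistic finite (and the call obvious) when they do not.

A property worth knowing: the Welch test with n = 3 and a random
Satterthwaite df (between 2 and 4) is conservative — under a global null
about 1.1% of probes fall below p = 0.02, not 2%. Type-I control therefore
holds as an upper bound; an exact pooled-df Student test would be calibrated
but is not the default because unequal replicate variances between arms are
common in treated cells. The test is configurable in principle through the
module surface; the Welch form is the one used everywhere downstream.

## Venn partition and pattern codes

The three DE lists (T3, CORT, combined, each vs vehicle) define a three-way
Venn diagram whose six regions are the first-level regulation patterns:
`a` (T3 only), `b` (CORT only), `c` (combined only), `d` (T3 ∩ combined),
`e` (CORT ∩ combined), `f` (all three). The partition is exact by
construction: |T3| = a+d+f, |CORT| = b+e+f, |combined| = c+d+e+f. Probes DE
in both singles but not the combined treatment have no region in this
taxonomy; they are folded into `none` with a warning so the identities stay
exact.

Intersection regions are refined by asking whether the combined signal
differs from the single hormone's signal (two-sided Welch on log2 signals at
`alpha_refine`, default 0.05 — the conventional level, exposed in the
thresholds because the original analysis states no alpha for this step):

* section `e` (CORT ∩ combined): not significant → E1/E2 (T3 does not
  affect the CORT response); significant with |log2FC(combined)| >
  |log2FC(CORT)| → E3/E4 (T3 enhances it); significant and smaller →
  E5/E6 (T3 suppresses it);
* section `d` mirrors this against T3 with three codes: D3 when not
  significant (the T3 response persists), D1 when significantly enhanced in
  the same direction, D2 otherwise (reversed or reduced — the classic case
  being a gene induced by T3 but repressed by the combination);
* sections `a`, `b`, `c`, `f` map directly to A1, B1/B2, C1/C2, F1 with no
  sub-test (`f` is deliberately not subdivided).

Odd/even code indices encode induced/repressed. Direction is taken from the
combined treatment for sections c–f and from the defining single hormone
for a and b; this convention is what makes a D2-style reversal legible.

Probe-to-gene collapsing keeps one probe per gene and set: when duplicate
probes of a gene disagree, the probe with the largest |log2FC| in its
section's defining treatment wins, with ties broken by probe id for
determinism. Unannotated probes are dropped and counted. The winner-takes-all
rule across sets is a package convention — how the original analysis
resolved cross-section duplicates is not stated anywhere we could follow.

## The synergy caller

A probe is synergistically regulated by the combination when either:

1. **combined-only response** — no DE response to either hormone alone but
   a significant response to the combination (exactly Venn section c); or
2. **greater-than-additive response** — the combined mean departs from the
   additive expectation by at least `sd_multiplier` (default 1) standard
   deviations *on the side of the combined response*, with a significant
   Welch variance-sum test (p < `alpha_de`), and the combined arm itself DE.

The additive expectation has two conventions. The default,
`baseline_corrected`,

$$E = \bar{x}_{T3} + \bar{x}_{CORT} - \bar{x}_{VEH},$$

treats the *effects above baseline* as additive. The `literal_sum` option
($E = \bar{x}_{T3} + \bar{x}_{CORT}$) is retained for fidelity checks, but
it cannot detect synergistic repression: the raw sum of two near-vehicle
signals always dwarfs a repressed combined signal, while repressed synergy
genes plainly exist in this system. Under the corrected form a repressed
gene synergizes when its combined signal falls *below* E by the margin.

The test statistic propagates every variance term of the comparison:

$$t = \frac{\bar{x}_{T3CORT} - E}
{\sqrt{s^2_{T3CORT}/n + s^2_{T3}/n + s^2_{CORT}/n \,[+\, s^2_{VEH}/n]}}$$

with Welch–Satterthwaite degrees of freedom over the same terms (the VEH
term enters only under `baseline_corrected`). The SD margin, by contrast,
is fixed at $\sqrt{s^2_{T3} + s^2_{CORT}}$ under both conventions — the sum
of the single-treatment variances is how the comparison's variance was
defined in the source analysis, and the margin follows that definition
literally while the combined-arm variance enters only the *t* denominator.

Two resolved ambiguities, both visible in the code:

* Criterion 2 requires the combined arm to be DE and the departure to lie on
  the same side as the combined response. This keeps suppressed responses
  (combined below additive but still induced — the E5/E6 pattern) out of the
  synergy list, and makes the identity *synergy set = section c ∪
  intersection probes passing criterion 2* hold by construction.
* The SD-margin rule and the Welch p-value are conjoined; both must pass.

The call's direction follows the sign of the departure from E (induced
above, repressed below).

**A power asymmetry to be aware of.** On the signal scale a repressed
departure shrinks multiplicatively while the Welch denominator is dominated
by the variances of the baseline-level arms, so criterion 2 detects
repressed greater-than-additive plants at roughly half the rate of induced
ones at the same log2 departure. Combined-only (criterion 1) calls do not
suffer from this, which is consistent with repressed synergy genes arising
almost entirely from section c in practice. Relatedly, with n = 3 the
variance-sum Welch test has df ≈ 4–5; a departure of six pooled noise SDs
yields criterion-2 power of only ~0.85–0.91, and p < 0.001 in only about a
third of draws. Claims of near-certain detection at six SDs implicitly
assume large-sample normality; the default synthetic benchmark therefore
plants combined-only synergy at +1.5 log2 (ten pooled SDs at the default
noise), where the full caller's sensitivity exceeds 99%.

## Receptor–enhancer co-localization

For each gene the mapping window is the gene body ± `flank_bp` (default
50 kb beyond the TSS and TTS; both ends flanked equally, so the window is
strand-independent), clamped at the chromosome origin. All coordinates are
BED convention — 0-based, half-open — and gaps are edge-to-edge with
book-ended intervals at gap 0, matching the coordinate arithmetic of the
BedOPS-style toolchain this analysis pattern comes from.

A receptor (GR or TR) ChIP peak *qualifies* for a gene and an enhancer-mark
group when it (i) at least partially overlaps the gene window and (ii) lies
within `proximity_bp` (default 1 kb) of some peak of that mark group; the
mark peak itself may sit outside the window. Mark groups are H3K27Ac, MED
(the union of MED1 and MED12 tracks), and RNA Pol2. The gene's class per
group is `both`, `GR_only`, `TR_only`, or `none`, and cohort summaries
report 100·count/total to two decimals. Partial window overlap counts, and
proximity is edge-to-edge; both were unstated in the source and are fixed
here as the permissive readings.

The proximity engine is a sorted sweep (running maximum of subject ends plus
a binary search per query), which the test suite verifies against a
brute-force all-pairs oracle — exactly, over hundreds of random fixtures —
and against an independent interval library on random pairs. A monotonicity
property (growing the window or the proximity threshold never demotes a
gene's class) guards the boundary arithmetic.

The control cohort is a uniform, seeded, without-replacement sample of
`n_control_genes` (default 300) genes excluding every regulated gene.

## What the synthetic generators emulate — and what they do not

`simulate_expression()` draws per-probe baselines
(log2 ~ N(7, 1.5²)), adds class-specific log2 effects (vehicle = baseline;
singles = baseline + own effect; combined = baseline + both effects +
departure), adds i.i.d. replicate noise (log2 SD 0.15), and exponentiates.
The default planted classes (documented in `?sim_pattern_classes`) echo the
hormone-response asymmetry of the study system — CORT-rich, T3-poor — with
effects of 1.0–1.5 log2, half induced and half repressed per class. The
e-enhanced class uses a CORT effect of 1.2 log2 because single-arm DE power
at the 1.5-FC/0.02 cut is ~0.95 at 1.0 log2 and ~0.985 at 1.2; the
suppressed class keeps its combined response at 0.9 log2 so it stays
reliably DE. Fractions are exact (rounded counts, not draws), so planted
cohort sizes are deterministic.

The generator does **not** emulate probe-level microarray artifacts:
spatial effects, cross-hybridization, intensity-dependent variance, probe
outliers, or correlation between probes of one gene. Passing recovery tests
therefore show that the *statistical pipeline* recovers its own model's
structure at the documented effect sizes; they do not certify performance
on arrays whose noise violates log-normality.

`simulate_tracks()` lays genes out without window overlap, divides each
window into well-separated slots (one per mark-group × receptor pair plus a
negative slot), and plants receptor–mark pairs at controlled gaps. Planted
proximal gaps stay at least `margin_bp` (default 2 bp) below the threshold
and negatives the same margin above it, so no off-by-one or open/closed
convention can flip a truth label. Intergenic decoy pairs sit outside every
window and must never classify. With the default 110-gene cohort and
planted fractions, the classifier must reproduce the planted percentages
exactly — e.g. 57/110 = 51.82% H3K27Ac-proximal.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data:
10,000-probe cohorts for recovery and false-positive benchmarks (a planted
proportion over thousands of probes estimates a rate to well under a
percentage point), 100+ random fixtures for the interval oracle, and a
110-gene track cohort for the mapping fractions. Every random stage takes
an explicit integer seed, all generation is wrapped in `withr::with_seed`,
and re-running any stage with the same config is bit-identical — determinism
is itself a tested property.

## Known limitations

* The per-probe test behind the original deposited gene lists is an
  unnamed vendor implementation; with the Welch default here, headline
  counts on the deposited data should be close but need not be identical
  (the conservative raw-p filter is the dominant factor).
* Criterion-2 synergy power is asymmetric between induction and repression
  (see above) and low near the margin at n = 3.
* The mapping stage assumes all inputs share one genome assembly; it
  validates chromosome-name compatibility but performs no conversion.
* Functional annotation clustering and motif scoring are out of scope;
  gene sets are exported for external tools.
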