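# hormsynergy

Tools for analysing coordinated transcriptional regulation by thyroid
hormone (T3) and glucocorticoid (CORT) in a replicated four-treatment
expression experiment (vehicle, T3, CORT, T3+CORT), as used to study
hormone crosstalk in hippocampal neurons. The package is for
transcriptomics analysts who have a normalized probe × sample signal matrix
plus (optionally) receptor and enhancer-mark ChIP peak tracks, and want
reproducible, testable answers to three questions:

1. **Which probes respond to which treatment?** Fold-change + Welch-test
   filtering against vehicle (FC ≥ 1.5, i.e. |log2 FC| ≥ 0.58496, raw
   p < 0.02).
2. **What regulation pattern does each responder follow?** Three-way Venn
   partition of the T3 / CORT / T3+CORT DE lists into sections a–f,
   refined by testing the combined signal against each single hormone into
   pattern codes A1–F1 (e.g. E3 = "T3 enhances the CORT response").
3. **Which genes are synergistically regulated, and is the receptor
   machinery nearby?** A two-criterion synergy caller, and a BED-interval
   proximity analysis classifying each gene by GR/TR peaks within 1 kb of
   enhancer marks (H3K27Ac, MED1/12, RNA Pol2) inside the gene body ± 50 kb.

The synergy statistic at the core: a probe is synergistic when it responds
only to the combined treatment (criterion 1), or when the combined signal
departs from the additive expectation

E = x̄(T3) + x̄(CORT) − x̄(VEH)

on the side of the combined response by at least one standard deviation
(SD margin = √(s²(T3) + s²(CORT))) with a significant variance-sum Welch
test (criterion 2):

t = (x̄(T3+CORT) − E) / √(s²(T3CORT)/n + s²(T3)/n + s²(CORT)/n + s²(VEH)/n)

with Welch–Satterthwaite degrees of freedom. Both a literal-sum and the
baseline-corrected expectation are supported; the corrected form is the
default because a literal sum cannot detect synergistic repression (see the
methods vignette, `vignettes/hormone-synergy-methods.Rmd`).

Synthetic generators (`simulate_expression()`, `simulate_tracks()`) produce
inputs with planted regulation classes, synergy departures and
receptor–mark co-localization — with machine-readable truth labels — so the
whole pipeline is testable offline.

## Worked example

```r
library(hormsynergy)

sim <- simulate_expression(sim_expression_config(rng_seed = 1))
fit <- run_pipeline(sim$expression, sim$design)
fit
#> <hs_pipeline>
#>   DE probes: T3 50 | CORT 496 | T3+CORT 458
#>   Venn: a=20 b=201 c=153 d=10 e=275 f=20 none=9321
#>   synergy: 181 (100 induced, 81 repressed)
#>   partition identities: ok
```

The report says: of 10,000 simulated probes, 50 respond to T3, 496 to CORT
and 458 to the combination; the Venn sections tile those lists exactly
(50 = a+d+f = 20+10+20, and so on — `identities: ok`); 181 probes are
called synergistic, 100 induced and 81 repressed. `tidy(fit)` returns the
per-probe table, `glance(fit)` the one-row summary, and
`synergy_tables(fit$synergy, n = 3)$induced` the top induced synergy
probes ranked by combined fold change:

```r
#>   probe_id    fc_t3 fc_cort fc_t3cort    welch_p synergy_criterion
#> 1 probe_00598 0.971    2.62      4.97 0.00000308 greater_than_additive
#> 2 probe_00581 1.02     2.28      4.97 0.000652   greater_than_additive
#> 3 probe_00599 0.995    2.32      4.93 0.000644   greater_than_additive
```

Each row reads like a study table: e.g. the first probe barely responds to
T3 (FC 0.97), responds 2.6-fold to CORT, and 5.0-fold to the combination —
significantly beyond the additive expectation (Welch p = 3e-6).

The mapping stage classifies genes by receptor/mark proximity:

```r
tr <- simulate_tracks(sim_track_config(rng_seed = 1))
summarize_fractions(classify_genes(tr$loci, tr$tracks))
#>   mark_group n_genes n_any pct_any pct_gr_only pct_tr_only pct_both
#> 1 H3K27Ac        110    57    51.8        20.9       14.6     16.4
#> 2 MED            110    52    47.3        18.2       17.3     11.8
#> 3 POL2           110    31    28.2        10.9        8.18     9.09
```

i.e. 57 of 110 genes (51.82%) have a GR or TR peak within 1 kb of an
H3K27Ac peak inside their ±50 kb window — 20.91% with GR only, 14.55% with
TR only, 16.36% with both.

Plots: `autoplot(fit, "patterns")`, `autoplot(fit, "synergy")`,
`plot_coloc_fractions()`, `plot_expression_heatmap()` (min–max row-scaled,
blue = row minimum, red = row maximum).

A thin command-line wrapper lives in `inst/scripts/hormsynergy.R`
(`run --config config.yaml`, `simulate expression|tracks`); real data in
GEO series-matrix layout imports via `read_series_matrix()` and BED tracks
via `read_bed()`.

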