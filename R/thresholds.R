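#' Analysis thresholds
#'
#' Bundle of the tunable cut-offs used across the pipeline. Defaults are the
#' study values: differential expression requires a 1.5 fold change
#' (log2 = 0.58496) and raw P < 0.02; intersection refinement uses alpha 0.05;
#' the synergy margin is one standard deviation; peak mapping searches the
#' gene body plus 50 kb flanks and requires receptor-to-mark gaps of at most
#' 1 kb; the random control cohort has 300 genes.
#'
#' @param fc_cutoff Fold-change ratio for a DE call (must be > 1). Down
#'   regulation is symmetric on the log scale: fc <= 1/fc_cutoff.
#' @param alpha_de Raw p-value cut-off for DE and for the synergy Welch test.
#' @param alpha_refine P-value cut-off for the intersection refinement tests
#'   (combined vs single hormone).
#' @param sd_multiplier Number of standard deviations the combined signal must
#'   depart from the additive expectation under synergy criterion 2.
#' @param flank_bp Flank added on each side of the gene body to form the
#'   mapping window, in bp.
#' @param proximity_bp Maximum receptor-peak-to-mark-peak gap, in bp.
#' @param n_control_genes Size of the random non-regulated control cohort.
#' @param signal_floor Minimum signal; values below are raised so ratios are
#'   defined (expression signals can be non-positive after background
#'   subtraction).
#' @param synergy_mode `"baseline_corrected"` (default; additive expectation
#'   `mean_T3 + mean_CORT - mean_VEH`) or `"literal_sum"`
#'   (`mean_T3 + mean_CORT`). See the methods vignette for why the corrected
#'   form is the default.
#' @param rng_seed Integer seed for the control-gene sampler.
#'
#' @return A list with class `"hs_thresholds"`.
#' @examples
#' hs_thresholds()
#' hs_thresholds(alpha_refine = 0.02)
#' @export
hs_thresholds <- function(fc_cutoff = 1.5,
                          alpha_de = 0.02,
                          alpha_refine = 0.05,
                          sd_multiplier = 1,
                          flank_bp = 50000L,
                          proximity_bp = 1000L,
                          n_control_genes = 300L,
                          signal_floor = 0.1,
                          synergy_mode = c("baseline_corrected", "literal_sum"),
                          rng_seed = 1L) {
  synergy_mode <- match.arg(synergy_mode)
  stopifnot(fc_cutoff > 1, alpha_de > 0, alpha_de < 1,
            alpha_refine > 0, alpha_refine < 1,
            sd_multiplier >= 0, flank_bp >= 0, proximity_bp >= 0,
            n_control_genes >= 1, signal_floor > 0)
  structure(
    list(fc_cutoff = fc_cutoff, alpha_de = alpha_de,
         alpha_refine = alpha_refine, sd_multiplier = sd_multiplier,
         flank_bp = as.integer(flank_bp),
         proximity_bp = as.integer(proximity_bp),
         n_control_genes = as.integer(n_control_genes),
         signal_floor = signal_floor, synergy_mode = synergy_mode,
         rng_seed = as.integer(rng_seed)),
    class = "hs_thresholds"
  )
}

#' @export
print.hs_thresholds <- function(x, ...) {
  cat("<hs_thresholds>\n")
  cat(sprintf("  DE: FC >= %.3g (log2 %.5f), p < %.3g\n",
              x$fc_cutoff, log2(x$fc_cutoff), x$alpha_de))
  cat(sprintf("  refine: p < %.3g | synergy: %g SD margin, mode %s\n",
              x$alpha_refine, x$sd_multiplier, x$synergy_mode))
  cat(sprintf("  mapping: +/- %d bp window, <= %d bp proximity, %d control genes\n",
              x$flank_bp, x$proximity_bp, x$n_control_genes))
  invisible(x)
}
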