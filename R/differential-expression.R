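#' Per-probe treatment statistics
#'
#' Computes, for every probe, the arithmetic mean, unbiased variance and
#' replicate count of the raw (floored) signal in each treatment arm, the
#' fold change of each hormone arm against vehicle (ratio of raw-signal
#' means), its log2, and a p-value from a two-sided Welch t-test of the
#' log2-transformed signals of the hormone arm against vehicle. Working on
#' log signals makes the test invariant to rescaling all intensities by a
#' positive constant; fold changes use the raw-scale means, as ratio-based
#' filtering does.
#'
#' @param expression Wide expression tibble (`probe_id` + sample columns),
#'   already validated/floored (see [read_expression_table()]).
#' @param design Validated design tibble.
#' @return A tibble with one row per probe: `n_*`, `mean_*`, `var_*` for each
#'   of VEH/T3/CORT/T3CORT (lower-case suffixes), and `fc_*`, `log2fc_*`,
#'   `p_*` for each hormone arm.
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 50, rng_seed = 1))
#' stats <- treatment_stats(sim$expression, sim$design)
#' dplyr::glimpse(stats)
#' @export
treatment_stats <- function(expression, design) {
  design <- validate_design(design)
  m <- .expr_matrix(expression, design)
  if (any(m <= 0)) {
    abort("signals must be positive; apply the signal floor first")
  }
  lm2 <- log2(m)
  out <- tibble::tibble(probe_id = expression$probe_id)
  cols <- lapply(setNames(TREATMENTS, TREATMENTS),
                 function(tr) .treatment_cols(design, tr))
  for (tr in TREATMENTS) {
    sub <- m[, cols[[tr]], drop = FALSE]
    suffix <- tolower(tr)
    out[[paste0("n_", suffix)]] <- ncol(sub)
    out[[paste0("mean_", suffix)]] <- rowMeans(sub)
    out[[paste0("var_", suffix)]] <- .row_var(sub)
  }
  veh_log <- lm2[, cols[["VEH"]], drop = FALSE]
  for (tr in HORMONE_ARMS) {
    suffix <- tolower(tr)
    fc <- out[[paste0("mean_", suffix)]] / out[["mean_veh"]]
    out[[paste0("fc_", suffix)]] <- fc
    out[[paste0("log2fc_", suffix)]] <- log2(fc)
    w <- .welch_rows(lm2[, cols[[tr]], drop = FALSE], veh_log)
    out[[paste0("p_", suffix)]] <- w$p
  }
  out
}

#' Call differential expression against vehicle
#'
#' A hormone arm is called `up` when its fold change is at least `fc_cutoff`
#' and its p-value is below `alpha_de`; `down` when the fold change is at most
#' `1/fc_cutoff` (symmetric on the log2 scale) with the same p-value
#' condition; `ns` otherwise. A Benjamini-Hochberg adjusted p-value column is
#' added per arm for information only — the calls use the raw p-values, as
#' the filtering scheme does.
#'
#' @param stats Output of [treatment_stats()].
#' @param thresholds An [hs_thresholds()] object.
#' @return `stats` with added `dir_t3`, `dir_cort`, `dir_t3cort` factors
#'   (levels up/down/ns) and `padj_*` columns.
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 50, rng_seed = 1))
#' calls <- call_de(treatment_stats(sim$expression, sim$design), hs_thresholds())
#' table(calls$dir_t3cort)
#' @export
call_de <- function(stats, thresholds = hs_thresholds()) {
  stopifnot(inherits(thresholds, "hs_thresholds"))
  out <- stats
  for (tr in HORMONE_ARMS) {
    suffix <- tolower(tr)
    fc <- out[[paste0("fc_", suffix)]]
    p <- out[[paste0("p_", suffix)]]
    dir <- dplyr::case_when(
      fc >= thresholds$fc_cutoff & p < thresholds$alpha_de ~ "up",
      fc <= 1 / thresholds$fc_cutoff & p < thresholds$alpha_de ~ "down",
      .default = "ns"
    )
    out[[paste0("dir_", suffix)]] <- factor(dir, levels = c("up", "down", "ns"))
    out[[paste0("padj_", suffix)]] <- stats::p.adjust(p, method = "BH")
  }
  out
}

#' Is a probe differentially expressed in an arm?
#'
#' @param calls Output of [call_de()].
#' @param arm One of `"t3"`, `"cort"`, `"t3cort"`.
#' @return Logical vector, one per probe.
#' @export
is_de <- function(calls, arm = c("t3", "cort", "t3cort")) {
  arm <- match.arg(arm)
  calls[[paste0("dir_", arm)]] != "ns"
}
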