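#' Additive expectation for the combined treatment
#'
#' The signal the combined T3+CORT treatment would show if the two hormone
#' effects simply summed. Two conventions are supported:
#' * `baseline_corrected` (default): `mean_T3 + mean_CORT - mean_VEH`, i.e.
#'   additivity of the effects above the vehicle baseline;
#' * `literal_sum`: `mean_T3 + mean_CORT`, the raw sum of the two
#'   single-treatment signals.
#'
#' The corrected form is the default because the literal sum of two signals
#' near baseline always exceeds a repressed combined signal, which would make
#' synergistic repression undetectable; see the methods vignette.
#'
#' @param mean_t3,mean_cort,mean_veh Mean signals (vectorised).
#' @param mode `"baseline_corrected"` or `"literal_sum"`.
#' @return Numeric vector of expected combined signals.
#' @examples
#' additive_expectation(300, 380, 100)                       # 580
#' additive_expectation(300, 380, 100, mode = "literal_sum") # 680
#' @export
additive_expectation <- function(mean_t3, mean_cort, mean_veh,
                                 mode = c("baseline_corrected", "literal_sum")) {
  mode <- match.arg(mode)
  switch(mode,
         baseline_corrected = mean_t3 + mean_cort - mean_veh,
         literal_sum = mean_t3 + mean_cort)
}

#' Welch variance-sum test of the combined signal against additivity
#'
#' Tests whether the combined-treatment mean departs from the additive
#' expectation, propagating the variance of every term of the expectation:
#' the variance of the comparison is the sum of the per-treatment variance
#' terms `var/n` over the combined arm, the T3 arm, the CORT arm and (under
#' `baseline_corrected`) the vehicle arm. Degrees of freedom follow
#' Welch-Satterthwaite over the same terms; the p-value is two-sided.
#'
#' @param stats Output of [treatment_stats()].
#' @param mode Additive-expectation convention (see [additive_expectation()]).
#' @return A tibble `probe_id`, `additive_expectation`, `delta`
#'   (`mean_t3cort` minus the expectation), `welch_t`, `welch_df`, `welch_p`.
#' @export
welch_sum_test <- function(stats, mode = c("baseline_corrected", "literal_sum")) {
  mode <- match.arg(mode)
  expect <- additive_expectation(stats$mean_t3, stats$mean_cort,
                                 stats$mean_veh, mode = mode)
  delta <- stats$mean_t3cort - expect
  terms <- cbind(stats$var_t3cort / stats$n_t3cort,
                 stats$var_t3 / stats$n_t3,
                 stats$var_cort / stats$n_cort)
  dfs <- cbind(stats$n_t3cort - 1, stats$n_t3 - 1, stats$n_cort - 1)
  if (mode == "baseline_corrected") {
    terms <- cbind(terms, stats$var_veh / stats$n_veh)
    dfs <- cbind(dfs, stats$n_veh - 1)
  }
  se2 <- rowSums(terms)
  degenerate <- se2 <= 0
  se2_eff <- ifelse(degenerate, VAR_FLOOR, se2)
  tval <- delta / sqrt(se2_eff)
  df_den <- rowSums(terms^2 / dfs)
  df <- ifelse(df_den > 0, se2^2 / df_den, rowSums(dfs))
  p <- 2 * pt(-abs(tval), df)
  flat <- degenerate & delta == 0
  tval[flat] <- 0
  p[flat] <- 1
  tibble::tibble(probe_id = stats$probe_id,
                 additive_expectation = expect,
                 delta = delta,
                 welch_t = tval, welch_df = df, welch_p = p)
}

#' Call synergistic regulation by the combined treatment
#'
#' A probe is synergistically regulated when either of two criteria holds:
#' 1. *combined-only*: no DE response to T3 or CORT alone but a significant
#'    response to the combined treatment (this is exactly Venn section c);
#' 2. *greater-than-additive*: the combined treatment is DE, and its mean
#'    signal departs from the additive expectation on the same side as the
#'    combined response (above it for induced genes, below for repressed) by
#'    at least `sd_multiplier` standard deviations — the SD margin being the
#'    square root of the summed single-treatment variances — with the Welch
#'    variance-sum test significant at `alpha_de`.
#'
#' Direction (`induced`/`repressed`) follows the sign of the departure from
#' the additive expectation.
#'
#' @param calls Output of [call_de()] (needs both DE directions and the
#'   per-treatment stats columns).
#' @param thresholds An [hs_thresholds()] object; `synergy_mode` selects the
#'   additive-expectation convention.
#' @return `calls` with added columns `additive_expectation`, `delta`,
#'   `sd_margin`, `welch_t`, `welch_df`, `welch_p`, `synergy_criterion`
#'   (factor: combined_only / greater_than_additive / both / none) and
#'   `synergy_direction` (factor: induced / repressed / none).
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 500, rng_seed = 1))
#' syn <- sim$expression |>
#'   treatment_stats(sim$design) |>
#'   call_de() |>
#'   call_synergy()
#' table(syn$synergy_criterion)
#' @export
call_synergy <- function(calls, thresholds = hs_thresholds()) {
  stopifnot(inherits(thresholds, "hs_thresholds"))
  w <- welch_sum_test(calls, mode = thresholds$synergy_mode)
  sd_margin <- sqrt(calls$var_t3 + calls$var_cort)
  crit1 <- calls$dir_t3 == "ns" & calls$dir_cort == "ns" &
    calls$dir_t3cort != "ns"
  comb_up <- calls$dir_t3cort == "up"
  comb_down <- calls$dir_t3cort == "down"
  margin_ok <- abs(w$delta) >= thresholds$sd_multiplier * sd_margin
  side_ok <- (comb_up & w$delta > 0) | (comb_down & w$delta < 0)
  crit2 <- side_ok & margin_ok & w$welch_p < thresholds$alpha_de
  criterion <- dplyr::case_when(
    crit1 & crit2 ~ "both",
    crit1 ~ "combined_only",
    crit2 ~ "greater_than_additive",
    .default = "none"
  )
  direction <- dplyr::case_when(
    criterion == "none" ~ "none",
    w$delta > 0 ~ "induced",
    w$delta < 0 ~ "repressed",
    .default = "none"
  )
  out <- calls
  out$additive_expectation <- w$additive_expectation
  out$delta <- w$delta
  out$sd_margin <- sd_margin
  out$welch_t <- w$welch_t
  out$welch_df <- w$welch_df
  out$welch_p <- w$welch_p
  out$synergy_criterion <- factor(
    criterion, levels = c("combined_only", "greater_than_additive", "both", "none"))
  out$synergy_direction <- factor(
    direction, levels = c("induced", "repressed", "none"))
  out
}

#' Ranked synergy tables
#'
#' Extracts the synergistically regulated probes and ranks them by combined
#' fold change: induced genes descending, repressed genes ascending, the way
#' top-gene tables are usually presented.
#'
#' @param synergy Output of [call_synergy()].
#' @param annotation Optional `probe_id`/`gene_symbol` tibble to attach
#'   symbols.
#' @param n Number of rows per table (default 20); `Inf` for all.
#' @return A list of two tibbles, `induced` and `repressed`, with columns
#'   probe/gene, the FC triple, criterion and Welch columns.
#' @export
synergy_tables <- function(synergy, annotation = NULL, n = 20) {
  hits <- synergy[synergy$synergy_criterion != "none", ]
  if (!is.null(annotation)) {
    hits <- dplyr::left_join(hits, tibble::as_tibble(annotation), by = "probe_id")
  }
  keep <- intersect(c("probe_id", "gene_symbol", "fc_t3", "fc_cort", "fc_t3cort",
                      "additive_expectation", "delta", "sd_margin",
                      "welch_t", "welch_df", "welch_p",
                      "synergy_criterion", "synergy_direction"), names(hits))
  hits <- hits[, keep]
  list(
    induced = hits |>
      dplyr::filter(.data$synergy_direction == "induced") |>
      dplyr::arrange(dplyr::desc(.data$fc_t3cort)) |>
      head(n),
    repressed = hits |>
      dplyr::filter(.data$synergy_direction == "repressed") |>
      dplyr::arrange(.data$fc_t3cort) |>
      head(n)
  )
}
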