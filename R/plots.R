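# ggplot2 views of the pipeline results. All plot functions accept the
# tibbles the pipeline stages return, so they chain naturally.

#' Bar chart of Venn-section / pattern-code counts
#'
#' @param fit An `hs_pipeline` object (or the output of [refine_patterns()]).
#' @param by `"venn_section"` or `"pattern_code"`.
#' @return A ggplot object.
#' @export
plot_pattern_counts <- function(fit, by = c("venn_section", "pattern_code")) {
  by <- match.arg(by)
  assignments <- if (inherits(fit, "hs_pipeline")) fit$assignments else fit
  df <- assignments |>
    dplyr::filter(.data[[by]] != "none") |>
    dplyr::count(.data[[by]], .data$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[by]], y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#c23b22", down = "#3b6fc2"),
                               na.value = "grey70") +
    ggplot2::labs(x = NULL, y = "probes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-change scatter of synergy calls
#'
#' Combined-treatment fold change against the additive expectation (both on
#' the log2 scale), coloured by synergy call; the diagonal marks exact
#' additivity.
#'
#' @param synergy Output of [call_synergy()] (or an `hs_pipeline`).
#' @return A ggplot object.
#' @export
plot_synergy <- function(synergy) {
  if (inherits(synergy, "hs_pipeline")) synergy <- synergy$synergy
  df <- synergy |>
    dplyr::mutate(log2_expected = log2(pmax(.data$additive_expectation,
                                            .Machine$double.eps)),
                  log2_observed = log2(.data$mean_t3cort))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_expected,
                                   y = .data$log2_observed,
                                   colour = .data$synergy_direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(induced = "#c23b22",
                                            repressed = "#3b6fc2",
                                            none = "grey80")) +
    ggplot2::labs(x = "log2 additive expectation", y = "log2 combined signal",
                  colour = "synergy") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of co-localization fractions
#'
#' GR-only / TR-only / both fractions per enhancer-mark group, optionally
#' side by side with a control cohort — the usual presentation for
#' receptor/mark proximity summaries.
#'
#' @param summary Output of [summarize_fractions()].
#' @param control Optional second summary (control cohort).
#' @return A ggplot object.
#' @export
plot_coloc_fractions <- function(summary, control = NULL) {
  prep <- function(s, cohort) {
    s |>
      tidyr::pivot_longer(c("pct_gr_only", "pct_tr_only", "pct_both"),
                          names_to = "class", values_to = "pct") |>
      dplyr::mutate(cohort = cohort,
                    class = factor(.data$class,
                                   levels = c("pct_both", "pct_tr_only",
                                              "pct_gr_only"),
                                   labels = c("both", "TR only", "GR only")))
  }
  df <- prep(summary, "study")
  if (!is.null(control)) df <- dplyr::bind_rows(df, prep(control, "control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~mark_group) +
    ggplot2::labs(x = NULL, y = "% of genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Row-scaled expression heatmap
#'
#' Min-max scales each probe row (see [row_scale()]) and renders the classic
#' blue-to-red tile heatmap, ordered by Venn section when assignments are
#' supplied.
#'
#' @param expression Wide expression tibble.
#' @param assignments Optional output of [venn_partition()] used to order and
#'   facet rows; only non-`none` probes are drawn.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(expression, assignments = NULL) {
  scaled <- row_scale(expression)
  if (!is.null(assignments)) {
    keep <- assignments$probe_id[assignments$venn_section != "none"]
    ord <- assignments[order(assignments$venn_section), ]
    keep <- ord$probe_id[ord$probe_id %in% keep]
    scaled <- scaled[match(keep, scaled$probe_id), ]
  }
  df <- tidyr::pivot_longer(scaled, -"probe_id",
                            names_to = "sample", values_to = "value")
  df$probe_id <- factor(df$probe_id, levels = rev(unique(scaled$probe_id)))
  df$sample <- factor(df$sample, levels = setdiff(names(scaled), "probe_id"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$probe_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "row-scaled\nsignal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pipeline results
#'
#' @param object An `hs_pipeline` object.
#' @param type One of `"patterns"`, `"synergy"`, `"coloc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_pipeline <- function(object, type = c("patterns", "synergy", "coloc"),
                                 ...) {
  type <- match.arg(type)
  switch(type,
         patterns = plot_pattern_counts(object),
         synergy = plot_synergy(object),
         coloc = plot_coloc_fractions(object$coloc_summary,
                                      object$control_summary))
}
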