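#' Run the full analysis pipeline
#'
#' Orchestrates the expression stages (per-probe stats, DE calls, Venn
#' partition, pattern refinement, synergy calls, gene collapsing) and the
#' mapping stage (receptor/mark co-localization for the synergy cohort and a
#' random non-regulated control cohort) from in-memory inputs, and assembles
#' a count report whose partition identities are checked.
#'
#' @param expression,design Validated expression tibble and design (see
#'   [read_expression_table()]).
#' @param annotation Optional `probe_id`/`gene_symbol` tibble; required for
#'   gene-level sets and for the mapping stage.
#' @param loci Optional gene loci tibble (see [read_gene_annotation()]).
#' @param tracks Optional named list of peak tibbles (GR, TR, marks).
#' @param thresholds An [hs_thresholds()] object.
#' @param stages Character subset of `c("expression", "coloc")`.
#' @return An object of class `"hs_pipeline"`: a list with elements
#'   `synergy` (per-probe tibble through [call_synergy()]), `assignments`
#'   (through [refine_patterns()]), `gene_sets`, `coloc_classes`,
#'   `coloc_summary`, `control_summary`, `report` (nested count list) and
#'   `thresholds`.
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 300, rng_seed = 2))
#' fit <- run_pipeline(sim$expression, sim$design)
#' glance(fit)
#' @export
run_pipeline <- function(expression, design, annotation = NULL, loci = NULL,
                         tracks = NULL, thresholds = hs_thresholds(),
                         stages = c("expression", "coloc")) {
  stopifnot(inherits(thresholds, "hs_thresholds"))
  stages <- match.arg(stages, several.ok = TRUE)
  design <- validate_design(design)
  out <- list(thresholds = thresholds)

  if ("expression" %in% stages) {
    assignments <- expression |>
      treatment_stats(design) |>
      call_de(thresholds) |>
      venn_partition() |>
      refine_patterns(expression, design, thresholds)
    synergy <- call_synergy(assignments, thresholds)
    out$assignments <- assignments
    out$synergy <- synergy
    if (!is.null(annotation)) {
      out$gene_sets <- collapse_probes(assignments, annotation)
    }
  }

  if ("coloc" %in% stages && !is.null(loci) && !is.null(tracks)) {
    if (!is.null(out$synergy) && "gene_symbol" %in% names(loci)) {
      syn_probes <- out$synergy$probe_id[out$synergy$synergy_criterion != "none"]
      syn_genes <- if (!is.null(annotation)) {
        unique(annotation$gene_symbol[annotation$probe_id %in% syn_probes])
      } else character()
      cohort <- loci[loci$gene_symbol %in% syn_genes, ]
      if (nrow(cohort) == 0L) cohort <- loci
    } else {
      cohort <- loci
      syn_genes <- character()
    }
    out$coloc_classes <- classify_genes(cohort, tracks, thresholds)
    out$coloc_summary <- summarize_fractions(out$coloc_classes)
    n_ctrl <- min(thresholds$n_control_genes,
                  nrow(loci) - length(intersect(loci$gene_symbol, syn_genes)))
    if (n_ctrl >= 1 && nrow(loci) > nrow(cohort)) {
      ctrl <- sample_control_genes(loci, exclude = syn_genes, n = n_ctrl,
                                   rng_seed = thresholds$rng_seed)
      out$control_summary <- summarize_fractions(
        classify_genes(ctrl, tracks, thresholds))
    }
  }

  out$report <- build_report(out)
  structure(out, class = "hs_pipeline")
}

#' Assemble the count report for a pipeline result
#'
#' @param fit A partially or fully populated pipeline list.
#' @return Nested list of per-stage counts plus `identities_ok`.
#' @export
build_report <- function(fit) {
  report <- list()
  if (!is.null(fit$assignments)) {
    ct <- pattern_counts(fit$assignments)
    report$de_lists <- as.list(ct$de_lists)
    report$venn_sections <- as.list(ct$sections)
    report$pattern_codes <- as.list(ct$codes)
    report$identities_ok <- suppressWarnings(
      check_partition_identities(fit$assignments))
  }
  if (!is.null(fit$synergy)) {
    syn <- fit$synergy
    hits <- syn$synergy_criterion != "none"
    report$synergy <- list(
      total = sum(hits),
      induced = sum(syn$synergy_direction == "induced"),
      repressed = sum(syn$synergy_direction == "repressed"),
      by_criterion = as.list(table(syn$synergy_criterion[hits]))
    )
  }
  if (!is.null(fit$coloc_summary)) {
    report$coloc <- purrr::map(
      split(fit$coloc_summary, fit$coloc_summary$mark_group),
      function(r) as.list(r[, -1]))
  }
  if (!is.null(fit$control_summary)) {
    report$coloc_control <- purrr::map(
      split(fit$control_summary, fit$control_summary$mark_group),
      function(r) as.list(r[, -1]))
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param fit An `hs_pipeline` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  jsonlite::write_json(fit$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the stage output tables of a pipeline run
#'
#' Writes `probe_stats.tsv` (per-probe stats, calls, sections, codes),
#' `synergy_calls.tsv`, `coloc_classes.tsv`, `coloc_summary.json`,
#' `report.json` and a `gene_sets/` directory of one-symbol-per-line files,
#' for whichever stages ran.
#'
#' @param fit An `hs_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fit$assignments)) {
    readr::write_tsv(fit$assignments, file.path(dir, "probe_stats.tsv"),
                     progress = FALSE)
  }
  if (!is.null(fit$synergy)) {
    readr::write_tsv(fit$synergy, file.path(dir, "synergy_calls.tsv"),
                     progress = FALSE)
  }
  if (!is.null(fit$gene_sets)) {
    gs_dir <- file.path(dir, "gene_sets")
    dir.create(gs_dir, showWarnings = FALSE)
    for (lab in unique(fit$gene_sets$label)) {
      writeLines(fit$gene_sets$gene_symbol[fit$gene_sets$label == lab],
                 file.path(gs_dir, paste0("section_", lab, ".txt")))
    }
  }
  if (!is.null(fit$coloc_classes)) {
    wide <- tidyr::pivot_wider(fit$coloc_classes, names_from = "mark_group",
                               values_from = "class")
    readr::write_tsv(wide, file.path(dir, "coloc_classes.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(cohort = fit$coloc_summary, control = fit$control_summary),
      file.path(dir, "coloc_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_report(fit, file.path(dir, "report.json"))
  invisible(dir)
}

#' Min-max scale each row to [0, 1]
#'
#' Heatmap-style per-row scaling: `(x - row min) / (row max - row min)`.
#' Constant rows map to 0.5 everywhere (no within-row contrast). Output is
#' invariant to any positive affine transform of a row.
#'
#' @param expression Wide expression tibble (`probe_id` + numeric columns) or
#'   a numeric matrix.
#' @return Object of the same shape with scaled values.
#' @examples
#' row_scale(matrix(c(1, 2, 3), nrow = 1))
#' @export
row_scale <- function(expression) {
  is_tbl <- is.data.frame(expression)
  m <- if (is_tbl) as.matrix(expression[, -1, drop = FALSE]) else expression
  rng_min <- apply(m, 1, min)
  rng_max <- apply(m, 1, max)
  span <- rng_max - rng_min
  scaled <- (m - rng_min) / ifelse(span > 0, span, 1)
  scaled[span == 0, ] <- 0.5
  if (is_tbl) {
    dplyr::bind_cols(expression[, 1], tibble::as_tibble(scaled))
  } else {
    scaled
  }
}

#' @export
print.hs_pipeline <- function(x, ...) {
  cat("<hs_pipeline>\n")
  r <- x$report
  if (!is.null(r$de_lists)) {
    cat(sprintf("  DE probes: T3 %d | CORT %d | T3+CORT %d\n",
                r$de_lists$t3, r$de_lists$cort, r$de_lists$t3cort))
    vs <- unlist(r$venn_sections)
    cat("  Venn:", paste(sprintf("%s=%d", names(vs), vs), collapse = " "), "\n")
  }
  if (!is.null(r$synergy)) {
    cat(sprintf("  synergy: %d (%d induced, %d repressed)\n",
                r$synergy$total, r$synergy$induced, r$synergy$repressed))
  }
  if (!is.null(r$coloc)) {
    for (g in names(r$coloc)) {
      cat(sprintf("  coloc %s: %.2f%% of genes receptor-proximal\n",
                  g, r$coloc[[g]]$pct_any))
    }
  }
  if (!is.null(r$identities_ok)) {
    cat("  partition identities:", if (r$identities_ok) "ok" else "VIOLATED", "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline result
#'
#' One row per probe with the key per-probe results: fold changes, DE
#' directions, Venn section, pattern code and synergy call.
#'
#' @param x An `hs_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hs_pipeline <- function(x, ...) {
  if (is.null(x$synergy)) {
    abort("expression stage was not run; nothing to tidy")
  }
  x$synergy |>
    dplyr::select(dplyr::any_of(c(
      "probe_id", "fc_t3", "fc_cort", "fc_t3cort",
      "p_t3", "p_cort", "p_t3cort",
      "dir_t3", "dir_cort", "dir_t3cort",
      "venn_section", "pattern_code", "direction",
      "additive_expectation", "delta", "sd_margin", "welch_p",
      "synergy_criterion", "synergy_direction")))
}

#' One-row summary of a pipeline result
#'
#' @param x An `hs_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of headline counts and identity status.
#' @export
glance.hs_pipeline <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_probes = if (!is.null(x$assignments)) nrow(x$assignments) else NA_integer_,
    n_de_t3 = r$de_lists$t3 %||% NA_integer_,
    n_de_cort = r$de_lists$cort %||% NA_integer_,
    n_de_t3cort = r$de_lists$t3cort %||% NA_integer_,
    n_synergy = r$synergy$total %||% NA_integer_,
    n_synergy_induced = r$synergy$induced %||% NA_integer_,
    n_synergy_repressed = r$synergy$repressed %||% NA_integer_,
    identities_ok = r$identities_ok %||% NA
  )
}
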