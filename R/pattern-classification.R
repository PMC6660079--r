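#' Three-way Venn partition of DE calls
#'
#' Assigns every probe to one of the six regions of the three-way Venn
#' diagram of the T3, CORT and T3+CORT DE lists (direction is ignored at
#' this step):
#' * `a` — DE in T3 only;
#' * `b` — DE in CORT only;
#' * `c` — DE in the combined treatment only;
#' * `d` — DE in T3 and combined, not CORT;
#' * `e` — DE in CORT and combined, not T3;
#' * `f` — DE in all three;
#' * `none` — DE in no arm.
#'
#' @param calls Output of [call_de()].
#' @return `calls` with an added `venn_section` factor.
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 200, rng_seed = 1))
#' parts <- sim$expression |>
#'   treatment_stats(sim$design) |>
#'   call_de() |>
#'   venn_partition()
#' table(parts$venn_section)
#' @export
venn_partition <- function(calls) {
  t3 <- calls$dir_t3 != "ns"
  cort <- calls$dir_cort != "ns"
  comb <- calls$dir_t3cort != "ns"
  section <- dplyr::case_when(
    t3 & !cort & !comb ~ "a",
    !t3 & cort & !comb ~ "b",
    !t3 & !cort & comb ~ "c",
    t3 & !cort & comb ~ "d",
    !t3 & cort & comb ~ "e",
    t3 & cort & comb ~ "f",
    t3 & cort & !comb ~ "ab", # both singles, combined lost: outside a-f proper
    .default = "none"
  )
  # The ab overlap (DE in both singles but not combined) has no study code;
  # keep it distinct from `none` would break the partition identity, so fold
  # it into `none` but record how often it occurred.
  n_ab <- sum(section == "ab")
  if (n_ab > 0) {
    warn(sprintf("%d probe(s) DE in T3 and CORT but not combined; assigned section 'none'", n_ab))
    section[section == "ab"] <- "none"
  }
  calls$venn_section <- factor(section, levels = c(letters[1:6], "none"))
  calls
}

PATTERN_CODES <- c("A1", "B1", "B2", "C1", "C2", "D1", "D2", "D3",
                   "E1", "E2", "E3", "E4", "E5", "E6", "F1", "none")

#' Refine Venn intersections into regulation-pattern codes
#'
#' Genes in the Venn intersections (sections d, e, f) are further segregated
#' by testing whether the combined-treatment signal differs from the single
#' hormone's signal (two-sided Welch t-test on log2 signals at
#' `alpha_refine`). Codes follow the study taxonomy:
#' * section `a` -> `A1` (CORT abolishes the T3 response);
#' * section `b` -> `B1`/`B2` (T3 abolishes the CORT response; induced/repressed);
#' * section `c` -> `C1`/`C2` (combined-only response);
#' * section `d`: combined vs T3 — not significant -> `D3` (T3 response
#'   persists); significant with the combined response larger and in the same
#'   direction -> `D1` (enhanced); significant otherwise (reversed or
#'   reduced) -> `D2`;
#' * section `e`: combined vs CORT — not significant -> `E1`/`E2`;
#'   significant with |log2 FC combined| > |log2 FC CORT| -> `E3`/`E4`
#'   (T3 enhances the CORT response); significant and smaller -> `E5`/`E6`
#'   (T3 suppresses it);
#' * section `f` -> `F1` (no sub-test).
#'
#' For two-letter code pairs the odd code is the induced and the even code the
#' repressed variant; direction is taken from the combined treatment for
#' sections c-f and from the defining single hormone for a and b.
#'
#' @param parts Output of [venn_partition()].
#' @param expression,design The validated expression tibble and design (the
#'   refinement tests need the replicate-level signals).
#' @param thresholds An [hs_thresholds()] object.
#' @return `parts` with added `pattern_code`, `direction`, `refine_p_vs_t3`,
#'   `refine_p_vs_cort` columns.
#' @export
refine_patterns <- function(parts, expression, design,
                            thresholds = hs_thresholds()) {
  stopifnot(inherits(thresholds, "hs_thresholds"))
  design <- validate_design(design)
  expression <- expression[match(parts$probe_id, expression$probe_id), ]
  lm2 <- log2(.expr_matrix(expression, design))
  comb_log <- lm2[, .treatment_cols(design, "T3CORT"), drop = FALSE]
  w_t3 <- .welch_rows(comb_log, lm2[, .treatment_cols(design, "T3"), drop = FALSE])
  w_cort <- .welch_rows(comb_log, lm2[, .treatment_cols(design, "CORT"), drop = FALSE])

  section <- as.character(parts$venn_section)
  refine_p_t3 <- ifelse(section == "d", w_t3$p, NA_real_)
  refine_p_cort <- ifelse(section == "e", w_cort$p, NA_real_)

  # direction of the section's defining treatment
  dir_chr <- function(col) as.character(parts[[col]])
  direction <- dplyr::case_when(
    section == "a" ~ dir_chr("dir_t3"),
    section == "b" ~ dir_chr("dir_cort"),
    section %in% c("c", "d", "e", "f") ~ dir_chr("dir_t3cort"),
    .default = NA_character_
  )
  induced <- direction == "up"

  sig_d <- section == "d" & refine_p_t3 < thresholds$alpha_refine
  sig_e <- section == "e" & refine_p_cort < thresholds$alpha_refine
  same_dir_d <- as.character(parts$dir_t3) == as.character(parts$dir_t3cort)
  bigger_d <- abs(parts$log2fc_t3cort) > abs(parts$log2fc_t3)
  bigger_e <- abs(parts$log2fc_t3cort) > abs(parts$log2fc_cort)

  code <- dplyr::case_when(
    section == "a" ~ "A1",
    section == "b" & induced ~ "B1",
    section == "b" ~ "B2",
    section == "c" & induced ~ "C1",
    section == "c" ~ "C2",
    section == "d" & !sig_d ~ "D3",
    section == "d" & sig_d & same_dir_d & bigger_d ~ "D1",
    section == "d" ~ "D2",
    section == "e" & !sig_e & induced ~ "E1",
    section == "e" & !sig_e ~ "E2",
    section == "e" & sig_e & bigger_e & induced ~ "E3",
    section == "e" & sig_e & bigger_e ~ "E4",
    section == "e" & sig_e & induced ~ "E5",
    section == "e" & sig_e ~ "E6",
    section == "f" ~ "F1",
    .default = "none"
  )
  parts$pattern_code <- factor(code, levels = PATTERN_CODES)
  parts$direction <- factor(direction, levels = c("up", "down"))
  parts$refine_p_vs_t3 <- refine_p_t3
  parts$refine_p_vs_cort <- refine_p_cort
  parts
}

#' Collapse probe-level assignments to gene-level sets
#'
#' Joins probe annotation, drops probes without a gene symbol (counting
#' them), and collapses duplicate probes of one gene into a single entry.
#' When probes of the same gene disagree on their set, the probe with the
#' largest |log2 fold change| in its section's defining treatment (T3 for a,
#' CORT for b, combined otherwise) decides the gene's set.
#'
#' @param assignments Output of [refine_patterns()] (or [venn_partition()];
#'   grouping then uses `venn_section` only).
#' @param annotation Tibble `probe_id`, `gene_symbol` (empty/NA symbol =
#'   unannotated).
#' @param by Grouping column for the sets: `"venn_section"` (default) or
#'   `"pattern_code"`.
#' @return A tibble `label`, `gene_symbol`, one row per gene per set, with
#'   attributes `n_unannotated` (dropped probes) and `n_collapsed`
#'   (conflicting duplicates resolved).
#' @export
collapse_probes <- function(assignments, annotation,
                            by = c("venn_section", "pattern_code")) {
  by <- match.arg(by)
  if (!by %in% names(assignments)) {
    abort(sprintf("column '%s' not found; run the upstream stage first", by))
  }
  ann <- tibble::as_tibble(annotation)
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(ann)))
  if (anyDuplicated(ann$probe_id)) {
    abort("duplicate probe_id in annotation")
  }
  df <- dplyr::left_join(assignments, ann, by = "probe_id")
  section <- as.character(df$venn_section)
  df$defining_log2fc <- dplyr::case_when(
    section == "a" ~ df$log2fc_t3,
    section == "b" ~ df$log2fc_cort,
    .default = df$log2fc_t3cort
  )
  unannotated <- is.na(df$gene_symbol) | df$gene_symbol == ""
  n_unannotated <- sum(unannotated & df[[by]] != "none")
  df <- df[!unannotated & df[[by]] != "none", ]
  # one winning probe per gene across ALL sets: max |log2fc| in the defining
  # treatment, ties broken by probe_id for determinism
  df <- df |>
    dplyr::arrange(.data$gene_symbol, dplyr::desc(abs(.data$defining_log2fc)),
                   .data$probe_id)
  winners <- df[!duplicated(df$gene_symbol), ]
  n_collapsed <- nrow(df) - nrow(winners)
  out <- winners |>
    dplyr::transmute(label = as.character(.data[[by]]),
                     gene_symbol = .data$gene_symbol) |>
    dplyr::arrange(.data$label, .data$gene_symbol)
  attr(out, "n_unannotated") <- n_unannotated
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' Count probes per Venn section and pattern code
#'
#' @param assignments Output of [refine_patterns()].
#' @return A list with `sections` (named integer vector a-f, none),
#'   `codes` (named integer vector over the pattern codes), and `de_lists`
#'   (sizes of the three DE lists).
#' @export
pattern_counts <- function(assignments) {
  sections <- table(assignments$venn_section)
  codes <- table(assignments$pattern_code)
  de_lists <- c(
    t3 = sum(assignments$dir_t3 != "ns"),
    cort = sum(assignments$dir_cort != "ns"),
    t3cort = sum(assignments$dir_t3cort != "ns")
  )
  list(sections = c(sections), codes = c(codes), de_lists = de_lists)
}

#' Check the Venn partition identities
#'
#' The three DE list sizes must tile exactly into the Venn sections:
#' |T3| = a+d+f, |CORT| = b+e+f, |combined| = c+d+e+f, and the e-section
#' refinement must satisfy e = (E1+E2)+(E3+E4)+(E5+E6).
#'
#' @param assignments Output of [refine_patterns()].
#' @return `TRUE` if all identities hold, otherwise `FALSE` (with a warning
#'   naming the violated identity).
#' @export
check_partition_identities <- function(assignments) {
  ct <- pattern_counts(assignments)
  s <- ct$sections
  k <- function(code) if (code %in% names(ct$codes)) ct$codes[[code]] else 0L
  checks <- c(
    t3 = unname(ct$de_lists["t3"] == s[["a"]] + s[["d"]] + s[["f"]]),
    cort = unname(ct$de_lists["cort"] == s[["b"]] + s[["e"]] + s[["f"]]),
    t3cort = unname(ct$de_lists["t3cort"] ==
                      s[["c"]] + s[["d"]] + s[["e"]] + s[["f"]]),
    e_refine = unname(s[["e"]] ==
                        k("E1") + k("E2") + k("E3") + k("E4") + k("E5") + k("E6"))
  )
  if (!all(checks)) {
    warn(paste0("partition identity violated: ",
                paste(names(checks)[!checks], collapse = ", ")))
  }
  all(checks)
}
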