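#' Read an expression matrix and its experimental design
#'
#' Reads a tab-delimited expression table (first column `probe_id`, remaining
#' columns one per sample, header row of sample ids) together with a design
#' table (`sample_id`, `treatment`, `replicate`), validates the pair, reorders
#' the matrix columns to the design order, and floors signals at
#' `signal_floor` so fold-change ratios are always defined.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @param signal_floor Minimum stored signal (default 0.1 signal units).
#' @return A list with elements `expression` (tibble: `probe_id` plus one
#'   numeric column per sample, in design order) and `design` (tibble:
#'   `sample_id`, `treatment`, `replicate`).
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 20, rng_seed = 1))
#' td <- tempfile(); dir.create(td)
#' write_expression_table(sim$expression, file.path(td, "expr.tsv"))
#' readr::write_tsv(sim$design, file.path(td, "design.tsv"))
#' dat <- read_expression_table(file.path(td, "expr.tsv"),
#'                              file.path(td, "design.tsv"))
#' dim(dat$expression)
#' @export
read_expression_table <- function(path, design_path, signal_floor = 0.1) {
  stopifnot(file.exists(path), file.exists(design_path))
  design <- read_design(design_path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (names(raw)[1] != "probe_id") {
    names(raw)[1] <- "probe_id"
  }
  expression <- validate_expression(raw, design, signal_floor = signal_floor)
  list(expression = expression, design = design)
}

#' Read and validate a design table
#'
#' @param path Design TSV with columns `sample_id`, `treatment`
#'   (VEH/T3/CORT/T3CORT), `replicate`.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    treatment = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  validate_design(design)
}

#' Validate a design tibble
#'
#' Checks that every treatment arm is present, every (treatment, replicate)
#' pair is unique, and each arm has at least two replicates (variance must be
#' estimable; the study design has three).
#'
#' @param design Tibble with `sample_id`, `treatment`, `replicate`.
#' @return The design, invisibly unchanged, as a tibble.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  required <- c("sample_id", "treatment", "replicate")
  missing <- setdiff(required, names(design))
  if (length(missing)) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(design$treatment), TREATMENTS)
  if (length(bad)) {
    abort(paste0("unknown treatment label(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(TREATMENTS, collapse = "/"), ")"))
  }
  absent <- setdiff(TREATMENTS, design$treatment)
  if (length(absent)) {
    abort(paste0("design lacks treatment arm(s): ", paste(absent, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("duplicate sample_id in design")
  }
  if (anyDuplicated(design[, c("treatment", "replicate")])) {
    abort("duplicate (treatment, replicate) pair in design")
  }
  if (any(design$replicate < 1)) {
    abort("replicate indices must be positive")
  }
  n_per <- table(design$treatment)
  if (any(n_per < 2)) {
    abort("every treatment needs >= 2 replicates for variance estimation")
  }
  design
}

#' Validate an expression table against a design
#'
#' Rejects duplicate probe ids, samples missing from either side, missing and
#' non-numeric cells (naming the offending row and column), then reorders
#' columns to the design order and applies the signal floor.
#'
#' @param expression Tibble whose first column is `probe_id`; remaining
#'   columns are samples (character or numeric).
#' @param design A validated design tibble.
#' @param signal_floor Minimum stored signal.
#' @return The validated expression tibble (numeric, floored, design order).
#' @export
validate_expression <- function(expression, design, signal_floor = 0.1) {
  expression <- tibble::as_tibble(expression)
  if (names(expression)[1] != "probe_id") {
    abort("first expression column must be `probe_id`")
  }
  if (anyDuplicated(expression$probe_id)) {
    dups <- unique(expression$probe_id[duplicated(expression$probe_id)])
    abort(paste0("duplicate probe id(s): ", paste(head(dups, 5), collapse = ", ")))
  }
  file_samples <- setdiff(names(expression), "probe_id")
  missing_in_file <- setdiff(design$sample_id, file_samples)
  if (length(missing_in_file)) {
    abort(paste0("sample(s) in design but not in expression table: ",
                 paste(missing_in_file, collapse = ", ")))
  }
  extra_in_file <- setdiff(file_samples, design$sample_id)
  if (length(extra_in_file)) {
    abort(paste0("sample(s) in expression table but not in design: ",
                 paste(extra_in_file, collapse = ", ")))
  }
  sig <- expression[, design$sample_id, drop = FALSE]
  for (j in seq_along(sig)) {
    col <- sig[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(sprintf("non-numeric cell at probe '%s', sample '%s': '%s'",
                      expression$probe_id[bad[1]], names(sig)[j], col[bad[1]]))
      }
      col <- num
    }
    if (anyNA(col)) {
      abort(sprintf("missing value at probe '%s', sample '%s'",
                    expression$probe_id[which(is.na(col))[1]], names(sig)[j]))
    }
    if (any(!is.finite(col))) {
      abort(sprintf("non-finite signal at probe '%s', sample '%s'",
                    expression$probe_id[which(!is.finite(col))[1]], names(sig)[j]))
    }
    sig[[j]] <- .floor_signals(col, signal_floor)
  }
  dplyr::bind_cols(expression["probe_id"], sig)
}

#' Write an expression tibble as the canonical TSV
#'
#' @param expression Wide expression tibble (`probe_id` first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Import a GEO series-matrix expression table
#'
#' Convenience importer for the GEO `series_matrix.txt` layout: metadata lines
#' start with `!`; the signal table sits between `!series_matrix_table_begin`
#' and `!series_matrix_table_end` with an `ID_REF` probe column. The table is
#' returned in the canonical wide layout; pair it with a design table and
#' [validate_expression()] before analysis.
#'
#' @param path Path to an (uncompressed) series-matrix file.
#' @return A tibble with `probe_id` plus one column per GEO sample.
#' @export
read_series_matrix <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    abort("no series-matrix table found (missing begin/end markers)")
  }
  block <- lines[(begin + 1):(end - 1)]
  tab <- readr::read_tsv(I(paste(block, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE)
  names(tab)[1] <- "probe_id"
  tab$probe_id <- gsub('^"|"$', "", as.character(tab$probe_id))
  names(tab) <- gsub('^"|"$', "", names(tab))
  tibble::as_tibble(tab)
}
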