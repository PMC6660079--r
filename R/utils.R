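# Internal numerical helpers shared by the DE, refinement and synergy stages.

# Variance floor applied when every replicate is identical but group means
# differ, so the Welch statistic stays finite without flipping obvious calls.
VAR_FLOOR <- 1e-12

# Row-wise unbiased variance of a matrix (n - 1 denominator).
.row_var <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

# Vectorised two-sided Welch t-test over matrix rows: row i of mx vs row i of
# my. Zero-variance rows: p = 1 when the means agree, otherwise the variance
# floor keeps the statistic finite (and the call obvious). Returns a list of
# vectors (estimate, t, df, p).
.welch_rows <- function(mx, my) {
  nx <- ncol(mx); ny <- ncol(my)
  stopifnot(nx >= 2, ny >= 2)
  mean_x <- rowMeans(mx); mean_y <- rowMeans(my)
  vx <- .row_var(mx); vy <- .row_var(my)
  diff <- mean_x - mean_y
  se2 <- vx / nx + vy / ny
  degenerate <- se2 <= 0
  se2_eff <- ifelse(degenerate, VAR_FLOOR, se2)
  tval <- diff / sqrt(se2_eff)
  df_den <- (vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)
  df <- ifelse(df_den > 0, se2^2 / df_den, nx + ny - 2)
  p <- 2 * pt(-abs(tval), df)
  flat <- degenerate & diff == 0
  tval[flat] <- 0
  p[flat] <- 1
  list(estimate = diff, t = tval, df = df, p = p)
}

# Signal floor: raise values below `floor` (normalized intensities can be
# zero or negative after background subtraction) so ratios are defined.
.floor_signals <- function(x, floor) {
  x[x < floor] <- floor
  x
}

# Wide expression tibble (probe_id + one column per sample) -> numeric matrix
# with probe_id rownames, columns in design order.
.expr_matrix <- function(expression, design) {
  m <- as.matrix(expression[, design$sample_id, drop = FALSE])
  if (!is.numeric(m)) {
    abort("expression signals must all be numeric")
  }
  m
}

# Column indices of a design's samples for one treatment.
.treatment_cols <- function(design, treatment) {
  which(design$treatment == treatment)
}
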