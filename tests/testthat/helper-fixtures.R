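# In-code fixture builders shared across the suite.

fixture_design <- function(n_reps = 3) {
  treatments <- c("VEH", "T3", "CORT", "T3CORT")
  tibble::tibble(
    sample_id = paste0(rep(treatments, each = n_reps), "_",
                       rep(seq_len(n_reps), times = 4)),
    treatment = rep(treatments, each = n_reps),
    replicate = rep(seq_len(n_reps), times = 4)
  )
}

# probes: named list probe_id -> list(VEH = c(...), T3 = ..., CORT = ...,
# T3CORT = ...) with one replicate vector per treatment.
fixture_expression <- function(probes, design = fixture_design()) {
  rows <- lapply(names(probes), function(pid) {
    vals <- unlist(lapply(c("VEH", "T3", "CORT", "T3CORT"),
                          function(tr) probes[[pid]][[tr]]))
    stats::setNames(as.list(c(pid, vals)), c("probe_id", design$sample_id))
  })
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  df[-1] <- lapply(df[-1], as.numeric)
  df
}

# A probe with near-constant replicates around the given treatment means
# (spread +/- `jitter` so variances are small but nonzero).
probe_around <- function(veh, t3, cort, t3cort, jitter = 1) {
  spread <- c(-jitter, 0, jitter)
  list(VEH = veh + spread, T3 = t3 + spread,
       CORT = cort + spread, T3CORT = t3cort + spread)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                             max_width = 800) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}
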