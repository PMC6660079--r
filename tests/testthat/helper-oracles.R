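# Independent brute-force oracles used to validate the interval machinery.

# All-pairs minimum gap: for each query row, scan every subject row and apply
# the half-open gap formula directly.
bf_min_gap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- subject$chrom == query$chrom[i]
    if (!any(same)) return(Inf)
    s <- subject[same, ]
    min(pmax(s$start - query$end[i], query$start[i] - s$end, 0))
  }, numeric(1))
}

# Brute-force gene classification: enumerate every (receptor peak, mark peak)
# pair for every gene and apply the rule literally.
bf_classify <- function(loci, tracks, flank_bp, proximity_bp,
                        mark_groups = default_mark_groups()) {
  win_start <- pmax(0, loci$start - flank_bp)
  win_end <- loci$end + flank_bp
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  out <- list()
  for (group in names(mark_groups)) {
    members <- mark_groups[[group]]
    mark <- dplyr::bind_rows(lapply(intersect(members, names(tracks)),
                                    function(nm) tracks[[nm]]))
    if (nrow(mark) == 0) mark <- empty
    cls <- character(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      qualifies <- function(rec) {
        if (is.null(rec) || nrow(rec) == 0) return(FALSE)
        for (j in seq_len(nrow(rec))) {
          in_window <- rec$chrom[j] == loci$chrom[i] &&
            rec$start[j] < win_end[i] && rec$end[j] > win_start[i]
          if (!in_window) next
          if (nrow(mark) == 0) next
          gaps <- bf_min_gap(rec[j, ], mark)
          if (gaps <= proximity_bp) return(TRUE)
        }
        FALSE
      }
      gr <- qualifies(tracks[["GR"]])
      tr <- qualifies(tracks[["TR"]])
      cls[i] <- if (gr && tr) "both" else if (gr) "GR_only" else
        if (tr) "TR_only" else "none"
    }
    out[[group]] <- tibble::tibble(gene_symbol = loci$gene_symbol,
                                   mark_group = group, class = cls)
  }
  dplyr::bind_rows(out)
}
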