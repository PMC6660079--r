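# Genomic intervals are BED-convention throughout: 0-based, half-open
# [start, end). Book-ended intervals ([100,200) then [200,300)) have gap 0.

#' Default enhancer-mark groups
#'
#' H3K27Ac marks open chromatin; MED1 and MED12 (merged into one `MED` group,
#' union of both tracks) mark Mediator-bound looping candidates; RNA Pol2
#' marks candidate transcribed enhancers.
#'
#' @return Named list mapping group label to member track names.
#' @export
default_mark_groups <- function() {
  list(H3K27Ac = "H3K27Ac", MED = c("MED1", "MED12"), POL2 = "POL2")
}

#' Gene search window
#'
#' The mapping window is the gene body plus `flank_bp` on each side (the
#' study uses 50 kb beyond the transcription start and termination sites),
#' clamped at the chromosome origin. Both ends are flanked equally, so the
#' window is strand-independent.
#'
#' @param loci Tibble with `gene_symbol`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param flank_bp Flank in bp.
#' @return `loci` with added `window_start`, `window_end`.
#' @examples
#' loci <- tibble::tibble(gene_symbol = "g", chrom = "chr1",
#'                        start = 100000, end = 120000, strand = "+")
#' gene_window(loci, 50000)
#' @export
gene_window <- function(loci, flank_bp = 50000L) {
  stopifnot(all(loci$start < loci$end), flank_bp >= 0)
  loci$window_start <- pmax(0L, loci$start - flank_bp)
  loci$window_end <- loci$end + flank_bp
  loci
}

#' Gap between two genomic intervals
#'
#' Edge-to-edge distance in bp under the half-open convention: `Inf` when the
#' intervals sit on different chromosomes, 0 when they overlap or are
#' book-ended, otherwise the number of bases strictly between them.
#'
#' @param a,b Lists or one-row data frames with `chrom`, `start`, `end`;
#'   vectorised over rows when both have the same length.
#' @return Numeric vector of gaps.
#' @examples
#' iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)
#' interval_gap(iv("chr1", 100, 200), iv("chr1", 1100, 1300)) # 900
#' interval_gap(iv("chr1", 100, 200), iv("chr1", 200, 300))   # 0 (book-ended)
#' @export
interval_gap <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  gap <- pmax(b$start - a$end, a$start - b$end, 0)
  ifelse(a$chrom == b$chrom, gap, Inf)
}

# Minimum gap from each query interval to a set of subject intervals on one
# chromosome. Subjects must be sorted by start; uses a running maximum of
# subject ends so each query costs O(log n). Returns Inf when no subjects.
.min_gap_sorted <- function(q_start, q_end, s_start, s_end) {
  n_s <- length(s_start)
  if (n_s == 0L) return(rep(Inf, length(q_start)))
  cend <- cummax(s_end)
  # subjects with s_start < q_end (candidates for overlap or left neighbour)
  k <- findInterval(q_end - 0.5, s_start)
  left_gap <- ifelse(k > 0, pmax(q_start - cend[pmax(k, 1L)], 0), Inf)
  right_gap <- ifelse(k < n_s, s_start[pmin(k + 1L, n_s)] - q_end, Inf)
  pmin(left_gap, right_gap)
}

# Minimum gap from each row of `query` to any interval of `subject`,
# chromosome-aware. Both are tibbles with chrom/start/end.
.min_gap_track <- function(query, subject) {
  out <- rep(Inf, nrow(query))
  if (nrow(subject) == 0L || nrow(query) == 0L) return(out)
  subject <- subject[order(subject$chrom, subject$start), ]
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- subject$chrom == chr
    out[qi] <- .min_gap_sorted(query$start[qi], query$end[qi],
                               subject$start[si], subject$end[si])
  }
  out
}

# Union of the member tracks of one mark group as a single tibble.
.mark_group_track <- function(tracks, members) {
  present <- intersect(members, names(tracks))
  if (!length(present)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(lapply(tracks[present], function(t) t[, c("chrom", "start", "end")]))
}

#' Classify genes by receptor/enhancer-mark co-localization
#'
#' For each gene and each enhancer-mark group, a receptor (GR or TR) ChIP
#' peak counts when it at least partially overlaps the gene window
#' (gene body +/- `flank_bp`) *and* lies within `proximity_bp` (edge to edge)
#' of some peak of that mark group; the mark peak itself need not be inside
#' the window. The gene's class for that group is `both` when at least one GR
#' and one TR peak qualify, `GR_only`/`TR_only` when a single receptor does,
#' `none` otherwise.
#'
#' @param loci Gene loci tibble (`gene_symbol`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param tracks Named list of peak tibbles (`chrom`, `start`, `end`); must
#'   contain `GR` and/or `TR` plus mark tracks; absent tracks count as empty.
#' @param thresholds An [hs_thresholds()] object (`flank_bp`, `proximity_bp`).
#' @param mark_groups Named list mapping group labels to member track names
#'   (default [default_mark_groups()]).
#' @return Long tibble `gene_symbol`, `mark_group`, `class` (factor
#'   none/GR_only/TR_only/both).
#' @export
classify_genes <- function(loci, tracks, thresholds = hs_thresholds(),
                           mark_groups = default_mark_groups()) {
  stopifnot(inherits(thresholds, "hs_thresholds"))
  track_chroms <- unique(unlist(lapply(tracks, function(t) t$chrom)))
  if (length(track_chroms) && !any(track_chroms %in% loci$chrom)) {
    warn(paste0("no chromosome name shared between gene loci and peak tracks; ",
                "are all inputs on one assembly with one naming scheme?"))
  }
  win <- gene_window(loci, thresholds$flank_bp)
  receptors <- list(
    GR = tracks[["GR"]] %||% tibble::tibble(chrom = character(), start = integer(), end = integer()),
    TR = tracks[["TR"]] %||% tibble::tibble(chrom = character(), start = integer(), end = integer())
  )
  out <- vector("list", length(mark_groups))
  for (gi in seq_along(mark_groups)) {
    group <- names(mark_groups)[gi]
    mark <- .mark_group_track(tracks, mark_groups[[gi]])
    hit <- sapply(receptors, function(rec) {
      if (nrow(rec) == 0L) return(rep(FALSE, nrow(win)))
      proximal <- .min_gap_track(rec, mark) <= thresholds$proximity_bp
      vapply(seq_len(nrow(win)), function(i) {
        same <- rec$chrom == win$chrom[i] &
          rec$start < win$window_end[i] & rec$end > win$window_start[i]
        any(same & proximal)
      }, logical(1))
    })
    hit <- matrix(hit, nrow = nrow(win), dimnames = list(NULL, names(receptors)))
    cls <- dplyr::case_when(
      hit[, "GR"] & hit[, "TR"] ~ "both",
      hit[, "GR"] ~ "GR_only",
      hit[, "TR"] ~ "TR_only",
      .default = "none"
    )
    out[[gi]] <- tibble::tibble(gene_symbol = win$gene_symbol,
                                mark_group = group, class = cls)
  }
  res <- dplyr::bind_rows(out)
  res$class <- factor(res$class, levels = c("none", "GR_only", "TR_only", "both"))
  res$mark_group <- factor(res$mark_group, levels = names(mark_groups))
  res
}

#' Summarize co-localization fractions
#'
#' Per mark group: the percentage of genes with any qualifying receptor peak
#' (class other than `none`) and its breakdown into GR-only, TR-only and
#' both, each as `100 * count / total` reported to 2 decimal places.
#'
#' @param classes Output of [classify_genes()].
#' @return Tibble `mark_group`, `n_genes`, `n_any`, `pct_any`, `pct_gr_only`,
#'   `pct_tr_only`, `pct_both`.
#' @export
summarize_fractions <- function(classes) {
  if (nrow(classes) == 0L) {
    abort("no co-localization classes to summarize")
  }
  pct <- function(x, n) round(100 * x / n, 2)
  classes |>
    dplyr::group_by(.data$mark_group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_any = sum(.data$class != "none"),
      pct_any = pct(sum(.data$class != "none"), dplyr::n()),
      pct_gr_only = pct(sum(.data$class == "GR_only"), dplyr::n()),
      pct_tr_only = pct(sum(.data$class == "TR_only"), dplyr::n()),
      pct_both = pct(sum(.data$class == "both"), dplyr::n()),
      .groups = "drop"
    )
}

#' Sample a random control cohort of non-regulated genes
#'
#' Uniform sample without replacement from the annotation universe minus the
#' regulated genes, reproducible under the seed (the study uses 300 control
#' genes).
#'
#' @param universe Gene loci tibble.
#' @param exclude Character vector of gene symbols to exclude (the regulated
#'   genes).
#' @param n Cohort size.
#' @param rng_seed Integer seed.
#' @return Tibble of `n` sampled loci.
#' @export
sample_control_genes <- function(universe, exclude = character(), n = 300L,
                                 rng_seed = 1L) {
  pool <- universe[!universe$gene_symbol %in% exclude, ]
  if (nrow(pool) < n) {
    abort(sprintf("control universe too small: %d available, %d requested",
                  nrow(pool), n))
  }
  idx <- withr::with_seed(rng_seed, sample.int(nrow(pool), n))
  pool[sort(idx), ]
}

#' Read gene loci from a BED6 or TSV annotation
#'
#' BED6 (`chrom start end name score strand`) via rtracklayer, or a TSV with
#' columns `gene_symbol`, `chrom`, `start`, `end`, `strand`. Coordinates are
#' returned 0-based half-open with `tss`/`tts` derived from strand.
#'
#' @param path Annotation file.
#' @param format `"bed"` or `"tsv"` (guessed from the extension by default).
#' @return Loci tibble (`gene_symbol`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tts`).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    loci <- read_bed(path)
    names(loci)[names(loci) == "name"] <- "gene_symbol"
  } else {
    loci <- readr::read_tsv(path, col_types = readr::cols(
      gene_symbol = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      strand = readr::col_character()
    ), progress = FALSE)
  }
  make_loci(loci)
}

#' Derive TSS/TTS from stranded loci
#'
#' @param loci Tibble with `gene_symbol`, `chrom`, `start`, `end`, `strand`.
#' @return Same tibble with `tss` and `tts` columns (TSS = `start` on `+`,
#'   `end` on `-`).
#' @export
make_loci <- function(loci) {
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("gene_symbol", "chrom", "start", "end", "strand") %in% names(loci)),
            all(loci$start >= 0), all(loci$start < loci$end))
  loci$tss <- ifelse(loci$strand == "-", loci$end, loci$start)
  loci$tts <- ifelse(loci$strand == "-", loci$start, loci$end)
  loci
}

#' Read a BED peak or annotation file
#'
#' Parses with `rtracklayer::import()` (the canonical BED reader) and
#' converts back to the 0-based half-open tibble the mapping stage uses.
#'
#' @param path BED3+ file.
#' @return Tibble `chrom`, `start`, `end` (+ `name`, `strand` when present),
#'   sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED files requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # GRanges is 1-based closed
    end = GenomicRanges::end(gr)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) out$name <- mc$name
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", ".", st)
  out[order(out$chrom, out$start), ]
}

#' Write intervals as BED
#'
#' @param intervals Tibble `chrom`, `start`, `end` (+ optional `name`,
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  df <- intervals[, cols]
  if ("name" %in% names(intervals)) {
    df$name <- intervals$name
    df$score <- 0L
    if ("strand" %in% names(intervals)) df$strand <- intervals$strand
  }
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
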