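iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

test_that("gene windows flank both ends and clamp at the origin", {
  loci <- tibble::tibble(gene_symbol = c("g1", "g2", "g3"),
                         chrom = "chr1",
                         start = c(100000, 10000, 100000),
                         end = c(120000, 20000, 120000),
                         strand = c("+", "-", "+"))
  w <- gene_window(loci, 50000)
  expect_equal(w$window_start, c(50000, 0, 50000))
  expect_equal(w$window_end, c(170000, 70000, 170000))
  w0 <- gene_window(loci, 0)
  expect_equal(w0$window_start, loci$start)
  expect_equal(w0$window_end, loci$end)
})

test_that("interval_gap follows the half-open BED convention", {
  expect_equal(interval_gap(iv("chr1", 100, 200), iv("chr1", 150, 250)), 0)
  expect_equal(interval_gap(iv("chr1", 100, 200), iv("chr1", 1100, 1300)), 900)
  expect_equal(interval_gap(iv("chr1", 100, 200), iv("chr1", 200, 300)), 0)
  expect_equal(interval_gap(iv("chr1", 100, 200), iv("chr2", 100, 200)), Inf)
  # symmetric
  expect_equal(interval_gap(iv("chr1", 1100, 1300), iv("chr1", 100, 200)), 900)
})

test_that("interval_gap agrees with GenomicRanges::distance on random pairs", {
  skip_if_not_installed("GenomicRanges")
  set.seed(60)
  a <- random_intervals(300)
  b <- random_intervals(300)
  got <- interval_gap(a, b)
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  ref <- suppressWarnings(GenomicRanges::distance(gra, grb))
  ref <- ifelse(is.na(ref), Inf, ref)
  expect_equal(got, as.numeric(ref))
})

test_that("classify_genes applies the window and proximity rules", {
  loci <- tibble::tibble(gene_symbol = "g", chrom = "chr1",
                         start = 100000, end = 120000, strand = "+")
  th <- hs_thresholds() # +/- 50 kb window, 1 kb proximity
  marks <- list(H3K27Ac = iv("chr1", 61100, 61400))
  # no receptor tracks at all
  expect_equal(as.character(
    classify_genes(loci, marks, th)$class[1]), "none")
  # GR peak inside the window, 900 bp from the mark
  gr_near <- iv("chr1", 60000, 60200) # gap to mark = 61100 - 60200 = 900
  cls <- classify_genes(loci, c(marks, list(GR = gr_near)), th)
  expect_equal(as.character(cls$class[cls$mark_group == "H3K27Ac"]), "GR_only")
  # add a separately proximal TR peak -> both
  tr_near <- iv("chr1", 62000, 62200)
  marks2 <- list(H3K27Ac = dplyr::bind_rows(marks$H3K27Ac,
                                            iv("chr1", 62500, 62800)))
  cls2 <- classify_genes(loci, c(marks2, list(GR = gr_near, TR = tr_near)), th)
  expect_equal(as.character(cls2$class[cls2$mark_group == "H3K27Ac"]), "both")
  # receptor outside the window does not count even if mark-proximal
  gr_out <- iv("chr1", 500, 700)
  far_marks <- list(H3K27Ac = iv("chr1", 750, 900))
  cls3 <- classify_genes(loci, c(far_marks, list(GR = gr_out)), th)
  expect_equal(as.character(cls3$class[cls3$mark_group == "H3K27Ac"]), "none")
  # mark outside the window still qualifies a window-overlapping receptor
  gr_edge <- iv("chr1", 169000, 170100) # overlaps window end at 170000
  out_mark <- list(H3K27Ac = iv("chr1", 170500, 170800)) # gap 400, outside
  cls4 <- classify_genes(loci, c(out_mark, list(GR = gr_edge)), th)
  expect_equal(as.character(cls4$class[cls4$mark_group == "H3K27Ac"]), "GR_only")
  # gap just over the threshold -> none
  gr_far <- iv("chr1", 60000, 60098) # gap 61100 - 60098 = 1002
  cls5 <- classify_genes(loci, c(marks, list(GR = gr_far)), th)
  expect_equal(as.character(cls5$class[cls5$mark_group == "H3K27Ac"]), "none")
})

test_that("disjoint chromosome naming schemes trigger a compatibility warning", {
  loci <- tibble::tibble(gene_symbol = "g", chrom = "chr1",
                         start = 1000, end = 3000, strand = "+")
  tracks <- list(GR = iv("1", 1500, 1700), H3K27Ac = iv("1", 1800, 2000))
  expect_warning(classify_genes(loci, tracks), "assembly")
})

test_that("the sweep proximity engine matches the brute-force oracle exactly", {
  set.seed(77)
  for (rep in 1:100) {
    q <- random_intervals(sample(1:60, 1), max_pos = 50000)
    s <- random_intervals(sample(0:80, 1), max_pos = 50000)
    expect_identical(hormsynergy:::.min_gap_track(q, s), bf_min_gap(q, s))
  }
})

test_that("classification matches a brute-force all-pairs classifier", {
  set.seed(123)
  th <- hs_thresholds(flank_bp = 5000, proximity_bp = 800)
  for (rep in 1:12) {
    n_genes <- sample(3:8, 1)
    start <- sort(sample.int(3e5, n_genes))
    loci <- tibble::tibble(gene_symbol = paste0("g", seq_len(n_genes)),
                           chrom = sample(c("chr1", "chr2"), n_genes,
                                          replace = TRUE),
                           start = start, end = start + 2000,
                           strand = "+")
    tracks <- list(GR = random_intervals(120, max_pos = 3.2e5),
                   TR = random_intervals(120, max_pos = 3.2e5),
                   H3K27Ac = random_intervals(150, max_pos = 3.2e5),
                   MED1 = random_intervals(60, max_pos = 3.2e5),
                   MED12 = random_intervals(60, max_pos = 3.2e5),
                   POL2 = random_intervals(80, max_pos = 3.2e5))
    got <- classify_genes(loci, tracks, th)
    ref <- bf_classify(loci, tracks, th$flank_bp, th$proximity_bp)
    expect_equal(as.character(got$class), ref$class)
  }
})

test_that("growing the window or proximity never demotes a gene's class", {
  set.seed(42)
  rank_of <- function(cls) {
    c(none = 0, GR_only = 1, TR_only = 1, both = 2)[as.character(cls)]
  }
  loci <- tibble::tibble(gene_symbol = paste0("g", 1:6), chrom = "chr1",
                         start = seq(50000, 300000, by = 50000),
                         end = seq(52000, 302000, by = 50000), strand = "+")
  tracks <- list(GR = random_intervals(150, chroms = "chr1", max_pos = 4e5),
                 TR = random_intervals(150, chroms = "chr1", max_pos = 4e5),
                 H3K27Ac = random_intervals(200, chroms = "chr1", max_pos = 4e5))
  base <- classify_genes(loci, tracks, hs_thresholds(flank_bp = 2000,
                                                     proximity_bp = 300))
  for (params in list(c(2000, 1500), c(20000, 300), c(20000, 1500))) {
    grown <- classify_genes(loci, tracks,
                            hs_thresholds(flank_bp = params[1],
                                          proximity_bp = params[2]))
    expect_true(all(rank_of(grown$class) >= rank_of(base$class)))
  }
})

test_that("summarize_fractions reports exact percentages to 2 d.p.", {
  classes <- tibble::tibble(
    gene_symbol = paste0("g", 1:110),
    mark_group = factor("H3K27Ac"),
    class = factor(c(rep("GR_only", 23), rep("TR_only", 16), rep("both", 18),
                     rep("none", 53)),
                   levels = c("none", "GR_only", "TR_only", "both")))
  s <- summarize_fractions(classes)
  expect_equal(s$n_any, 57)
  expect_equal(s$pct_any, 51.82)
  expect_equal(s$pct_gr_only, 20.91)
  expect_equal(s$pct_tr_only, 14.55)
  expect_equal(s$pct_both, 16.36)
  # all-none cohort
  none <- dplyr::mutate(classes, class = factor("none", levels = levels(class)))
  expect_equal(summarize_fractions(none)$pct_any, 0)
  expect_error(summarize_fractions(classes[0, ]), "summarize")
})

test_that("control-gene sampling is seeded, exclusive and exhaustive", {
  loci <- tibble::tibble(gene_symbol = paste0("g", 1:50), chrom = "chr1",
                         start = 1:50 * 1000, end = 1:50 * 1000 + 500,
                         strand = "+")
  excl <- paste0("g", 1:10)
  s1 <- sample_control_genes(loci, excl, n = 20, rng_seed = 99)
  s2 <- sample_control_genes(loci, excl, n = 20, rng_seed = 99)
  expect_identical(s1, s2)
  expect_length(intersect(s1$gene_symbol, excl), 0)
  s3 <- sample_control_genes(loci, excl, n = 40, rng_seed = 1)
  expect_setequal(s3$gene_symbol, setdiff(loci$gene_symbol, excl))
  expect_error(sample_control_genes(loci, excl, n = 41), "too small")
})

test_that("BED files round-trip through the importer", {
  skip_if_not_installed("rtracklayer")
  peaks <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                          start = c(100, 5000, 20),
                          end = c(600, 5400, 400),
                          name = c("pk1", "pk2", "pk3"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, path)
  got <- read_bed(path)
  expect_equal(got$chrom, peaks$chrom)
  expect_equal(got$start, peaks$start)
  expect_equal(got$end, peaks$end)
  expect_equal(got$name, peaks$name)
})
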