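# Synthetic-data generators. Both emit the same tabular formats the pipeline
# consumes, plus machine-readable truth labels, so every stage can be tested
# against known ground truth without any download.

#' Default planted regulation classes
#'
#' One row per planted class: the fraction of probes, the log2 effect of each
#' single hormone, the departure of the combined treatment from additivity
#' (`dep`, log2), the Venn section the class should land in, and whether the
#' class is synergistic by construction (departure on the same side as the
#' combined response). Effects are signed per probe: half of each class is
#' induced, half repressed (all effects flipped). The mix is CORT-rich and
#' T3-poor, echoing the hormone-response asymmetry of the study system.
#'
#' Classes (log2 effects, induced variant):
#' * `t3_only`: T3 +1.5, combined response abolished (section a);
#' * `cort_only`: CORT +1.5, abolished in combined (section b);
#' * `combined_only`: no single effects, combined departs +1.5 — ten pooled
#'   noise SDs at the default noise — (section c, synergistic);
#' * `t3_combined`: T3 +1.5 persisting unchanged in combined (section d);
#' * `cort_combined`: CORT +1.5, exactly additive in combined (section e);
#' * `e_enhanced`: CORT +1.2, combined +1.0 beyond additive (section e,
#'   E3-style, synergistic);
#' * `e_suppressed`: CORT +1.5, combined 0.6 below additive but still
#'   responsive (section e, E5-style — suppression, not synergy);
#' * `all_three`: T3 +1.0 and CORT +1.0, additive combined (section f).
#'
#' @return Tibble `class`, `fraction`, `eff_t3`, `eff_cort`, `dep`,
#'   `section`, `synergistic`.
#' @export
sim_pattern_classes <- function() {
  tibble::tribble(
    ~class,          ~fraction, ~eff_t3, ~eff_cort, ~dep,  ~section, ~synergistic,
    "t3_only",       0.002,     1.5,     0,         -1.5,  "a",      FALSE,
    "cort_only",     0.020,     0,       1.5,       -1.5,  "b",      FALSE,
    "combined_only", 0.015,     0,       0,          1.5,  "c",      TRUE,
    "t3_combined",   0.001,     1.5,     0,          0,    "d",      FALSE,
    "cort_combined", 0.020,     0,       1.5,        0,    "e",      FALSE,
    "e_enhanced",    0.004,     0,       1.2,        1.0,  "e",      TRUE,
    "e_suppressed",  0.004,     0,       1.5,       -0.6,  "e",      FALSE,
    "all_three",     0.002,     1.0,     1.0,        0,    "f",      FALSE
  )
}

#' Expression-simulation configuration
#'
#' Log-normal signal model: per probe a baseline log2 level is drawn, class
#' effects are added per treatment (vehicle = baseline; singles = baseline +
#' own effect; combined = baseline + both effects + departure), i.i.d.
#' replicate noise is added in log2 space, and signals are exponentiated.
#' Additive log2 effects match ratio-based fold-change analysis and keep
#' signals positive.
#'
#' @param n_probes Number of probes.
#' @param n_reps Replicates per treatment (study design: 3).
#' @param baseline_log2_mean,baseline_log2_sd Baseline level distribution.
#' @param replicate_noise_sd Replicate noise SD in log2 units.
#' @param classes Planted-class tibble (see [sim_pattern_classes()]);
#'   fractions must sum to at most 1, the remainder being null probes.
#' @param rng_seed Integer seed.
#' @return A list with class `"sim_expression_config"`.
#' @export
sim_expression_config <- function(n_probes = 10000L, n_reps = 3L,
                                  baseline_log2_mean = 7,
                                  baseline_log2_sd = 1.5,
                                  replicate_noise_sd = 0.15,
                                  classes = sim_pattern_classes(),
                                  rng_seed = 1L) {
  stopifnot(n_probes >= 1, n_reps >= 2, replicate_noise_sd > 0,
            baseline_log2_sd >= 0)
  classes <- tibble::as_tibble(classes)
  if (sum(classes$fraction) > 1) {
    abort("planted class fractions sum to more than 1")
  }
  structure(list(n_probes = as.integer(n_probes), n_reps = as.integer(n_reps),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 classes = classes, rng_seed = as.integer(rng_seed)),
            class = "sim_expression_config")
}

#' Simulate an expression matrix with planted regulation structure
#'
#' @param config A [sim_expression_config()].
#' @return List with `expression` (wide tibble), `design`, and `truth`
#'   (tibble `probe_id`, `class`, `direction`, `section`, `synergistic`,
#'   `eff_t3`, `eff_cort`, `dep` — signed per-probe effects). Identical
#'   configs give bit-identical output.
#' @examples
#' sim <- simulate_expression(sim_expression_config(n_probes = 100, rng_seed = 7))
#' table(sim$truth$class)
#' @export
simulate_expression <- function(config = sim_expression_config()) {
  stopifnot(inherits(config, "sim_expression_config"))
  n <- config$n_probes
  cls <- config$classes
  counts <- pmin(round(cls$fraction * n), n)
  if (sum(counts) > n) {
    abort("planted class counts exceed n_probes")
  }
  class_vec <- rep("null", n)
  idx <- 1L
  for (i in seq_len(nrow(cls))) {
    if (counts[i] > 0) {
      class_vec[idx:(idx + counts[i] - 1L)] <- cls$class[i]
      idx <- idx + counts[i]
    }
  }
  probe_id <- sprintf("probe_%05d", seq_len(n))
  lk <- match(class_vec, cls$class)
  eff_t3 <- ifelse(is.na(lk), 0, cls$eff_t3[lk])
  eff_cort <- ifelse(is.na(lk), 0, cls$eff_cort[lk])
  dep <- ifelse(is.na(lk), 0, cls$dep[lk])
  section <- ifelse(is.na(lk), "none", cls$section[lk])
  synergistic <- ifelse(is.na(lk), FALSE, cls$synergistic[lk])
  # first half of each class induced, second half repressed
  sign <- rep(1, n)
  for (i in seq_len(nrow(cls))) {
    members <- which(class_vec == cls$class[i])
    if (length(members) > 1) {
      flip <- members[(floor(length(members) / 2) + 1L):length(members)]
      sign[flip] <- -1
    }
  }
  eff_t3 <- sign * eff_t3; eff_cort <- sign * eff_cort; dep <- sign * dep
  direction <- dplyr::case_when(class_vec == "null" ~ "none",
                                sign > 0 ~ "induced",
                                .default = "repressed")

  design <- tibble::tibble(
    sample_id = paste0(rep(TREATMENTS, each = config$n_reps), "_",
                       rep(seq_len(config$n_reps), times = length(TREATMENTS))),
    treatment = rep(TREATMENTS, each = config$n_reps),
    replicate = rep(seq_len(config$n_reps), times = length(TREATMENTS))
  )
  mu <- cbind(VEH = 0, T3 = eff_t3, CORT = eff_cort,
              T3CORT = eff_t3 + eff_cort + dep)
  signals <- withr::with_seed(config$rng_seed, {
    baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    m <- matrix(0, n, nrow(design))
    for (j in seq_len(nrow(design))) {
      m[, j] <- 2^(baseline + mu[, design$treatment[j]] +
                     rnorm(n, 0, config$replicate_noise_sd))
    }
    m
  })
  colnames(signals) <- design$sample_id
  expression <- dplyr::bind_cols(tibble::tibble(probe_id = probe_id),
                                 tibble::as_tibble(signals))
  truth <- tibble::tibble(probe_id = probe_id, class = class_vec,
                          direction = direction, section = section,
                          synergistic = synergistic,
                          eff_t3 = eff_t3, eff_cort = eff_cort, dep = dep)
  list(expression = expression, design = design, truth = truth)
}

#' Default planted co-localization fractions
#'
#' Per mark group, the fraction of genes planted as GR-only, TR-only or both
#' (the remainder is `none`). Defaults mirror the study cohort's observed
#' breakdown so a 110-gene simulation reproduces its printed percentages.
#'
#' @return Tibble `mark_group`, `frac_gr_only`, `frac_tr_only`, `frac_both`.
#' @export
sim_planted_fractions <- function() {
  tibble::tribble(
    ~mark_group, ~frac_gr_only, ~frac_tr_only, ~frac_both,
    "H3K27Ac",   0.2090,        0.1454,        0.1636,
    "MED",       0.1818,        0.1727,        0.1182,
    "POL2",      0.1091,        0.0818,        0.0909
  )
}

#' Track-simulation configuration
#'
#' @param n_genes Number of gene loci.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param gene_length_range,peak_width_range Ranges (bp) for gene and peak
#'   sizes.
#' @param planted Planted class fractions per mark group
#'   (see [sim_planted_fractions()]).
#' @param flank_bp,proximity_bp Window flank and proximity threshold the
#'   plants are calibrated against.
#' @param margin_bp Safety margin around `proximity_bp`: proximal plants stay
#'   at least this far below the threshold and negatives this far above it,
#'   so no coordinate convention can flip a truth label.
#' @param intergenic_decoys Place receptor+mark decoy pairs between gene
#'   windows (they must never classify).
#' @param rng_seed Integer seed.
#' @return A list with class `"sim_track_config"`.
#' @export
sim_track_config <- function(n_genes = 110L,
                             chrom_sizes = c(chr1 = 8e6, chr2 = 8e6),
                             gene_length_range = c(2000L, 20000L),
                             peak_width_range = c(200L, 600L),
                             planted = sim_planted_fractions(),
                             flank_bp = 50000L, proximity_bp = 1000L,
                             margin_bp = 2L, intergenic_decoys = TRUE,
                             rng_seed = 1L) {
  planted <- tibble::as_tibble(planted)
  stopifnot(n_genes >= 1, all(chrom_sizes > 0),
            all(planted$frac_gr_only + planted$frac_tr_only + planted$frac_both <= 1),
            all(c(planted$frac_gr_only, planted$frac_tr_only, planted$frac_both) >= 0),
            gene_length_range[1] > 0, peak_width_range[1] > 0, margin_bp >= 1)
  structure(list(n_genes = as.integer(n_genes), chrom_sizes = chrom_sizes,
                 gene_length_range = as.integer(gene_length_range),
                 peak_width_range = as.integer(peak_width_range),
                 planted = planted, flank_bp = as.integer(flank_bp),
                 proximity_bp = as.integer(proximity_bp),
                 margin_bp = as.integer(margin_bp),
                 intergenic_decoys = isTRUE(intergenic_decoys),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_track_config")
}

#' Simulate gene loci and peak tracks with planted co-localization
#'
#' Genes are laid out without window overlap on the synthetic chromosomes.
#' Each gene window is divided into well-separated slots, one per
#' (mark group, receptor) pair plus one negative slot per mark group; a
#' planted proximal pair places a receptor peak and a mark peak at an
#' edge-to-edge gap at most `proximity_bp - margin_bp`; a planted negative
#' places them `proximity_bp + margin_bp` or more apart. MED-group mark
#' peaks alternate between the MED1 and MED12 tracks to exercise the track
#' union. Optional intergenic decoy pairs sit outside every window.
#'
#' @param config A [sim_track_config()].
#' @return List with `loci` (tibble), `tracks` (named list of interval
#'   tibbles: GR, TR, H3K27Ac, MED1, MED12, POL2), and `truth` (tibble
#'   `gene_symbol`, `mark_group`, `class`). Deterministic under the seed.
#' @examples
#' sim <- simulate_tracks(sim_track_config(n_genes = 10, rng_seed = 3))
#' sim$truth |> dplyr::count(mark_group, class)
#' @export
simulate_tracks <- function(config = sim_track_config()) {
  stopifnot(inherits(config, "sim_track_config"))
  withr::with_seed(config$rng_seed, .simulate_tracks_impl(config))
}

.simulate_tracks_impl <- function(config) {
  n <- config$n_genes
  groups <- config$planted$mark_group
  spacing <- 4L * (config$proximity_bp + config$margin_bp) + 2000L

  gene_len <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                     n, replace = TRUE)
  span <- gene_len + 2L * config$flank_bp
  # sequential placement, chromosome by chromosome
  chrom <- character(n); gstart <- integer(n)
  ci <- 1L; cursor <- spacing
  chrom_names <- names(config$chrom_sizes)
  for (i in seq_len(n)) {
    while (cursor + span[i] + spacing > config$chrom_sizes[ci]) {
      ci <- ci + 1L
      if (ci > length(config$chrom_sizes)) {
        abort("chromosomes too small for the requested number of genes")
      }
      cursor <- spacing
    }
    chrom[i] <- chrom_names[ci]
    gstart[i] <- cursor + config$flank_bp
    cursor <- cursor + span[i] + spacing
  }
  loci <- tibble::tibble(
    gene_symbol = sprintf("gene_%03d", seq_len(n)),
    chrom = chrom, start = gstart, end = gstart + gene_len,
    strand = rep(c("+", "-"), length.out = n)
  )
  loci <- make_loci(loci)

  # planted class per gene per mark group (deterministic counts, seeded
  # assignment order)
  truth <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    fr <- config$planted[gi, ]
    n_gr <- round(fr$frac_gr_only * n); n_tr <- round(fr$frac_tr_only * n)
    n_both <- round(fr$frac_both * n)
    cls <- rep("none", n)
    ord <- sample.int(n)
    cls[ord[seq_len(n_gr)]] <- "GR_only"
    if (n_tr > 0) cls[ord[n_gr + seq_len(n_tr)]] <- "TR_only"
    if (n_both > 0) cls[ord[n_gr + n_tr + seq_len(n_both)]] <- "both"
    truth[[gi]] <- tibble::tibble(gene_symbol = loci$gene_symbol,
                                  mark_group = groups[gi], class = cls)
  }
  truth <- dplyr::bind_rows(truth)

  peak_w <- function(k) sample(config$peak_width_range[1]:config$peak_width_range[2],
                               k, replace = TRUE)
  prox_gap <- function(k) sample(0:(config$proximity_bp - config$margin_bp),
                                 k, replace = TRUE)
  far_gap <- function(k) config$proximity_bp + config$margin_bp +
    sample(0:500, k, replace = TRUE)

  recs <- vector("list", 8L * n * length(groups))
  n_rec <- 0L
  add <- function(track, chrom, start, end) {
    n_rec <<- n_rec + 1L
    recs[[n_rec]] <<- list(track = track, chrom = chrom,
                           start = as.integer(start), end = as.integer(end))
  }
  mark_track_of <- function(group, i) {
    if (group == "MED") c("MED1", "MED12")[(i %% 2L) + 1L] else
      if (group == "POL2") "POL2" else group
  }

  n_slots <- 3L * length(groups)
  win_start <- pmax(0L, loci$start - config$flank_bp)
  win_end <- loci$end + config$flank_bp
  slot_w <- (win_end - win_start) %/% n_slots
  if (any(slot_w < 2L * max(config$peak_width_range) +
          config$proximity_bp + config$margin_bp + 600L)) {
    abort("gene windows too small for peak slot layout; increase flank or shrink peaks")
  }
  for (gi in seq_along(groups)) {
    group <- groups[gi]
    g_truth <- truth[truth$mark_group == group, ]
    for (i in seq_len(n)) {
      cls <- g_truth$class[i]
      base <- win_start[i] + (3L * (gi - 1L)) * slot_w[i]
      place_pair <- function(slot, receptor, gap) {
        s <- base + (slot - 1L) * slot_w[i] + 100L
        w1 <- peak_w(1); w2 <- peak_w(1)
        add(receptor, loci$chrom[i], s, s + w1)
        add(mark_track_of(group, i), loci$chrom[i], s + w1 + gap, s + w1 + gap + w2)
      }
      if (cls %in% c("GR_only", "both")) place_pair(1L, "GR", prox_gap(1))
      if (cls %in% c("TR_only", "both")) place_pair(2L, "TR", prox_gap(1))
      if (cls == "GR_only") place_pair(2L, "TR", far_gap(1))
      if (cls == "TR_only") place_pair(1L, "GR", far_gap(1))
      if (cls == "none") {
        place_pair(3L, "GR", far_gap(1))
      }
    }
  }
  if (config$intergenic_decoys) {
    # receptor+mark pairs in the gaps between windows: outside every gene
    # window, so they must never contribute to a class
    for (i in seq_len(n - 1L)) {
      if (loci$chrom[i] != loci$chrom[i + 1L]) next
      gap_start <- win_end[i]; gap_end <- win_start[i + 1L]
      if (gap_end - gap_start < spacing) next
      mid <- (gap_start + gap_end) %/% 2L
      w <- peak_w(2)
      add(if (i %% 2L) "GR" else "TR", loci$chrom[i], mid, mid + w[1])
      add(groups[(i %% length(groups)) + 1L] |> mark_track_of(i),
          loci$chrom[i], mid + w[1] + 50L, mid + w[1] + 50L + w[2])
    }
  }
  all_peaks <- dplyr::bind_rows(recs[seq_len(n_rec)])
  tracks <- lapply(split(all_peaks[, c("chrom", "start", "end")], all_peaks$track),
                   function(t) tibble::as_tibble(t[order(t$chrom, t$start), ]))
  # every canonical track key exists even if empty
  for (nm in c("GR", "TR", "H3K27Ac", "MED1", "MED12", "POL2")) {
    if (is.null(tracks[[nm]]) && nm %in% c("GR", "TR")) {
      tracks[[nm]] <- tibble::tibble(chrom = character(), start = integer(),
                                     end = integer())
    }
  }
  truth$class <- factor(truth$class,
                        levels = c("none", "GR_only", "TR_only", "both"))
  truth$mark_group <- factor(truth$mark_group, levels = groups)
  list(loci = loci, tracks = tracks, truth = truth)
}
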