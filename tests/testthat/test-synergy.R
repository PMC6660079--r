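test_that("additive expectation follows the selected convention", {
  expect_equal(additive_expectation(300, 380, 100), 580)
  expect_equal(additive_expectation(300, 380, 100, mode = "literal_sum"), 680)
  expect_equal(additive_expectation(100, 100, 100), 100)
  expect_error(additive_expectation(1, 1, 1, mode = "nope"))
})

test_that("an exactly additive probe gives t = 0, p = 1", {
  design <- fixture_design()
  expr <- fixture_expression(list(p = probe_around(100, 300, 380, 580)))
  w <- welch_sum_test(treatment_stats(expr, design))
  expect_equal(w$additive_expectation, 580)
  expect_equal(w$delta, 0)
  expect_equal(w$welch_t, 0)
  expect_equal(w$welch_p, 1)
})

test_that("literal-sum test with a zero-variance arm matches the textbook
           two-sample Welch computation", {
  design <- fixture_design()
  # combined (650,700,750): mean 700, var 2500; T3 (250,300,350): var 2500;
  # CORT constant at 380 contributes no variance -> the statistic reduces to
  # a plain two-sample Welch test of 700 +/- 50 vs 680 +/- 50, n = 3 each.
  expr <- fixture_expression(list(p = list(
    VEH = c(90, 100, 110), T3 = c(250, 300, 350),
    CORT = c(380, 380, 380), T3CORT = c(650, 700, 750))))
  w <- welch_sum_test(treatment_stats(expr, design), mode = "literal_sum")
  # independent closed-form oracle
  se2 <- 2500 / 3 + 2500 / 3
  t_ref <- (700 - 680) / sqrt(se2)
  df_ref <- se2^2 / ((2500 / 3)^2 / 2 + (2500 / 3)^2 / 2)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(w$additive_expectation, 680)
  expect_equal(w$welch_t, t_ref, tolerance = 1e-12)
  expect_equal(w$welch_df, df_ref, tolerance = 1e-12)
  expect_equal(w$welch_p, p_ref, tolerance = 1e-12)
})

synergy_one <- function(veh, t3, cort, t3cort, jitter = 1, ...) {
  design <- fixture_design()
  expr <- fixture_expression(list(p = probe_around(veh, t3, cort, t3cort,
                                                   jitter = jitter)))
  expr |>
    treatment_stats(design) |>
    call_de(hs_thresholds(...)) |>
    venn_partition() |>
    call_synergy(hs_thresholds(...))
}

test_that("criterion 1 fires for combined-only responses", {
  s <- synergy_one(100, 100, 100, 400)
  expect_equal(as.character(s$synergy_criterion), "both")
  expect_equal(as.character(s$synergy_direction), "induced")
  # combined-only without a greater-than-additive margin is still criterion 1:
  # singles just under the FC cut-off, combined just over it but below the
  # additive expectation
  s2 <- synergy_one(100, 140, 140, 170)
  expect_equal(as.character(s2$dir_t3), "ns")
  expect_equal(as.character(s2$synergy_criterion), "combined_only")
})

test_that("criterion 2 fires for the greater-than-additive configuration", {
  # FC triple (2.61, 3.78, 10.52): combined far above the additive
  # expectation of 5.39x
  s <- synergy_one(100, 261, 378, 1052, jitter = 5)
  expect_equal(as.character(s$venn_section), "f")
  expect_equal(as.character(s$synergy_criterion), "greater_than_additive")
  expect_equal(as.character(s$synergy_direction), "induced")
  expect_equal(s$additive_expectation, 539)
  expect_equal(s$sd_margin, sqrt(s$var_t3 + s$var_cort))
  expect_gte(abs(s$delta), s$sd_margin)
  expect_lt(s$welch_p, 0.02)
})

test_that("synergistic repression mirrors induction", {
  s <- synergy_one(400, 390, 380, 100)
  expect_equal(as.character(s$dir_t3), "ns")
  expect_equal(as.character(s$dir_cort), "ns")
  expect_equal(as.character(s$dir_t3cort), "down")
  expect_true(as.character(s$synergy_criterion) %in% c("both", "combined_only"))
  expect_equal(as.character(s$synergy_direction), "repressed")
  expect_lt(s$delta, 0)
})

test_that("suppressed responses on the wrong side are never called synergy", {
  # CORT induces 8x; the combined response (3x) is below the additive
  # expectation: a suppressed response, not synergistic repression
  s <- synergy_one(100, 100, 800, 300)
  expect_equal(as.character(s$dir_t3cort), "up")
  expect_lt(s$delta, 0)
  expect_equal(as.character(s$synergy_criterion), "none")
  # exactly additive -> none
  s2 <- synergy_one(100, 300, 380, 580)
  expect_equal(as.character(s2$synergy_criterion), "none")
})

test_that("criterion 2 is invariant to rescaling all signals", {
  design <- fixture_design()
  sim <- simulate_expression(sim_expression_config(n_probes = 400, rng_seed = 21))
  run <- function(k) {
    e <- sim$expression
    e[-1] <- e[-1] * k
    e |>
      treatment_stats(design) |>
      call_de() |>
      call_synergy()
  }
  s1 <- run(1); s2 <- run(11.3)
  expect_equal(as.character(s2$synergy_criterion),
               as.character(s1$synergy_criterion))
  expect_equal(s2$welch_t, s1$welch_t, tolerance = 1e-9)
})

test_that("the synergy set equals section c plus intersection criterion-2 hits", {
  sim <- simulate_expression(sim_expression_config(n_probes = 4000, rng_seed = 6))
  syn <- suppressWarnings(
    sim$expression |>
      treatment_stats(sim$design) |>
      call_de() |>
      venn_partition() |>
      call_synergy())
  called <- syn$probe_id[syn$synergy_criterion != "none"]
  section_c <- syn$probe_id[syn$venn_section == "c"]
  crit2 <- syn$probe_id[syn$synergy_criterion %in%
                          c("greater_than_additive", "both")]
  intersection_hits <- intersect(crit2,
                                 syn$probe_id[syn$venn_section %in% c("d", "e", "f")])
  expect_setequal(called, union(section_c, intersection_hits))
  # induced and repressed are mutually exclusive and exhaust the calls
  expect_equal(sum(syn$synergy_direction != "none"), length(called))
})

test_that("all-zero variances with zero departure give p = 1, not NaN", {
  design <- fixture_design()
  expr <- fixture_expression(list(p = list(
    VEH = rep(100, 3), T3 = rep(200, 3), CORT = rep(300, 3),
    T3CORT = rep(400, 3))))
  w <- welch_sum_test(treatment_stats(expr, design))
  expect_equal(w$delta, 0)
  expect_equal(w$welch_p, 1)
})

test_that("synergy_tables ranks by combined fold change", {
  sim <- simulate_expression(sim_expression_config(n_probes = 2000, rng_seed = 13))
  syn <- suppressWarnings(
    sim$expression |>
      treatment_stats(sim$design) |>
      call_de() |>
      venn_partition() |>
      call_synergy())
  tabs <- synergy_tables(syn, n = 10)
  expect_lte(nrow(tabs$induced), 10)
  expect_true(!is.unsorted(rev(tabs$induced$fc_t3cort)))
  expect_true(!is.unsorted(tabs$repressed$fc_t3cort))
  expect_true(all(tabs$repressed$fc_t3cort < 1))
})
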