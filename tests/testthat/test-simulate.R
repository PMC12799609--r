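test_that("the generator is deterministic for a fixed seed", {
  a <- generate_enrichment(enrichment_config(), seed = 42)
  b <- generate_enrichment(enrichment_config(), seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "ground_truth")$endpoint_draws,
                   attr(b, "ground_truth")$endpoint_draws)
  c_ <- generate_enrichment(enrichment_config(), seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
})

test_that("zero noise places every cycle exactly at the configured means", {
  cfg <- enrichment_config(rel_sd = 0)
  ds <- generate_enrichment(cfg, seed = 1)
  sm <- summarize_generation(ds)
  g3 <- sm[sm$generation == "G3" & sm$culture == "RF", ]
  expect_equal(g3$bicarb_reduction_pct, rep(55.4, 3), tolerance = 1e-9)
  g4 <- sm[sm$generation == "G4" & sm$culture == "AC", ]
  expect_equal(g4$co2_consumed_pct, rep(54.8, 3), tolerance = 1e-9)
  expect_equal(sm$vfa_end_g_per_l[sm$culture == "Blend" &
                                    sm$generation == "G1"],
               rep(3.467, 3), tolerance = 1e-9)
})

test_that("generated trajectories respect physical bounds and monotonicity", {
  ds <- generate_enrichment(enrichment_config(), seed = 7)
  expect_true(all(ds$bicarbonate_g_per_l >= 0))
  expect_true(all(ds$vfa_g_per_l >= 0))
  expect_true(all(ds$ph >= 0 & ds$ph <= 14))
  expect_true(all(is.na(ds$co2_consumed_pct) |
                    (ds$co2_consumed_pct >= 0 & ds$co2_consumed_pct <= 100)))
  by_cycle <- split(ds, interaction(ds$culture, ds$generation, ds$cycle))
  for (cyc in by_cycle) {
    cyc <- cyc[order(cyc$time_h), ]
    expect_true(all(diff(cyc$time_h) > 0))
    expect_true(all(diff(cyc$bicarbonate_g_per_l) <= 1e-12))
    expect_true(all(diff(cyc$od600) >= -1e-12))
  }
})

test_that("configured generation means are recovered within 3 standard errors", {
  cfg <- enrichment_config()
  ds <- generate_enrichment(cfg, seed = 2026)
  gm <- generation_means(ds)
  n <- cfg$cycles
  for (cu in cfg$cultures) {
    for (gen in c("G1", "G2", "G3")) {
      target <- cfg$bicarb_reduction_pct[cu, gen]
      got <- gm$bicarb_reduction_pct[gm$culture == cu & gm$generation == gen]
      se <- cfg$rel_sd * target / sqrt(n)
      expect_lt(abs(got - target), 3 * se)
    }
    target <- cfg$vfa_end_g_l[cu]
    got <- mean(gm$vfa_end_g_per_l[gm$culture == cu])
    se <- cfg$rel_sd * target / sqrt(n * 5)
    expect_lt(abs(got - target), 3 * se)
    target <- cfg$co2_consumption_pct$enriched[cu]
    got <- gm$co2_consumed_pct[gm$culture == cu & gm$generation == "G4"]
    expect_lt(abs(got - target), 3 * cfg$rel_sd * target / sqrt(n))
  }
})

test_that("invalid configurations are refused with the offending fields", {
  expect_error(enrichment_config(rel_sd = -0.1), "rel_sd")
  expect_error(enrichment_config(vfa_end_g_l = c(AC = -1, CF = 1, RF = 1,
                                                 Blend = 1)),
               "negative concentration")
  expect_error(enrichment_config(cycles = 0), "cycles")
})

test_that("anova dataset generator validates input and embeds ground truth", {
  d <- generate_anova_dataset(c(a = 1, b = 2), sd = 0.1, n = 4, seed = 5)
  expect_equal(nrow(d), 8)
  expect_equal(attr(d, "ground_truth")$means, c(a = 1, b = 2))
  expect_error(generate_anova_dataset(c(a = 1, b = 2), sd = -1, n = 3),
               "sd")
  expect_error(generate_anova_dataset(c(a = 1, b = 2), sd = 1, n = 1),
               "n >= 2")
  # sd = 0 with unequal means: perfect separation -> Inf F flag
  d0 <- generate_anova_dataset(c(a = 1, b = 2), sd = 0, n = 3, seed = 1)
  expect_identical(tidy(one_way_anova(d0, value, factor_a))$statistic[1], Inf)
})

test_that("per-cycle summaries compute reduction arithmetic correctly", {
  toy <- tibble::tibble(
    culture = "AC", generation = "G3", cycle = 1,
    time_h = c(0, 36, 72),
    ph = c(7, 6.8, 6.5),
    od600 = c(0.2, 0.8, 1.2),
    bicarbonate_g_per_l = c(6, 4, 3),
    co2_consumed_pct = c(0, 20, 40),
    vfa_g_per_l = c(0, 1, 2),
    dcw_g_per_l = c(0.5, 2, 4),
    phb_g_per_l = c(0, 0.05, 0.2)
  )
  sm <- summarize_generation(toy)
  expect_equal(sm$bicarb_reduction_pct, 50)
  expect_equal(sm$delta_ph, -0.5)
  expect_equal(sm$vfa_end_g_per_l, 2)
  expect_equal(sm$phb_pct_dcw, 5)
  expect_false(sm$undefined_reduction)

  const <- toy
  const$bicarbonate_g_per_l <- c(6, 6, 6)
  expect_equal(summarize_generation(const)$bicarb_reduction_pct, 0)

  none <- toy
  none$bicarbonate_g_per_l <- 0
  sm0 <- summarize_generation(none)
  expect_true(is.na(sm0$bicarb_reduction_pct))
  expect_true(sm0$undefined_reduction)
})
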