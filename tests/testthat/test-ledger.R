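test_that("stream carbon converts compounds and passes direct values through", {
  s <- stream_carbon(ac_streams())
  expect_equal(s$gc_per_l[s$name == "sodium bicarbonate"], 0.858,
               tolerance = 0.001)
  expect_equal(s$gc_per_l[s$name == "inoculum biomass"], 0.45)
  zero <- carbon_stream("empty", "input", "substrate",
                        conc_g_per_l = 0, formula = "C6H12O6")
  expect_equal(stream_carbon(zero)$gc_per_l, 0)
  carbonfree <- carbon_stream("water", "input", "substrate",
                              conc_g_per_l = 1, formula = "H2O")
  expect_error(stream_carbon(carbonfree), "carbon-free")
})

test_that("carbon_stream enforces exactly one quantity representation", {
  expect_error(carbon_stream("x", "input", "substrate"), "exactly one")
  expect_error(carbon_stream("x", "input", "substrate",
                             conc_g_per_l = 1, formula = "CO2",
                             carbon_gc_per_l = 1), "exactly one")
  expect_error(carbon_stream("x", "input", "substrate", conc_g_per_l = 2),
               "needs a formula")
  expect_error(carbon_stream("x", "input", "substrate",
                             carbon_gc_per_l = -1), "non-negative")
})

test_that("VFA partition splits mass by the 1.5:1 ratio and conserves total", {
  p <- vfa_partition(3.467, 1.5)
  expect_equal(p$conc_g_per_l[p$acid == "acetic"], 2.080, tolerance = 1e-3)
  expect_equal(p$conc_g_per_l[p$acid == "butyric"], 1.387, tolerance = 1e-3)
  expect_equal(sum(p$conc_g_per_l), 3.467)

  expect_equal(vfa_partition(0)$conc_g_per_l, c(0, 0))
  # r -> infinity: everything acetic
  p_inf <- vfa_partition(2, 1e12)
  expect_equal(p_inf$conc_g_per_l[p_inf$acid == "acetic"], 2,
               tolerance = 1e-9)
  # mass always conserved; carbon bounded by the butyric fraction
  for (seed in 1:10) {
    set.seed(seed)
    tot <- runif(1, 0, 10); r <- runif(1, 0.1, 10)
    p <- vfa_partition(tot, r)
    expect_equal(sum(p$conc_g_per_l), tot, tolerance = 1e-12)
    expect_lte(sum(p$carbon_gc_per_l),
               tot * element_mass_fraction("C4H8O2", "C") + 1e-12)
  }
  expect_error(vfa_partition(-1), "non-negative")
  expect_error(vfa_partition(1, 0), "positive")
})

test_that("the balance reports the residual metabolites term and closure 1", {
  led <- carbon_balance(ac_streams())
  expect_equal(led$total_in, 0.858 + 0.45 + 0.048, tolerance = 1e-3)
  expect_equal(led$total_out_known, 0.48 + 0.324 + 0.025 + 0.3455)
  expect_equal(led$residual_metabolites,
               led$total_in - led$total_out_known)
  expect_equal(led$closure, 1)
  expect_true("residual_is_balancing_term" %in% led$flags)
  # conservation to machine precision with the residual as balancing term
  expect_equal(led$total_out_known + led$residual_metabolites, led$total_in,
               tolerance = 1e-15)
})

test_that("explicit metabolite streams switch closure to measured mode", {
  streams <- dplyr::bind_rows(
    ac_streams(),
    carbon_stream("other metabolites", "output", "metabolites",
                  carbon_gc_per_l = 0.1)
  )
  led <- carbon_balance(streams)
  expect_false(led$explicit_metabolites == FALSE)
  expect_equal(led$residual_metabolites, 0.1)
  expect_equal(led$closure, (led$total_out_known + 0.1) / led$total_in)
})

test_that("outputs equal to inputs give zero residual; over-closure is flagged", {
  streams <- dplyr::bind_rows(
    carbon_stream("in", "input", "substrate", carbon_gc_per_l = 1.2),
    carbon_stream("out", "output", "vfa", carbon_gc_per_l = 1.2)
  )
  expect_equal(carbon_balance(streams)$residual_metabolites, 0)

  over <- dplyr::bind_rows(
    carbon_stream("in", "input", "substrate", carbon_gc_per_l = 1),
    carbon_stream("out", "output", "vfa", carbon_gc_per_l = 1.5)
  )
  led <- carbon_balance(over)
  expect_lt(led$residual_metabolites, 0)
  expect_true(any(grepl("over_closure", led$flags)))

  none <- carbon_stream("in", "input", "substrate", carbon_gc_per_l = 0)
  bad <- dplyr::bind_rows(none,
                          carbon_stream("out", "output", "vfa",
                                        carbon_gc_per_l = 1))
  expect_error(carbon_balance(bad), "zero total input")
  expect_error(carbon_balance(none[0, ]), "at least one input")
})

test_that("generated scenarios recover the planted metabolite carbon", {
  for (seed in c(1, 7, 42)) {
    sc <- generate_ledger_scenario(seed = seed, n_streams = 4,
                                   metabolite_gc_per_l = 0.1)
    led <- carbon_balance(sc$streams)
    expect_equal(led$residual_metabolites, 0.1, tolerance = 1e-9)
  }
  sc0 <- generate_ledger_scenario(seed = 3, metabolite_gc_per_l = 0)
  expect_equal(carbon_balance(sc0$streams)$residual_metabolites, 0,
               tolerance = 1e-9)
})

test_that("scaling every stream scales the residual linearly", {
  sc <- generate_ledger_scenario(seed = 11, metabolite_gc_per_l = 0.08)
  doubled <- sc$streams
  doubled$conc_g_per_l <- doubled$conc_g_per_l * 2
  doubled$carbon_gc_per_l <- doubled$carbon_gc_per_l * 2
  expect_equal(carbon_balance(doubled)$residual_metabolites,
               2 * carbon_balance(sc$streams)$residual_metabolites,
               tolerance = 1e-12)
})

test_that("yield and PHB-content formulas behave and validate", {
  expect_equal(fermentable_yield(0.54, 10), 0.054)
  expect_equal(fermentable_yield(0, 5), 0)
  expect_equal(fermentable_yield(2 * 0.54, 10), 2 * fermentable_yield(0.54, 10))
  expect_error(fermentable_yield(0.5, 0), "positive")

  expect_equal(percent_phb(0.182, 4.45), 4.1, tolerance = 0.01)
  expect_equal(percent_phb(0.236, 4.21), 5.6, tolerance = 0.01)
  expect_equal(percent_phb(0, 3), 0)
  expect_error(percent_phb(5, 4), "impossible")
  expect_error(percent_phb(0.1, 0), "positive")
  # bounded in [0, 100] whenever the preconditions hold
  for (seed in 1:10) {
    set.seed(seed)
    dcw <- runif(1, 0.1, 10); phb <- runif(1, 0, dcw)
    expect_gte(percent_phb(phb, dcw), 0)
    expect_lte(percent_phb(phb, dcw), 100)
  }
})

test_that("tidy and glance expose the ledger pieces", {
  led <- carbon_balance(ac_streams())
  td <- tidy(led)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("name", "role", "gc_per_l") %in% names(td)))
  gl <- glance(led)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$closure, 1)
})
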