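test_that("one-way decomposition matches the hand-computed example", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
  fit <- one_way_anova(d, y, g)
  td <- tidy(fit)
  expect_equal(td$sumsq[td$term == "group"], 1.5)
  expect_equal(td$sumsq[td$term == "residuals"], 4)
  expect_equal(td$df, c(1, 4))
  expect_equal(td$statistic[1], 1.5)
})

test_that("degenerate layouts are reported, not errored", {
  ident <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(5, 6))
  expect_equal(tidy(one_way_anova(ident, y, g))$statistic[1], 0)

  sep <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2), each = 3))
  fit <- one_way_anova(sep, y, g)
  expect_identical(tidy(fit)$statistic[1], Inf)
  expect_true(any(grepl("zero residual", fit$flags)))

  expect_error(one_way_anova(data.frame(g = "a", y = 1:3), y, g), "2 groups")
})

test_that("one-way F with two groups equals the squared t statistic", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- data.frame(g = rep(c("a", "b"), each = 6), y = rnorm(12))
    f_stat <- tidy(one_way_anova(d, y, g))$statistic[1]
    t_stat <- stats::t.test(y ~ g, data = d, var.equal = TRUE)$statistic
    expect_equal(f_stat, unname(t_stat)^2, tolerance = 1e-10)
  }
})

test_that("results match stats::aov on random one- and two-way layouts", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(g = rep(letters[1:4], each = 5), y = rnorm(20))
    mine <- tidy(one_way_anova(d, y, g))
    ref <- summary(stats::aov(y ~ g, data = d))[[1]]
    expect_equal(mine$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(mine$statistic[1], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p.value[1], ref[["Pr(>F)"]][1], tolerance = 1e-10)

    d2 <- expand.grid(a = letters[1:3], b = LETTERS[1:2], r = 1:3)
    d2$y <- rnorm(nrow(d2))
    mine2 <- tidy(two_way_anova(d2, y, a, b))
    ref2 <- summary(stats::aov(y ~ a * b, data = d2))[[1]]
    expect_equal(mine2$sumsq, ref2[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(mine2$statistic[1:3], ref2[["F value"]][1:3],
                 tolerance = 1e-10)
    expect_equal(mine2$p.value[1:3], ref2[["Pr(>F)"]][1:3], tolerance = 1e-10)
  }
})

test_that("balanced two-way sums of squares decompose the total", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- expand.grid(a = letters[1:3], b = LETTERS[1:2], r = 1:4)
    d$y <- rnorm(nrow(d), mean = as.integer(d$a))
    td <- tidy(two_way_anova(d, y, a, b))
    total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(td$sumsq), total, tolerance = 1e-9 * total)
    expect_equal(td$df, c(2, 1, 2, 18))
  }
})

test_that("two-way handles separation and refuses unbalanced designs", {
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), r = 1:2)
  d$y <- ifelse(d$a == "x", 10, 20)
  fit <- two_way_anova(d, y, a, b)
  td <- tidy(fit)
  expect_identical(td$statistic[td$term == "factor_a"], Inf)
  expect_equal(td$statistic[td$term == "factor_b"], 0)

  d$y <- 7
  td_const <- tidy(two_way_anova(d, y, a, b))
  expect_equal(td_const$statistic[1:3], c(0, 0, 0))

  unb <- rbind(d, d[1, ])
  expect_error(two_way_anova(unb, y, a, b), "unbalanced")
})

test_that("ANOVA is shift-invariant and SS scales quadratically", {
  set.seed(99)
  d <- expand.grid(a = letters[1:3], b = LETTERS[1:2], r = 1:3)
  d$y <- rnorm(nrow(d))
  base <- tidy(two_way_anova(d, y, a, b))
  d$shift <- d$y + 100
  shifted <- tidy(two_way_anova(d, shift, a, b))
  expect_equal(shifted$sumsq, base$sumsq, tolerance = 1e-9)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-9)
  d$scaled <- 3 * d$y
  scaled <- tidy(two_way_anova(d, scaled, a, b))
  expect_equal(scaled$sumsq, 9 * base$sumsq, tolerance = 1e-9)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-9)
})

test_that("null simulations give a calibrated type-I error", {
  alpha <- 0.05
  reps <- 2000
  rejections <- 0L
  for (i in seq_len(reps)) {
    d <- generate_anova_dataset(c(a = 1, b = 1, c = 1, d = 1),
                                sd = 0.5, n = 3, seed = 10000 + i)
    p <- tidy(one_way_anova(d, value, factor_a))$p.value[1]
    if (p < alpha) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("planted enrichment and VFA effects are detected with high power", {
  # two-way: enriched vs non-enriched CO2-consumption means per culture
  m <- rbind(AC = c(enriched = 54.8, non_enriched = 17.4),
             CF = c(enriched = 63.2, non_enriched = 21.2),
             RF = c(enriched = 82.1, non_enriched = 21.4))
  hits <- 0L
  for (i in seq_len(500)) {
    d <- generate_anova_dataset(m, sd = 5, n = 3, seed = 20000 + i)
    td <- tidy(two_way_anova(d, value, factor_a, factor_b))
    if (td$p.value[td$term == "factor_b"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.95)

  # one-way: culture-mean VFA titers
  vfa <- c(AC = 2.017, RF = 2.307, CF = 3.243, Blend = 3.467)
  hits <- 0L
  for (i in seq_len(500)) {
    d <- generate_anova_dataset(vfa, sd = 0.1, n = 3, seed = 30000 + i)
    if (tidy(one_way_anova(d, value, factor_a))$p.value[1] < 0.001) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 500, 0.95)
})
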