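test_that("the null case is forced by the definitions", {
  d <- design_metrics(0, 0.25, alpha = 0.05)
  expect_equal(d$power, 0.05)
  expect_equal(d$type_s, 0.5)
  expect_identical(d$type_m, Inf)
  expect_false(d$type_m_defined)
})

test_that("asymptotic limits and sign symmetry hold", {
  big <- design_metrics(10, 0.25)
  expect_equal(big$power, 1, tolerance = 1e-8)
  expect_equal(big$type_s, 0, tolerance = 1e-12)
  expect_equal(big$type_m, 1, tolerance = 1e-6)

  a <- design_metrics(0.3, 0.2)
  b <- design_metrics(-0.3, 0.2)
  expect_equal(a$power, b$power)
  expect_equal(a$type_s, b$type_s)
  expect_equal(a$type_m, b$type_m)
})

test_that("power rises and Type M / Type S fall with the signal-to-noise ratio", {
  lam <- seq(0.2, 4, length.out = 15)
  d <- design_metrics(lam, 1)
  expect_true(all(diff(d$power) > 0))
  expect_true(all(diff(d$type_s) < 0))
  expect_true(all(diff(d$type_m) < 0))
})

test_that("closed forms agree with the Monte-Carlo retrodesign", {
  n_sims <- 2e5
  for (cs in list(c(0.25, 0.25, 0.05), c(0.1, 0.25, 0.05), c(0.3, 0.2, 0.01))) {
    cf <- design_metrics(cs[1], cs[2], cs[3])
    mc <- retrodesign_mc(cs[1], cs[2], cs[3], n_sims = n_sims, seed = 99)
    se_pow <- sqrt(cf$power * (1 - cf$power) / n_sims)
    expect_lt(abs(cf$power - mc$power), 3 * se_pow + 1e-9)
    se_ts <- sqrt(cf$type_s * (1 - cf$type_s) / mc$n_significant)
    expect_lt(abs(cf$type_s - mc$type_s), 3 * se_ts + 1e-9)
    expect_equal(cf$type_m, mc$type_m, tolerance = 0.02)
  }
})

test_that("the Monte-Carlo retrodesign is seeded and scales as expected", {
  a <- retrodesign_mc(0.2, 0.25, n_sims = 1e4, seed = 5)
  b <- retrodesign_mc(0.2, 0.25, n_sims = 1e4, seed = 5)
  expect_identical(a, b)
  cc <- retrodesign_mc(0.2, 0.25, n_sims = 1e4, seed = 6)
  expect_false(identical(a$power, cc$power))
})

test_that("sampling-level aggregation matches closed-form and mixed-model oracles", {
  # constants aggregate to themselves
  agg <- aggregate_sampling_level(rep(0.4, 10), rep(1:5, each = 2))
  expect_equal(agg$mean, 0.4)
  expect_equal(agg$median, 0.4)

  # balanced design: intercept equals the grand mean of study means
  set.seed(55)
  study <- rep(1:12, each = 4)
  vals <- 0.3 + rnorm(12, 0, 0.1)[study] + rnorm(48, 0, 0.05)
  agg <- aggregate_sampling_level(vals, study)
  expect_equal(agg$mean, mean(tapply(vals, study, mean)), tolerance = 1e-5)
  expect_equal(agg$method, "lmm")

  # unbalanced design: agrees with an independent mixed-model fitter
  skip_if_not_installed("lme4")
  study2 <- rep(1:10, times = c(2, 5, 3, 1, 6, 2, 4, 3, 2, 7))
  vals2 <- 0.25 + rnorm(10, 0, 0.12)[study2] + rnorm(length(study2), 0, 0.06)
  agg2 <- aggregate_sampling_level(vals2, study2)
  lm4 <- lme4::lmer(vals2 ~ 1 + (1 | study2), REML = TRUE)
  expect_equal(agg2$mean, unname(lme4::fixef(lm4)[1]), tolerance = 1e-3)

  # degenerate grouping falls back to the plain mean
  expect_warning(agg3 <- aggregate_sampling_level(c(0.1, 0.5), c(1, 1)),
                 "degenerate")
  expect_equal(agg3$mean, 0.3)
  expect_equal(agg3$method, "mean")
})

test_that("meta-level aggregation weights by k and filters only membership", {
  v <- c(0.2, 0.4, 0.6)
  expect_equal(aggregate_meta_level(v, c(3, 3, 3))$mean, mean(v))
  # one dominating meta-analysis pulls the aggregate to its value
  expect_equal(aggregate_meta_level(v, c(1, 1, 1e7))$mean, 0.6,
               tolerance = 1e-4)
  p <- c(0.001, 0.2, 0.01)
  filt <- aggregate_meta_level(v, c(3, 3, 3), p, post_hoc_filter = TRUE)
  expect_equal(filt$n, 2)
  expect_equal(filt$filtered_out, 1L)
  expect_equal(filt$mean, mean(v[c(1, 3)]))
  expect_error(aggregate_meta_level(v, c(3, 3, 3), rep(0.9, 3),
                                    post_hoc_filter = TRUE), "no meta-analyses")
})
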