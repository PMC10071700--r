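test_that("expected slope signs mirror the overall effect's sign", {
  pos <- expected_signs(0.3)
  expect_equal(pos$small_study, 1)
  expect_equal(pos$time_lag, -1)
  neg <- expected_signs(-0.3)
  expect_equal(neg$small_study, -1)
  expect_equal(neg$time_lag, 1)
  zero <- expected_signs(0)
  expect_true(zero$indeterminate)
})

test_that("a constant year collapses the full model to the error-only model", {
  dat <- one_meta(seed = 3)
  dat$year <- 2010
  models <- fit_bias_models(dat, "SMD")
  expect_true("year" %in% models$linear$dropped)
  ref <- pubbias:::.fit_bias_variant(dat, pubbias:::.bias_predictor(dat, "SMD"),
                                     "error", "linear")
  expect_equal(models$linear$fit$beta, ref$fit$beta)
  expect_equal(models$linear$fit$logLik, ref$fit$logLik)
})

test_that("year centring makes the analysis invariant to shifting all years", {
  dat <- one_meta(seed = 4)
  r1 <- analyze_meta(dat, "SMD", meta_id = 1)
  dat2 <- dat
  dat2$year <- dat$year + 57
  r2 <- analyze_meta(dat2, "SMD", meta_id = 1)
  attr(r1, "fits") <- NULL
  attr(r2, "fits") <- NULL
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("the decision tree maps every sign pattern to the specified refit", {
  dat <- one_meta(seed = 6)
  models <- fit_bias_models(dat, "SMD")
  b1 <- models$linear$fit$beta[["error"]]
  b2 <- models$linear$fit$beta[["year"]]
  pred <- pubbias:::.bias_predictor(dat, "SMD")
  mk_exp <- function(e1, e2) list(small_study = e1, time_lag = e2,
                                  indeterminate = FALSE)

  # both slopes as expected: keep the full quadratic-model intercept
  t1 <- apply_decision_tree(dat, "SMD", models, mk_exp(sign(b1), sign(b2)))
  expect_equal(t1$scenario, 1L)
  expect_identical(t1$beta0[["estimate"]],
                   models$quadratic$fit$beta[["intercept"]])

  # small-study expected, time-lag unexpected: quadratic error term only
  t2 <- apply_decision_tree(dat, "SMD", models, mk_exp(sign(b1), -sign(b2)))
  expect_equal(t2$scenario, 2L)
  ref2 <- pubbias:::.fit_bias_variant(dat, pred, "error", "quadratic")
  expect_equal(t2$beta0[["estimate"]], ref2$fit$beta[["intercept"]])

  # small-study unexpected, time-lag expected: year term only
  t3 <- apply_decision_tree(dat, "SMD", models, mk_exp(-sign(b1), sign(b2)))
  expect_equal(t3$scenario, 3L)
  ref3 <- pubbias:::.fit_bias_variant(dat, pred, "year", "quadratic")
  expect_equal(t3$beta0[["estimate"]], ref3$fit$beta[["intercept"]])

  # both unexpected: fall back to the intercept-only overall model
  t4 <- apply_decision_tree(dat, "SMD", models, mk_exp(-sign(b1), -sign(b2)))
  expect_equal(t4$scenario, 4L)
  ref4 <- fit_multilevel(mlma_spec(dat$es, dat$var, dat$study))
  expect_equal(t4$beta0[["estimate"]], ref4$beta[["intercept"]])

  # the alternative mapping swaps the two single-term scenarios
  t2c <- apply_decision_tree(dat, "SMD", models, mk_exp(sign(b1), -sign(b2)),
                             variant = "figure_caption")
  expect_equal(t2c$scenario, 3L)
  expect_equal(t2c$beta0[["estimate"]], ref3$fit$beta[["intercept"]])
  t3c <- apply_decision_tree(dat, "SMD", models, mk_exp(-sign(b1), sign(b2)),
                             variant = "figure_caption")
  expect_equal(t3c$scenario, 2L)
})

test_that("an indeterminate overall sign falls back to the full model with a warning", {
  dat <- one_meta(seed = 6)
  models <- fit_bias_models(dat, "SMD")
  expect_warning(
    tr <- apply_decision_tree(dat, "SMD", models, expected_signs(0)),
    "indeterminate")
  expect_identical(tr$scenario, "full")
  expect_identical(tr$beta0[["estimate"]],
                   models$quadratic$fit$beta[["intercept"]])
})

test_that("analyze_meta is deterministic and near-exact on noise-free data", {
  dat <- one_meta(seed = 8)
  r1 <- analyze_meta(dat, "SMD", meta_id = "m1")
  r2 <- analyze_meta(dat, "SMD", meta_id = "m1")
  attr(r1, "fits") <- NULL; attr(r2, "fits") <- NULL
  expect_identical(r1, r2)

  # degenerate noise-free corpus: huge groups, no heterogeneity
  quiet <- one_meta(seed = 9, mu = 0.4, sigma_study = 0, sigma_obs = 0,
                    n_studies = 15)
  quiet$es <- 0.4           # exact truth, zero noise limit
  quiet$es <- quiet$es + rnorm(nrow(quiet), 0, 1e-6)
  r <- analyze_meta(quiet, "SMD")
  expect_equal(r$beta0_overall, 0.4, tolerance = 1e-3)
  expect_equal(r$beta0_corrected2, r$beta0_overall, tolerance = 1e-3)
})

test_that("strong selection induces a positive small-study slope more often than not", {
  hits <- 0L
  n_rep <- 12
  for (s in seq_len(n_rep)) {
    dat <- one_meta(seed = 100 + s, mu = 0.15, selection_strength = 3,
                    n_studies = 25)
    r <- analyze_meta(dat, "SMD")
    if (!is.na(r$beta1) && r$beta1 > 0) hits <- hits + 1L
  }
  expect_gt(hits, n_rep / 2)
})
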