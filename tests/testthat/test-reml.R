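test_that("zero-heterogeneity GLS collapses to the inverse-variance average", {
  sp <- mlma_spec(c(0, 1), c(1, 1), study = c("a", "b"))
  gls <- pubbias:::.mlma_gls(sp, 0, 0)
  expect_equal(unname(gls$beta), 0.5)
  expect_equal(unname(gls$se), sqrt(0.5))
})

test_that("homogeneous data collapse to the fixed-effect mean", {
  set.seed(5)
  k <- 30
  y <- rnorm(k, 0.4, sqrt(0.05))
  f <- suppressWarnings(
    fit_multilevel(mlma_spec(y, rep(0.05, k), study = seq_len(k))))
  expect_equal(unname(f$beta), mean(y), tolerance = 0.02)
  expect_equal(unname(f$se), sqrt(0.05 / k), tolerance = 0.02)
})

test_that("fit is location- and scale-equivariant", {
  dat <- fixture12()
  f0 <- fit_multilevel(mlma_spec(dat$es, dat$var, dat$study))
  fshift <- fit_multilevel(mlma_spec(dat$es + 3, dat$var, dat$study))
  expect_equal(unname(fshift$beta), unname(f0$beta) + 3, tolerance = 1e-5)
  expect_equal(fshift$sigma2_study, f0$sigma2_study, tolerance = 1e-5)
  expect_equal(fshift$sigma2_obs, f0$sigma2_obs, tolerance = 1e-5)

  c_ <- 2.5
  fsc <- fit_multilevel(mlma_spec(c_ * dat$es, c_^2 * dat$var, dat$study))
  expect_equal(unname(fsc$beta), c_ * unname(f0$beta), tolerance = 1e-5)
  expect_equal(unname(fsc$se), c_ * unname(f0$se), tolerance = 1e-5)
  expect_equal(fsc$sigma2_study, c_^2 * f0$sigma2_study, tolerance = 1e-4)
})

test_that("REML optimum is invariant to moderator centring", {
  dat <- fixture12()
  x <- dat$year - 2000
  f1 <- fit_multilevel(mlma_spec(dat$es, dat$var, dat$study,
                                 cbind(intercept = 1, x = x)))
  f2 <- fit_multilevel(mlma_spec(dat$es, dat$var, dat$study,
                                 cbind(intercept = 1, x = x - mean(x))))
  expect_lt(abs(f1$sigma2_study - f2$sigma2_study), 1e-6)
  expect_lt(abs(f1$sigma2_obs - f2$sigma2_obs), 1e-6)
  expect_equal(unname(f1$beta["x"]), unname(f2$beta["x"]), tolerance = 1e-5)
  expect_equal(unname(f1$beta["intercept"]),
               unname(f2$beta["intercept"] - mean(x) * f2$beta["x"]),
               tolerance = 1e-5)
})

test_that("estimates agree with an independent multilevel REML fitter", {
  skip_if_not_installed("metafor")
  dat <- fixture12()
  dat$obs <- seq_len(nrow(dat))
  f <- fit_multilevel(mlma_spec(dat$es, dat$var, dat$study))
  m <- metafor::rma.mv(yi = es, V = var,
                       random = list(~ 1 | study, ~ 1 | obs),
                       data = dat, method = "REML")
  expect_equal(unname(f$beta), unname(coef(m)), tolerance = 1e-4)
  expect_equal(unname(f$se), unname(m$se), tolerance = 1e-4)
  expect_equal(sort(c(f$sigma2_study, f$sigma2_obs)), sort(unname(m$sigma2)),
               tolerance = 1e-3)
})

test_that("one effect per study reports the identifiability warning and a two-level fit", {
  set.seed(11)
  k <- 15
  v <- runif(k, 0.02, 0.1)
  y <- rnorm(k, 0.3, sqrt(0.05 + v))
  expect_warning(f <- fit_multilevel(mlma_spec(y, v, study = seq_len(k))),
                 "unidentifiable")
  expect_identical(f$identifiable, FALSE)
  expect_identical(f$sigma2_study, 0)
  skip_if_not_installed("metafor")
  m <- metafor::rma.uni(yi = y, vi = v, method = "REML",
                        control = list(tol = 1e-10))
  expect_equal(f$sigma2_obs, unname(m$tau2), tolerance = 1e-3)
  expect_equal(unname(f$beta), unname(coef(m)), tolerance = 1e-4)
})

test_that("Wald inference follows normal quantile arithmetic", {
  fit <- structure(list(beta = c(intercept = 1), se = c(intercept = 0.5)),
                   class = "mlma_fit")
  tab <- wald_inference(fit)
  expect_equal(tab$z, 2)
  expect_equal(tab$pval, 2 * pnorm(-2), tolerance = 1e-6)
  expect_equal(tab$ci_lb, 1 - qnorm(0.975) * 0.5)
  expect_equal(tab$ci_ub, 1 + qnorm(0.975) * 0.5)

  fit0 <- structure(list(beta = c(intercept = 0), se = c(intercept = 0.5)),
                    class = "mlma_fit")
  tab0 <- wald_inference(fit0)
  expect_equal(tab0$pval, 1)
  expect_equal(tab0$ci_lb, -tab0$ci_ub)
})

test_that("heterogeneity statistics hit their definitional anchors", {
  mk <- function(s2s, s2o, v) structure(
    list(sigma2_study = s2s, sigma2_obs = s2o, v = v), class = "mlma_fit")
  expect_equal(heterogeneity_stats(mk(0, 0, rep(0.1, 6)))$I2_total, 0)
  # equal variances: typical variance equals the common value, so
  # sigma2 total equal to it puts I2 at the definitional midpoint
  vt <- typical_sampling_variance(rep(0.1, 6))
  expect_equal(vt, 0.1)
  expect_equal(heterogeneity_stats(mk(0.06, 0.04, rep(0.1, 6)))$I2_total, 0.5)
  # the two typical-variance rules agree closely on the standard fixture
  v <- fixture12()$var
  vw <- typical_sampling_variance(v, "weighted")
  vh <- typical_sampling_variance(v, "harmonic")
  expect_lt(abs(vw - vh) / vh, 0.05)
})

test_that("p-values are calibrated against the simulated null z distribution", {
  set.seed(21)
  z <- rnorm(20000)
  p <- 2 * pnorm(-abs(z))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  fit <- structure(list(beta = c(x = z[1]), se = c(x = 1)), class = "mlma_fit")
  expect_equal(wald_inference(fit)$pval, p[1])
})
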