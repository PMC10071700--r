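test_that("the generator is deterministic given a seed and leaves the RNG alone", {
  cfg <- generator_config(n_meta = 3, studies_per_meta = 10, seed = 42)
  set.seed(1); before <- runif(1)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1, g2)
  g3 <- generate_corpus(generator_config(n_meta = 3, studies_per_meta = 10,
                                         seed = 43))
  expect_false(identical(g1$corpus$es, g3$corpus$es))
  set.seed(1)
  expect_identical(before, runif(1))   # generator restored the RNG state
})

test_that("generated sampling variances obey the metric formulas exactly", {
  g <- generate_corpus(generator_config(n_meta = 2, studies_per_meta = 8,
                                        metric = "SMD", seed = 2))$corpus
  v <- (g$n_e + g$n_c) / (g$n_e * g$n_c) + g$es^2 / (2 * (g$n_e + g$n_c))
  expect_equal(g$var, v, tolerance = 1e-12)

  z <- generate_corpus(generator_config(n_meta = 2, studies_per_meta = 8,
                                        metric = "Zr", seed = 2))$corpus
  expect_equal(z$var, 1 / (z$n_total - 3), tolerance = 1e-12)
  expect_true(all(z$n_total > 3))

  l <- generate_corpus(generator_config(n_meta = 2, studies_per_meta = 8,
                                        metric = "lnRR", seed = 2))$corpus
  expect_true(all(l$var > 0))
})

test_that("a noise-free configuration recovers the true effect", {
  cfg <- generator_config(n_meta = 1, studies_per_meta = 12, mu = 0.35,
                          sigma_study = 0, sigma_obs = 0,
                          group_size_range = c(5000, 5000), seed = 3)
  g <- generate_corpus(cfg)$corpus
  expect_true(all(abs(g$es - 0.35) < 0.1))
  f <- fit_multilevel(mlma_spec(g$es, g$var, g$study_id))
  expect_equal(unname(f$beta), 0.35, tolerance = 0.02)
})

test_that("selection keeps all significant records and never adds any", {
  g <- generate_corpus(generator_config(n_meta = 1, studies_per_meta = 40,
                                        mu = 0.2, seed = 5))$corpus
  expect_identical(apply_selection(g, 0), g)

  sel <- apply_selection(g, 1.2, seed = 9)
  expect_lte(nrow(sel), nrow(g))
  p <- 2 * pnorm(-abs(g$es) / sqrt(g$var))
  sig_keys <- g$obs_id[p < 0.05]
  expect_true(all(sig_keys %in% sel$obs_id))

  # infinite strength: exactly the significant records survive
  hard <- apply_selection(g, Inf, seed = 9)
  expect_setequal(hard$obs_id, sig_keys)
})

test_that("selection that empties a corpus raises a degeneracy error", {
  # every record non-significant, so infinite selection keeps none
  g <- data.frame(es = rep(0.01, 12), var = rep(0.04, 12),
                  year = rep(2005:2010, 2), study_id = rep(1:6, 2),
                  obs_id = 1:12)
  expect_error(apply_selection(g, Inf, seed = 1), "degenerate")
})

test_that("time-relaxed selection admits more non-significant records in later years", {
  set.seed(123)
  n <- 4000
  g <- data.frame(es = rnorm(n, 0, 0.1), var = rep(0.04, n),
                  year = rep(2000:2019, each = n / 20),
                  study_id = rep(1:(n / 4), each = 4), obs_id = 1:n)
  sel <- apply_selection(g, 2, decline = TRUE, seed = 11)
  early <- mean(sel$year <= 2005)
  late <- mean(sel$year >= 2014)
  expect_gt(late, early)   # later years over-represented after selection
})
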