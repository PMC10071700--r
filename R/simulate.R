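#' Configuration for the synthetic-literature generator
#'
#' Describes a corpus of meta-analyses with effect sizes nested in studies:
#' a shared true overall effect, between-study and observation-level
#' heterogeneity, sampling variances derived from simulated group sizes,
#' publication years, and optional significance-driven selection (with an
#' optional time-relaxing mode that induces a decline effect).
#'
#' @param n_meta Number of meta-analyses.
#' @param studies_per_meta Number of studies per meta-analysis (scalar or
#'   inclusive range).
#' @param effects_per_study Effect sizes per study (scalar or range).
#' @param metric `"SMD"`, `"lnRR"` or `"Zr"`.
#' @param mu True overall effect (metric units).
#' @param sigma_study Between-study SD of true effects.
#' @param sigma_obs Observation-level SD of true effects.
#' @param group_size_range Inclusive range of per-group sample sizes
#'   (minimum 3, so Zr variances exist).
#' @param year_range Inclusive calendar-year range.
#' @param selection_strength Selection severity (>= 0; 0 disables selection).
#'   Non-significant records survive with probability
#'   `exp(-selection_strength)`.
#' @param decline If `TRUE`, selection strength decreases linearly with
#'   publication year, reaching 0 at the latest year, so later years admit
#'   more non-significant results and published effects decline over time.
#' @param seed Master integer seed; per-meta-analysis child seeds are
#'   derived deterministically from it.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_meta = 12, studies_per_meta = 30,
                             effects_per_study = c(1, 3), metric = "SMD",
                             mu = 0.3, sigma_study = 0.2, sigma_obs = 0.1,
                             group_size_range = c(10, 100),
                             year_range = c(2000, 2019),
                             selection_strength = 0, decline = FALSE,
                             seed = 1L) {
  metric <- match.arg(metric, c("SMD", "lnRR", "Zr"))
  rng2 <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])
  studies_per_meta <- rng2(studies_per_meta)
  effects_per_study <- rng2(effects_per_study)
  group_size_range <- rng2(group_size_range)
  year_range <- rng2(year_range)
  if (n_meta < 1 || studies_per_meta[1] < 2 || effects_per_study[1] < 1)
    stop("invalid corpus dimensions")
  if (sigma_study < 0 || sigma_obs < 0) stop("SDs must be >= 0")
  if (group_size_range[1] < 3) stop("group sizes must be >= 3")
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  structure(list(n_meta = n_meta, studies_per_meta = studies_per_meta,
                 effects_per_study = effects_per_study, metric = metric,
                 mu = mu, sigma_study = sigma_study, sigma_obs = sigma_obs,
                 group_size_range = group_size_range, year_range = year_range,
                 selection_strength = selection_strength, decline = decline,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.runif_int <- function(n, rng) {
  if (rng[1] == rng[2]) rep(rng[1], n)
  else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

## Simulate one observed effect size of the requested metric given its true
## value on the metric scale and the design sizes. Summary statistics are
## simulated first, then converted by the effect-size engine, so the
## estimate-variance coupling matches real data.
.simulate_record <- function(metric, theta, n_e, n_c) {
  if (metric == "SMD") {
    m_c <- stats::rnorm(1, 0, 1 / sqrt(n_c))
    m_e <- stats::rnorm(1, theta, 1 / sqrt(n_e))
    s_c <- sqrt(stats::rchisq(1, n_c - 1) / (n_c - 1))
    s_e <- sqrt(stats::rchisq(1, n_e - 1) / (n_e - 1))
    es <- compute_effect_size("SMD", mean_e = m_e, mean_c = m_c,
                              sd_e = s_e, sd_c = s_c, n_e = n_e, n_c = n_c)
    c(es$es, es$var, n_e, n_c, n_e + n_c)
  } else if (metric == "lnRR") {
    base <- 10; cv <- 0.3
    mu_c <- base; mu_e <- base * exp(theta)
    repeat {
      m_c <- stats::rnorm(1, mu_c, cv * mu_c / sqrt(n_c))
      m_e <- stats::rnorm(1, mu_e, cv * mu_e / sqrt(n_e))
      s_c <- cv * mu_c * sqrt(stats::rchisq(1, n_c - 1) / (n_c - 1))
      s_e <- cv * mu_e * sqrt(stats::rchisq(1, n_e - 1) / (n_e - 1))
      if (m_c > 0 && m_e > 0 && s_c > 0 && s_e > 0) break
    }
    es <- compute_effect_size("lnRR", mean_e = m_e, mean_c = m_c,
                              sd_e = s_e, sd_c = s_c, n_e = n_e, n_c = n_c)
    c(es$es, es$var, n_e, n_c, n_e + n_c)
  } else {
    n <- n_e + n_c   # total sample for the correlation design
    rho <- tanh(theta)
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    r <- stats::cor(x, y)
    if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
    es <- compute_effect_size("Zr", r = r, n = n)
    c(es$es, es$var, NA, NA, n)
  }
}

#' Generate a synthetic meta-analytic corpus with known truth
#'
#' Draws, for each meta-analysis, study-level true effects around the
#' configured overall effect, observation-level deviations, simulated group
#' sizes and publication years; observed effect sizes and their sampling
#' variances are produced by simulating metric-appropriate summary
#' statistics. When `selection_strength > 0`, significance-based selection
#' (see [apply_selection()]) is applied per meta-analysis. Deterministic
#' given the config (one master seed, deterministic child seeds per
#' meta-analysis).
#'
#' @param config A [generator_config()].
#' @return A list: `corpus` (data frame: meta_id, study_id, obs_id, metric,
#'   es, var, n_e, n_c, n_total, year) and `truth` (one row per
#'   meta-analysis with the generating parameters).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- vector("list", config$n_meta)
  for (m in seq_len(config$n_meta)) {
    set.seed((config$seed + 104729L * m) %% .Machine$integer.max)
    n_st <- .runif_int(1, config$studies_per_meta)
    rows <- list()
    obs <- 0L
    for (j in seq_len(n_st)) {
      s_j <- stats::rnorm(1, 0, config$sigma_study)
      n_e <- .runif_int(1, config$group_size_range)
      n_c <- .runif_int(1, config$group_size_range)
      year <- .runif_int(1, config$year_range)
      n_eff <- .runif_int(1, config$effects_per_study)
      for (i in seq_len(n_eff)) {
        theta <- config$mu + s_j + stats::rnorm(1, 0, config$sigma_obs)
        rec <- .simulate_record(config$metric, theta, n_e, n_c)
        obs <- obs + 1L
        rows[[obs]] <- data.frame(
          meta_id = m, study_id = j, obs_id = obs, metric = config$metric,
          es = rec[1], var = rec[2], n_e = rec[3], n_c = rec[4],
          n_total = rec[5], year = year, stringsAsFactors = FALSE)
      }
    }
    dat <- do.call(rbind, rows)
    if (config$selection_strength > 0)
      dat <- apply_selection(dat, config$selection_strength,
                             decline = config$decline,
                             seed = (config$seed + 7919L * m) %%
                               .Machine$integer.max)
    out[[m]] <- dat
  }
  corpus <- do.call(rbind, out)
  rownames(corpus) <- NULL
  truth <- data.frame(meta_id = seq_len(config$n_meta),
                      metric = config$metric, mu = config$mu,
                      sigma2_study = config$sigma_study^2,
                      sigma2_obs = config$sigma_obs^2,
                      selection_strength = config$selection_strength,
                      decline = config$decline)
  list(corpus = corpus, truth = truth)
}

#' Significance-based selection on a meta-analytic dataset
#'
#' Emulates the file-drawer process: records whose two-sided p-value (from
#' es / se) falls below `alpha` are always retained; non-significant records
#' survive with probability `exp(-strength)`. With `decline = TRUE` the
#' strength decreases linearly with publication year to 0 at the latest
#' year, so later years admit more non-significant effects and the
#' published record shows a decline effect.
#'
#' @param data Records with columns `es`, `var`, `year`, `study_id`.
#' @param strength Selection severity (>= 0; 0 returns `data` unchanged).
#' @param decline Relax selection over time?
#' @param alpha Significance threshold.
#' @param seed Integer seed for the survival draws.
#' @return The retained subset of `data`.
#' @export
apply_selection <- function(data, strength, decline = FALSE, alpha = 0.05,
                            seed = 1L) {
  stopifnot(strength >= 0)
  if (strength == 0) return(data)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- 2 * stats::pnorm(-abs(data$es) / sqrt(data$var))
  sig <- p < alpha
  yr <- data$year
  s_y <- if (decline && max(yr) > min(yr)) {
    strength * (max(yr) - yr) / (max(yr) - min(yr))
  } else rep(strength, nrow(data))
  keep <- sig | (stats::runif(nrow(data)) < exp(-s_y))
  out <- data[keep, , drop = FALSE]
  if (length(unique(out$study_id)) < 2)
    stop("corpus degenerate: selection removed almost all studies")
  rownames(out) <- NULL
  out
}
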