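#' Statistical power, Type M and Type S errors for a two-sided z-test
#'
#' For an estimate distributed Normal(true_effect, se^2) tested two-sided at
#' `alpha`: power is the probability of significance; the Type S error is
#' the probability that a significant estimate has the wrong sign; the
#' Type M error (exaggeration ratio) is the expected absolute estimate,
#' conditional on significance, divided by |true_effect|. All three depend
#' only on the signal-to-noise ratio lambda = true_effect / se and alpha.
#' The closed forms use truncated-normal expectations; at true_effect = 0
#' power equals alpha, Type S equals 1/2, and Type M is undefined (returned
#' as `Inf` with `type_m_defined = FALSE`).
#'
#' @param true_effect True effect size.
#' @param se Standard error of the estimate (> 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @return A list: `power`, `type_s`, `type_m`, `type_m_defined`, `lambda`.
#' @export
design_metrics <- function(true_effect, se, alpha = 0.05) {
  if (any(se <= 0)) stop("se must be > 0")
  stopifnot(alpha > 0, alpha < 1)
  lam <- true_effect / se
  zc <- stats::qnorm(1 - alpha / 2)
  pow <- 1 - stats::pnorm(zc - lam) + stats::pnorm(-zc - lam)
  wrong <- ifelse(lam >= 0, stats::pnorm(-zc - lam), 1 - stats::pnorm(zc - lam))
  type_s <- ifelse(lam == 0, 0.5, wrong / pow)
  ## E[|est|; significant] for true > 0 (sign-symmetric otherwise)
  al <- abs(lam)
  e_abs <- abs(true_effect) * (1 - stats::pnorm(zc - al)) +
    se * stats::dnorm(zc - al) -
    abs(true_effect) * stats::pnorm(-zc - al) +
    se * stats::dnorm(zc + al)
  type_m <- ifelse(lam == 0, Inf, e_abs / (abs(true_effect) * pow))
  list(power = pow, type_s = type_s, type_m = type_m,
       type_m_defined = lam != 0, lambda = lam)
}

#' Monte-Carlo retrodesign
#'
#' Simulation counterpart of [design_metrics()]: draws estimates from
#' Normal(true_effect, se^2), flags two-sided significance, and computes the
#' empirical power, sign-error rate among significant draws, and
#' exaggeration ratio. Serves as an independent oracle for the closed forms.
#'
#' @param true_effect,se,alpha As in [design_metrics()].
#' @param n_sims Number of draws (>= 1e4).
#' @param seed Integer seed.
#' @return A list: `power`, `type_s`, `type_m`, `n_significant`,
#'   `available` (FALSE when no draw reached significance), and the
#'   Monte-Carlo standard errors `mc_se_power`, `mc_se_type_s`,
#'   `mc_se_type_m`.
#' @export
retrodesign_mc <- function(true_effect, se, alpha = 0.05, n_sims = 1e5,
                           seed = 1L) {
  stopifnot(se > 0, n_sims >= 1e4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  est <- stats::rnorm(n_sims, true_effect, se)
  zc <- stats::qnorm(1 - alpha / 2)
  sig <- abs(est) > zc * se
  ns <- sum(sig)
  if (ns == 0)
    return(list(power = 0, type_s = NA_real_, type_m = NA_real_,
                n_significant = 0L, available = FALSE))
  wrong <- if (true_effect >= 0) sum(sig & est < 0) else sum(sig & est > 0)
  pow <- ns / n_sims
  ts <- wrong / ns
  abs_sig <- abs(est[sig])
  list(power = pow,
       type_s = ts,
       type_m = if (true_effect == 0) NA_real_
                else mean(abs_sig) / abs(true_effect),
       n_significant = as.integer(ns), available = TRUE,
       mc_se_power = sqrt(pow * (1 - pow) / n_sims),
       mc_se_type_s = sqrt(ts * (1 - ts) / ns),
       mc_se_type_m = if (true_effect == 0) NA_real_
                      else stats::sd(abs_sig) / sqrt(ns) / abs(true_effect))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Aggregate design metrics over primary studies (sampling level)
#'
#' Averages per-effect-size power / Type M / Type S values with a
#' random-intercept-by-study variance-components model (the multilevel REML
#' engine with the known-sampling-variance terms set to zero), so dependent
#' effect sizes from one study do not dominate. The median is reported
#' alongside. Degenerate grouping (every value its own study, or a single
#' study) falls back to the plain mean with a warning.
#'
#' @param values Per-effect-size metric values.
#' @param study Study identifiers.
#' @return A list: `mean` (model intercept), `median`, `n`, `n_studies`,
#'   `method` (`"lmm"` or `"mean"`).
#' @export
aggregate_sampling_level <- function(values, study) {
  keep <- is.finite(values)
  values <- values[keep]
  study <- factor(study[keep])
  n <- length(values)
  if (n == 0) stop("no finite values to aggregate")
  study <- droplevels(study)
  degenerate <- nlevels(study) < 2 || nlevels(study) == n ||
    stats::sd(values) == 0
  if (degenerate) {
    if (stats::sd(values) > 0)
      warning("degenerate study grouping: falling back to the plain mean")
    return(list(mean = mean(values), median = stats::median(values),
                n = n, n_studies = nlevels(study), method = "mean"))
  }
  fit <- fit_multilevel(mlma_spec(values, rep(0, n), study),
                        warn_identifiability = FALSE)
  list(mean = unname(fit$beta[1]), median = stats::median(values),
       n = n, n_studies = nlevels(study), method = "lmm")
}

#' Aggregate design metrics over meta-analyses (synthesis level)
#'
#' k-weighted mean (the intercept of a weighted regression on a constant)
#' and median of per-meta-analysis power / Type M / Type S values, with an
#' optional post hoc filter that drops meta-analyses whose overall mean
#' effect is not statistically significant before aggregating.
#'
#' @param values Per-meta-analysis metric values.
#' @param k Number of effect sizes per meta-analysis (the weights).
#' @param p_overall Per-meta-analysis p-values of the overall effect
#'   (required when filtering).
#' @param post_hoc_filter Drop cases with `p_overall >= alpha`?
#' @param alpha Filter threshold.
#' @return A list: `mean`, `median`, `n`, `filtered_out`.
#' @export
aggregate_meta_level <- function(values, k, p_overall = NULL,
                                 post_hoc_filter = FALSE, alpha = 0.05) {
  stopifnot(length(values) == length(k))
  keep <- is.finite(values)
  dropped <- 0L
  if (post_hoc_filter) {
    if (is.null(p_overall)) stop("post hoc filter requires p_overall")
    sel <- keep & p_overall < alpha
    dropped <- sum(keep) - sum(sel)
    keep <- sel
  }
  if (!any(keep)) stop("no meta-analyses left to aggregate")
  v <- values[keep]
  w <- k[keep]
  fit <- stats::lm(v ~ 1, weights = w)
  list(mean = unname(stats::coef(fit)[1]), median = stats::median(v),
       n = sum(keep), filtered_out = dropped)
}
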