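## Shifted z-scores: z(x) - z(x0) = (x - x0) / sd(x). Centring on x0 makes
## the model intercept conditional on x = x0 while keeping unit slope scale.
.shifted_z <- function(x, x0) {
  s <- stats::sd(x)
  if (s == 0) return(NULL)
  (x - x0) / s
}

#' Standardize one meta-analysis' bias models for cross-metric pooling
#'
#' Effect-size metrics live on different scales, so per-meta-analysis model
#' coefficients are standardized before being pooled across meta-analyses:
#' the response is divided by its sample SD (not centred, so the intercept
#' stays interpretable), and the uncertainty and centred-year predictors are
#' z-scaled, shifted so that the intercept remains conditional on zero
#' sampling error at the latest publication year. The quadratic correction
#' model squares the shifted uncertainty z-score. The sign decision tree is
#' re-applied on the standardized fits for the direction-controlled
#' ("type 2") estimates.
#'
#' @param data One meta-analysis' records (`es`, `var`, `study`, `year`,
#'   optional `n_e`, `n_c`).
#' @param metric Effect-size metric.
#' @param meta_id Identifier carried into the result.
#' @param predictor_mode `"auto"` or `"se"` (see [fit_bias_models()]).
#' @param variant Decision-tree variant (see [apply_decision_tree()]).
#' @return A one-row data frame: `sd_response`, standardized overall effect
#'   `eta0_overall`, slopes `eta1` and `eta2` (linear model), corrected
#'   intercepts `eta0_corrected1` (full quadratic model) and
#'   `eta0_corrected2` (decision tree), each with SE and p, plus
#'   `scenario_std`.
#' @export
standardize_case <- function(data, metric, meta_id = NA,
                             predictor_mode = "auto",
                             variant = "main_text") {
  if (nrow(data) < 4) stop("standardization requires k >= 4")
  sd_y <- stats::sd(data$es)
  if (sd_y <= 0) stop("response has zero variance; cannot standardize")
  cy <- data$es / sd_y
  cv <- data$var / sd_y^2
  pred <- .bias_predictor(data, metric, predictor_mode)
  ze <- .shifted_z(pred$linear, 0)               # z(error_i) - z(error_0)
  zy <- .shifted_z(data$year, max(data$year))    # z(year_i) - z(year_latest)

  fit_std <- function(terms, error_order) {
    cols <- list(intercept = rep(1, nrow(data)))
    if (terms %in% c("both", "error") && !is.null(ze))
      cols$error <- if (error_order == "linear") ze else ze^2
    if (terms %in% c("both", "year") && !is.null(zy))
      cols$year <- zy
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
    list(fit = fit_multilevel(mlma_spec(cy, cv, data$study, X)),
         terms = setdiff(names(cols), "intercept"))
  }

  overall <- fit_multilevel(mlma_spec(cy, cv, data$study))
  e0 <- .coef_row(list(fit = overall), "intercept")
  lin <- fit_std("both", "linear")
  quad <- fit_std("both", "quadratic")
  e1 <- .coef_row(lin, "error")
  e2 <- .coef_row(lin, "year")
  c1 <- .coef_row(quad, "intercept")

  exp_s <- expected_signs(e0[["estimate"]])
  if (isTRUE(exp_s$indeterminate)) {
    scen <- "full"
    sel <- quad
  } else {
    b1 <- e1[["estimate"]]; b2 <- e2[["estimate"]]
    b1_ok <- is.na(b1) || sign(b1) == exp_s$small_study
    b2_ok <- is.na(b2) || sign(b2) == exp_s$time_lag
    scen <- if (b1_ok && b2_ok) 1L else if (b1_ok && !b2_ok) 2L
    else if (!b1_ok && b2_ok) 3L else 4L
    if (variant == "figure_caption" && scen %in% c(2L, 3L)) scen <- 5L - scen
    sel <- switch(as.character(scen),
                  "1" = quad,
                  "2" = fit_std("error", "quadratic"),
                  "3" = fit_std("year", "quadratic"),
                  "4" = list(fit = overall, terms = character(0)))
  }
  c2 <- .coef_row(sel, "intercept")
  data.frame(meta_id = meta_id, metric = metric, k = nrow(data),
             sd_response = sd_y,
             eta0_overall = e0[["estimate"]], eta0_overall_se = e0[["se"]],
             eta0_overall_p = e0[["pval"]],
             eta1 = e1[["estimate"]], eta1_se = e1[["se"]],
             eta1_p = e1[["pval"]],
             eta2 = e2[["estimate"]], eta2_se = e2[["se"]],
             eta2_p = e2[["pval"]],
             eta0_corrected1 = c1[["estimate"]],
             eta0_corrected1_se = c1[["se"]],
             eta0_corrected1_p = c1[["pval"]],
             eta0_corrected2 = c2[["estimate"]],
             eta0_corrected2_se = c2[["se"]],
             eta0_corrected2_p = c2[["pval"]],
             scenario_std = as.character(scen),
             stringsAsFactors = FALSE)
}

#' Second-order random-effects pooling of per-meta-analysis coefficients
#'
#' Pools coefficients estimated by first-order meta-analyses across
#' meta-analyses with a random-effects model fitted by REML (the multilevel
#' engine with a single level), weighting each case by the inverse square of
#' its standard error. An optional effect-size-type moderator yields
#' per-level pooled means and the marginal R-squared it explains.
#'
#' @param estimate,se Per-case coefficient estimates and standard errors.
#' @param moderator Optional factor (e.g. effect-size metric).
#' @param level Confidence level.
#' @return A list of class `"second_order_summary"`: `estimate`, `se`, `z`,
#'   `pval`, `ci_lb`, `ci_ub` for the grand mean; `tau2`, `I2_among`,
#'   `n_cases`; with a moderator also `by_level` (a data frame of per-level
#'   pooled means) and `R2_marginal`.
#' @export
pool_coefficients <- function(estimate, se, moderator = NULL, level = 0.95) {
  keep <- is.finite(estimate) & is.finite(se) & se > 0
  estimate <- estimate[keep]
  se <- se[keep]
  if (!is.null(moderator)) moderator <- factor(moderator[keep])
  n <- length(estimate)
  if (n == 0) stop("no usable cases to pool")
  if (n == 1) {
    warning("single case: between-case heterogeneity is unestimable")
    crit <- stats::qnorm(1 - (1 - level) / 2)
    return(structure(list(estimate = estimate, se = se, z = estimate / se,
                          pval = 2 * stats::pnorm(-abs(estimate / se)),
                          ci_lb = estimate - crit * se,
                          ci_ub = estimate + crit * se,
                          tau2 = NA_real_, I2_among = NA_real_, n_cases = 1L),
                     class = "second_order_summary"))
  }
  if (n == 2) {
    ## tau2 is unestimable from two cases: fixed-effect inverse-variance pool
    warning("two cases: heterogeneity set to zero (fixed-effect pool)")
    w <- 1 / se^2
    est <- sum(w * estimate) / sum(w)
    se_p <- sqrt(1 / sum(w))
    crit <- stats::qnorm(1 - (1 - level) / 2)
    return(structure(list(estimate = est, se = se_p, z = est / se_p,
                          pval = 2 * stats::pnorm(-abs(est / se_p)),
                          ci_lb = est - crit * se_p, ci_ub = est + crit * se_p,
                          tau2 = 0, I2_among = NA_real_, n_cases = 2L),
                     class = "second_order_summary"))
  }
  spec <- mlma_spec(estimate, se^2, study = seq_len(n))
  fit <- fit_multilevel(spec, warn_identifiability = FALSE)
  tab <- wald_inference(fit, level)
  vt <- typical_sampling_variance(se^2)
  out <- list(estimate = tab$estimate[1], se = tab$se[1], z = tab$z[1],
              pval = tab$pval[1], ci_lb = tab$ci_lb[1], ci_ub = tab$ci_ub[1],
              tau2 = fit$sigma2_obs,
              I2_among = fit$sigma2_obs / (fit$sigma2_obs + vt),
              n_cases = n)
  if (!is.null(moderator) && nlevels(moderator) > 1 &&
      n >= nlevels(moderator) + 2) {
    X <- stats::model.matrix(~ 0 + moderator)
    colnames(X) <- levels(moderator)
    mfit <- fit_multilevel(mlma_spec(estimate, se^2, seq_len(n), X),
                           warn_identifiability = FALSE)
    mtab <- wald_inference(mfit, level)
    mtab$n <- as.integer(table(moderator)[mtab$term])
    out$by_level <- mtab
    fitted_fix <- drop(X %*% mfit$beta)
    vf <- stats::var(fitted_fix)
    out$R2_marginal <- vf / (vf + mfit$sigma2_obs)
  }
  class(out) <- "second_order_summary"
  out
}
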