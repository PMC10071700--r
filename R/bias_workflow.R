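#' Expected slope signs for publication-bias indicators
#'
#' Under selective publication, for an overall effect expected to be
#' positive, small studies overshoot upwards (positive slope on sampling
#' error) and published effects decline over time (negative slope on year).
#' The expectations mirror for a negative overall effect.
#'
#' @param beta0_sign Sign of the overall (uncorrected) effect: a numeric
#'   whose sign is used.
#' @return A list with `small_study` and `time_lag` entries each in
#'   \{-1, 1\}, or `indeterminate = TRUE` when the overall effect is exactly
#'   zero.
#' @export
expected_signs <- function(beta0_sign) {
  s <- sign(beta0_sign)
  if (s == 0)
    return(list(small_study = NA_real_, time_lag = NA_real_,
                indeterminate = TRUE))
  list(small_study = s, time_lag = -s, indeterminate = FALSE)
}

## Choose the small-study predictor for a meta-analysis dataset.
## SMD/lnRR with complete group sizes -> effective-sample predictor;
## otherwise (and for Zr by default) the standard error / variance.
.bias_predictor <- function(data, metric, predictor_mode = c("auto", "se")) {
  predictor_mode <- match.arg(predictor_mode)
  has_n <- !is.null(data$n_e) && !is.null(data$n_c) &&
    !anyNA(data$n_e) && !anyNA(data$n_c)
  if (predictor_mode == "auto" && metric %in% c("SMD", "lnRR") && has_n) {
    list(linear = effective_sample_predictor(data$n_e, data$n_c, "linear"),
         quadratic = effective_sample_predictor(data$n_e, data$n_c, "quadratic"),
         mode = "effective_n")
  } else {
    list(linear = sqrt(data$var), quadratic = data$var, mode = "se")
  }
}

## Fit one bias-regression variant. terms: "both", "error", "year", "none";
## error_order: "linear" or "quadratic". Returns the mlma fit plus metadata.
.fit_bias_variant <- function(data, pred, terms, error_order) {
  err <- if (error_order == "linear") pred$linear else pred$quadratic
  yr <- data$year - max(data$year)
  cols <- list(intercept = rep(1, nrow(data)))
  dropped <- character(0)
  want_err <- terms %in% c("both", "error")
  want_yr <- terms %in% c("both", "year")
  if (want_err) {
    if (stats::sd(err) > 0) cols$error <- err
    else dropped <- c(dropped, "error")
  }
  if (want_yr) {
    if (stats::sd(yr) > 0) cols$year <- yr
    else dropped <- c(dropped, "year")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  fit <- fit_multilevel(mlma_spec(data$es, data$var, data$study, X))
  list(fit = fit, dropped = dropped, error_order = error_order,
       terms = setdiff(names(cols), "intercept"))
}

#' Fit the small-study / decline-effect meta-regressions
#'
#' Fits the multilevel extension of Egger's regression for one
#' meta-analysis: effect sizes regressed on their uncertainty index and on
#' publication year centred at the latest year, with study-level and
#' observation-level random effects. Two full models are fitted: the linear
#' model (uncertainty entering as a standard-error-like term), used to
#' detect small-study and decline effects, and the quadratic model
#' (uncertainty entering on the variance scale), used to estimate the
#' bias-corrected intercept.
#'
#' @param data A data frame with columns `es`, `var`, `study`, `year`, and
#'   optionally `n_e`, `n_c`.
#' @param metric Effect-size metric of this meta-analysis.
#' @param predictor_mode `"auto"` (effective-sample predictor for SMD/lnRR
#'   when group sizes are available) or `"se"` (always the standard error /
#'   variance).
#' @return A list with elements `linear` and `quadratic` (each a fitted
#'   variant carrying `fit`, `dropped`, `terms`), plus `predictor_mode`.
#' @export
fit_bias_models <- function(data, metric, predictor_mode = "auto") {
  if (nrow(data) < 4) stop("bias regression requires k >= 4")
  pred <- .bias_predictor(data, metric, predictor_mode)
  list(linear = .fit_bias_variant(data, pred, "both", "linear"),
       quadratic = .fit_bias_variant(data, pred, "both", "quadratic"),
       predictor_mode = pred$mode)
}

## Pull a coefficient (estimate, se, p) from a variant fit; NA if dropped.
.coef_row <- function(variant, term) {
  tab <- wald_inference(variant$fit)
  i <- match(term, tab$term)
  if (is.na(i)) c(estimate = NA_real_, se = NA_real_, pval = NA_real_)
  else c(estimate = tab$estimate[i], se = tab$se[i], pval = tab$pval[i])
}

#' Sign-based decision tree for the bias-corrected intercept
#'
#' High heterogeneity can flip the bias slopes to signs inconsistent with
#' publication bias, in which case keeping those terms misestimates the
#' corrected intercept. The tree compares the detected slope signs (from the
#' linear detection model) with the expected signs and selects:
#' scenario 1 (both expected) the full quadratic-model intercept;
#' scenario 2 (small-study expected, time-lag unexpected) a refit with the
#' uncertainty term only; scenario 3 (small-study unexpected, time-lag
#' expected) a refit with the year term only; scenario 4 (both unexpected)
#' the intercept-only model. `variant = "figure_caption"` swaps the
#' conditions for scenarios 2 and 3.
#'
#' @param data,metric,predictor_mode As in [fit_bias_models()].
#' @param models A [fit_bias_models()] result for `data`.
#' @param expected [expected_signs()] of the overall effect.
#' @param variant `"main_text"` (default) or `"figure_caption"`.
#' @return A list with `scenario` (1:4), the selected `fit`, and the
#'   corrected-intercept coefficient row `beta0`.
#' @export
apply_decision_tree <- function(data, metric, models, expected,
                                predictor_mode = "auto",
                                variant = c("main_text", "figure_caption")) {
  variant <- match.arg(variant)
  if (isTRUE(expected$indeterminate)) {
    warning("overall effect exactly zero: expected signs indeterminate; ",
            "using the full-model corrected intercept")
    return(list(scenario = "full", fit = models$quadratic,
                beta0 = .coef_row(models$quadratic, "intercept")))
  }
  det <- models$linear
  b1 <- .coef_row(det, "error")[["estimate"]]
  b2 <- .coef_row(det, "year")[["estimate"]]
  b1_ok <- !is.na(b1) && sign(b1) == expected$small_study
  b2_ok <- !is.na(b2) && sign(b2) == expected$time_lag
  ## dropped terms cannot show an unexpected sign; treat as expected so the
  ## surviving term decides
  if (is.na(b1)) b1_ok <- TRUE
  if (is.na(b2)) b2_ok <- TRUE
  scen <- if (b1_ok && b2_ok) 1L else if (b1_ok && !b2_ok) 2L
  else if (!b1_ok && b2_ok) 3L else 4L
  if (variant == "figure_caption" && scen %in% c(2L, 3L)) scen <- 5L - scen
  pred <- .bias_predictor(data, metric, predictor_mode)
  sel <- switch(as.character(scen),
    "1" = models$quadratic,
    "2" = .fit_bias_variant(data, pred, "error", "quadratic"),
    "3" = .fit_bias_variant(data, pred, "year", "quadratic"),
    "4" = {
      f <- fit_multilevel(mlma_spec(data$es, data$var, data$study))
      list(fit = f, dropped = character(0), terms = character(0),
           error_order = "none")
    })
  list(scenario = scen, fit = sel, beta0 = .coef_row(sel, "intercept"))
}

#' Full publication-bias analysis of one meta-analysis
#'
#' Runs the complete per-meta-analysis chain: the intercept-only multilevel
#' model for the uncorrected overall effect, the linear detection model for
#' the small-study and time-lag slopes, the quadratic model for the
#' full-model ("type 1") corrected intercept, and the sign decision tree for
#' the direction-controlled ("type 2") corrected intercept.
#'
#' @param data One meta-analysis' records (`es`, `var`, `study`, `year`,
#'   optional `n_e`, `n_c`).
#' @param metric Effect-size metric.
#' @param meta_id Identifier carried into the result.
#' @param predictor_mode,variant As in [apply_decision_tree()].
#' @param alpha Two-sided significance level for the significance flags.
#' @return A one-row data frame (class `"bias_case"` attributes carry the
#'   fits): meta_id, metric, k, n_studies, the overall effect, both slopes,
#'   both corrected intercepts (each with SE and p), scenario, expected
#'   signs, and the predictor mode used.
#' @export
analyze_meta <- function(data, metric, meta_id = NA, predictor_mode = "auto",
                         variant = "main_text", alpha = 0.05) {
  stopifnot(all(c("es", "var", "study", "year") %in% names(data)))
  overall <- fit_multilevel(mlma_spec(data$es, data$var, data$study))
  b0 <- .coef_row(list(fit = overall), "intercept")
  exp_s <- expected_signs(b0[["estimate"]])
  models <- fit_bias_models(data, metric, predictor_mode)
  b1 <- .coef_row(models$linear, "error")
  b2 <- .coef_row(models$linear, "year")
  c1 <- .coef_row(models$quadratic, "intercept")
  tree <- apply_decision_tree(data, metric, models, exp_s,
                              predictor_mode, variant)
  out <- data.frame(
    meta_id = meta_id, metric = metric, k = nrow(data),
    n_studies = overall$n_studies,
    beta0_overall = b0[["estimate"]], beta0_overall_se = b0[["se"]],
    beta0_overall_p = b0[["pval"]],
    beta1 = b1[["estimate"]], beta1_se = b1[["se"]], beta1_p = b1[["pval"]],
    beta2 = b2[["estimate"]], beta2_se = b2[["se"]], beta2_p = b2[["pval"]],
    beta0_corrected1 = c1[["estimate"]], beta0_corrected1_se = c1[["se"]],
    beta0_corrected1_p = c1[["pval"]],
    beta0_corrected2 = tree$beta0[["estimate"]],
    beta0_corrected2_se = tree$beta0[["se"]],
    beta0_corrected2_p = tree$beta0[["pval"]],
    scenario = tree$scenario,
    expected_sign_beta1 = exp_s$small_study,
    expected_sign_beta2 = exp_s$time_lag,
    predictor_mode = models$predictor_mode,
    sigma2_study = overall$sigma2_study, sigma2_obs = overall$sigma2_obs,
    stringsAsFactors = FALSE)
  attr(out, "fits") <- list(overall = overall, models = models, tree = tree)
  out
}
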