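#' Specify a three-level meta-analytic model
#'
#' Bundles responses, known sampling variances, study grouping, and an
#' optional moderator matrix into a validated model specification. The
#' marginal model is y = X beta + s_study + o_obs + m, where the study and
#' observation effects are mean-zero normal with variances sigma2_study and
#' sigma2_obs, and m has known diagonal covariance diag(v).
#'
#' @param es Numeric vector of effect sizes (the response).
#' @param var Numeric vector of known sampling variances (> 0, or >= 0 for
#'   plain variance-components models).
#' @param study Study identifiers (coerced to factor); effect sizes sharing a
#'   study share the between-study random effect.
#' @param X Moderator matrix including the intercept column. `NULL` means
#'   intercept-only.
#' @return An object of class `"mlma_spec"`.
#' @export
mlma_spec <- function(es, var, study, X = NULL) {
  es <- as.numeric(es)
  k <- length(es)
  var <- as.numeric(var)
  if (length(var) != k) stop("es and var must have equal length")
  if (any(!is.finite(es)) || any(!is.finite(var))) stop("non-finite inputs")
  if (any(var < 0)) stop("sampling variances must be >= 0")
  study <- factor(study)
  if (length(study) != k) stop("study ids must align with es")
  if (is.null(X)) X <- matrix(1, k, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (nrow(X) != k) stop("moderator matrix must align with es")
  if (qr(X)$rank < ncol(X)) stop("moderator matrix is rank deficient")
  structure(list(y = es, v = var, study = study, X = X, k = k, p = ncol(X),
                 n_studies = nlevels(study),
                 idx = split(seq_len(k), study)),
            class = "mlma_spec")
}

## Per-study Woodbury pieces: V is block-diagonal with blocks
## diag(v + sigma2_obs) + sigma2_study * J. Returns the GLS cross-products
## and log-determinant without forming V.
.mlma_quadforms <- function(spec, sigma2_study, sigma2_obs) {
  d <- spec$v + sigma2_obs
  if (any(d <= 0)) return(NULL)
  a <- 1 / d
  aX <- a * spec$X            # diag(a) %*% X, row-wise
  ay <- a * spec$y
  G <- rowsum(aX, spec$study)           # per-study colSums of aX
  gy <- rowsum(ay, spec$study)[, 1]
  S <- rowsum(a, spec$study)[, 1]
  cc <- sigma2_study / (1 + sigma2_study * S)
  list(XtViX = crossprod(spec$X, aX) - crossprod(G, cc * G),
       XtViy = colSums(ay * spec$X) - colSums(G * (cc * gy)),
       ytViy = sum(ay * spec$y) - sum(cc * gy^2),
       logdet = sum(log(d)) + sum(log1p(sigma2_study * S)))
}

#' Restricted log-likelihood of the multilevel model
#'
#' Evaluates the REML criterion at fixed variance components, profiling the
#' fixed effects out by generalized least squares. Used both by the fitter
#' and directly (e.g. for grid searches over the variance components).
#'
#' @param sigma2_study Between-study variance (>= 0).
#' @param sigma2_obs Observation-level (within-study) variance (>= 0).
#' @param spec An [mlma_spec()].
#' @return The restricted log-likelihood (scalar; `-Inf` for inadmissible
#'   variance values).
#' @export
reml_loglik <- function(sigma2_study, sigma2_obs, spec) {
  stopifnot(inherits(spec, "mlma_spec"))
  if (sigma2_study < 0 || sigma2_obs < 0) return(-Inf)
  qf <- .mlma_quadforms(spec, sigma2_study, sigma2_obs)
  if (is.null(qf)) return(-Inf)
  ch <- tryCatch(chol(qf$XtViX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), qf$XtViy))
  rss <- qf$ytViy - sum(qf$XtViy * beta)
  -0.5 * ((spec$k - spec$p) * log(2 * pi) + qf$logdet +
            2 * sum(log(diag(ch))) + rss)
}

.mlma_gls <- function(spec, sigma2_study, sigma2_obs) {
  qf <- .mlma_quadforms(spec, sigma2_study, sigma2_obs)
  vb <- solve(qf$XtViX)
  beta <- drop(vb %*% qf$XtViy)
  names(beta) <- colnames(spec$X)
  se <- sqrt(diag(vb))
  names(se) <- colnames(spec$X)
  list(beta = beta, se = se, vcov = vb)
}

#' Fit a multilevel meta-analytic model by REML
#'
#' Estimates the between-study and observation-level variance components by
#' restricted maximum likelihood (optimizing over log-variances with
#' `L-BFGS-B`, a Nelder-Mead fallback, and three deterministic starting
#' points), then the fixed effects by generalized least squares at the
#' optimum. With one effect size per study the two components are jointly
#' unidentifiable; the fit then reports a single total heterogeneity in
#' `sigma2_obs` with `identifiable = FALSE` and a warning.
#'
#' @param spec An [mlma_spec()].
#' @param reltol Convergence tolerance on the restricted log-likelihood.
#' @param warn_identifiability Warn when the two variance components cannot
#'   be separated (default `TRUE`); single-level callers set this to `FALSE`.
#' @return An object of class `"mlma_fit"`: coefficients `beta` with `se` and
#'   `vcov`, variance components `sigma2_study` and `sigma2_obs`, restricted
#'   log-likelihood `logLik`, `converged`, `identifiable`, `k`, `n_studies`.
#' @export
fit_multilevel <- function(spec, reltol = 1e-8, warn_identifiability = TRUE) {
  stopifnot(inherits(spec, "mlma_spec"))
  if (spec$k < spec$p + 2)
    stop("too few effect sizes (k >= p + 2 required)")
  floor_v <- 1e-10
  one_per_study <- max(tabulate(spec$study)) == 1L
  if (one_per_study && warn_identifiability)
    warning("one effect size per study: sigma2_study and sigma2_obs are ",
            "jointly unidentifiable; reporting total heterogeneity in ",
            "sigma2_obs")

  ## crude scale for starting values
  tot <- max(stats::var(spec$y) - mean(spec$v), mean(spec$v), floor_v)
  nll <- if (one_per_study) {
    function(th) -reml_loglik(0, exp(th[1]), spec)
  } else {
    function(th) -reml_loglik(exp(th[1]), exp(th[2]), spec)
  }
  npar <- if (one_per_study) 1L else 2L
  starts <- list(log(rep(tot / npar, npar)),
                 log(rep(tot / 10, npar) + floor_v),
                 log(rep(tot * 2, npar) + floor_v))
  lb <- rep(log(floor_v), npar)
  ub <- rep(log(tot * 1e4 + 1), npar)
  best <- NULL
  if (npar == 1L) {
    best <- stats::optim(starts[[1]], nll, method = "Brent",
                         lower = lb, upper = ub,
                         control = list(reltol = 1e-12))
  } else {
    for (st in starts) {
      op <- tryCatch(
        stats::optim(pmin(pmax(st, lb), ub), nll, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(factr = 1e5)),
        error = function(e) NULL)
      if (is.null(op))
        op <- stats::optim(pmin(pmax(st, lb), ub), nll,
                           method = "Nelder-Mead",
                           control = list(reltol = reltol, maxit = 2000))
      if (is.null(best) || op$value < best$value - 1e-12) best <- op
    }
    pol <- stats::optim(best$par, nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 2000))
    if (pol$value < best$value) best <- pol
  }
  s2 <- exp(best$par)
  s2[s2 <= floor_v * 1.01] <- 0
  s2 <- pmax(s2, 0)
  sigma2_study <- if (one_per_study) 0 else s2[1]
  sigma2_obs <- if (one_per_study) s2[1] else s2[2]
  ## floor for the GLS solve only, to keep V nonsingular when v has zeros
  eff_obs <- if (all(spec$v + sigma2_obs > 0)) sigma2_obs else floor_v
  gls <- .mlma_gls(spec, sigma2_study, eff_obs)
  structure(list(beta = gls$beta, se = gls$se, vcov = gls$vcov,
                 sigma2_study = sigma2_study, sigma2_obs = sigma2_obs,
                 logLik = -best$value,
                 converged = is.null(best$convergence) || best$convergence == 0,
                 identifiable = !one_per_study,
                 k = spec$k, n_studies = spec$n_studies,
                 v = spec$v, p = spec$p),
            class = "mlma_fit")
}

#' Wald coefficient table for a fitted multilevel model
#'
#' Normal-theory (z) tests and confidence intervals for the fixed effects.
#'
#' @param fit An [fit_multilevel()] result.
#' @param level Confidence level (default 0.95).
#' @return A data frame with `term`, `estimate`, `se`, `z`, `pval`,
#'   `ci_lb`, `ci_ub`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mlma_fit"))
  z <- fit$beta / fit$se
  crit <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             se = unname(fit$se),
             z = unname(z),
             pval = unname(2 * stats::pnorm(-abs(z))),
             ci_lb = unname(fit$beta - crit * fit$se),
             ci_ub = unname(fit$beta + crit * fit$se),
             row.names = NULL)
}

#' Typical sampling variance of a set of effect sizes
#'
#' @param v Sampling variances.
#' @param method `"weighted"` for the Higgins-style k-weighted formula
#'   (k-1) * sum(w) / (sum(w)^2 - sum(w^2)) with w = 1/v, or `"harmonic"`
#'   for the harmonic mean of the variances.
#' @return Scalar typical variance.
#' @export
typical_sampling_variance <- function(v, method = c("weighted", "harmonic")) {
  method <- match.arg(method)
  if (any(v <= 0)) stop("variances must be > 0")
  w <- 1 / v
  if (method == "weighted") {
    (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  } else {
    length(v) / sum(w)
  }
}

#' Heterogeneity statistics for a fitted multilevel model
#'
#' Multilevel I-squared: the share of total variability (heterogeneity plus
#' typical sampling variance) attributable to heterogeneity, reported both in
#' total and split by level.
#'
#' @param fit An [fit_multilevel()] result.
#' @param method Passed to [typical_sampling_variance()].
#' @return A list with `sigma2_study`, `sigma2_obs`, `v_typical`, `I2_total`,
#'   `I2_study`, `I2_obs`.
#' @export
heterogeneity_stats <- function(fit, method = "weighted") {
  stopifnot(inherits(fit, "mlma_fit"))
  vt <- typical_sampling_variance(fit$v, method)
  tot <- fit$sigma2_study + fit$sigma2_obs + vt
  list(sigma2_study = fit$sigma2_study,
       sigma2_obs = fit$sigma2_obs,
       v_typical = vt,
       I2_total = (fit$sigma2_study + fit$sigma2_obs) / tot,
       I2_study = fit$sigma2_study / tot,
       I2_obs = fit$sigma2_obs / tot)
}
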