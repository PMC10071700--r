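#' Compute an effect size and its sampling variance from summary statistics
#'
#' Supports the three metrics most common in ecological and evolutionary
#' meta-analysis: the standardized mean difference (Hedges' g, small-sample
#' corrected), the log response ratio (lnRR, delta-method variance), and
#' Fisher's z-transformed correlation (Zr).
#'
#' @param metric One of `"SMD"`, `"lnRR"`, `"Zr"`.
#' @param mean_e,mean_c Group means (experimental, control); SMD and lnRR.
#' @param sd_e,sd_c Group standard deviations (> 0); SMD and lnRR.
#' @param n_e,n_c Group sample sizes (>= 2); SMD and lnRR.
#' @param r Correlation coefficient in (-1, 1); Zr only.
#' @param n Total sample size (> 3); Zr only.
#'
#' @details
#' For SMD, the pooled-SD standardized difference is multiplied by the
#' small-sample correction J = 1 - 3/(4(n_e + n_c - 2) - 1) and the variance
#' is (n_e + n_c)/(n_e n_c) + g^2 / (2(n_e + n_c)). For lnRR both means must
#' be positive; the variance is sd_e^2/(n_e mean_e^2) + sd_c^2/(n_c mean_c^2).
#' For Zr, es = atanh(r) and var = 1/(n - 3).
#'
#' @return A list with elements `es` and `var`.
#' @export
compute_effect_size <- function(metric, mean_e = NULL, mean_c = NULL,
                                sd_e = NULL, sd_c = NULL,
                                n_e = NULL, n_c = NULL,
                                r = NULL, n = NULL) {
  metric <- match.arg(metric, c("SMD", "lnRR", "Zr"))
  if (metric == "Zr") {
    stopifnot(is.numeric(r), is.numeric(n))
    if (any(abs(r) >= 1)) stop("Zr requires |r| < 1")
    if (any(n <= 3)) stop("Zr requires n > 3")
    return(list(es = atanh(r), var = 1 / (n - 3)))
  }
  stopifnot(is.numeric(mean_e), is.numeric(mean_c),
            is.numeric(sd_e), is.numeric(sd_c),
            is.numeric(n_e), is.numeric(n_c))
  if (any(sd_e <= 0) || any(sd_c <= 0)) stop("group SDs must be > 0")
  if (any(n_e < 2) || any(n_c < 2)) stop("group sizes must be >= 2")
  if (metric == "SMD") {
    df <- n_e + n_c - 2
    sp <- sqrt(((n_e - 1) * sd_e^2 + (n_c - 1) * sd_c^2) / df)
    j <- 1 - 3 / (4 * df - 1)
    g <- j * (mean_e - mean_c) / sp
    v <- (n_e + n_c) / (n_e * n_c) + g^2 / (2 * (n_e + n_c))
    list(es = g, var = v)
  } else {
    if (any(mean_e <= 0) || any(mean_c <= 0))
      stop("lnRR requires positive group means")
    es <- log(mean_e / mean_c)
    v <- sd_e^2 / (n_e * mean_e^2) + sd_c^2 / (n_c * mean_c^2)
    list(es = es, var = v)
  }
}

#' Effective-sample-size predictor for small-study regressions
#'
#' For SMD and lnRR the point estimate is artefactually correlated with its
#' standard error, so bias regressions replace se_i by a function of the
#' effective sample size n_tilde = n_e n_c / (n_e + n_c): the linear
#' predictor sqrt(1/n_tilde) stands in for se_i, and its square 1/n_tilde
#' stands in for the sampling variance.
#'
#' @param n_e,n_c Group sample sizes (>= 1).
#' @param order `"linear"` (sqrt scale, replaces se) or `"quadratic"`
#'   (variance scale).
#' @return Numeric predictor value(s).
#' @export
effective_sample_predictor <- function(n_e, n_c, order = c("linear", "quadratic")) {
  order <- match.arg(order)
  if (any(is.na(n_e)) || any(is.na(n_c)))
    stop("missing group sizes: fall back to se/var predictors")
  if (any(n_e < 1) || any(n_c < 1)) stop("group sizes must be >= 1")
  q <- (n_e + n_c) / (n_e * n_c)
  if (order == "linear") sqrt(q) else q
}
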