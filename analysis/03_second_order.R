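#!/usr/bin/env Rscript
# Second-order meta-analysis: pool the standardized small-study (eta1) and
# time-lag (eta2) slopes across meta-analyses, for the full case set and the
# expected-direction (reduced) set, overall and per effect-size metric.
# On the null corpus both pooled slopes should be compatible with zero; on
# the biased corpus eta1 should pool positive and eta2 negative.

library(pubbias)

rows <- list()
for (label in c("null", "biased")) {
  std <- read.csv(sprintf("results/standardized_%s.csv", label))
  cases <- read.csv(sprintf("results/cases_%s.csv", label))
  for (coefname in c("eta1", "eta2")) {
    est <- std[[coefname]]
    se <- std[[paste0(coefname, "_se")]]
    expected <- if (coefname == "eta1") cases$expected_sign_beta1 else
      cases$expected_sign_beta2
    for (setname in c("full", "reduced")) {
      keep <- if (setname == "full") is.finite(est) else
        is.finite(est) & sign(est) == expected
      if (sum(keep) < 3) next
      p <- suppressWarnings(pool_coefficients(est[keep], se[keep],
                                              std$metric[keep]))
      rows[[length(rows) + 1L]] <- data.frame(
        corpus = label, coef = coefname, set = setname,
        estimate = p$estimate, se = p$se, ci_lb = p$ci_lb, ci_ub = p$ci_ub,
        pval = p$pval, tau2 = p$tau2, I2_among = p$I2_among, n = p$n_cases)
      cat(sprintf("%s %s (%s set): pooled = %+.3f [%.3f, %.3f], p = %.3g, tau2 = %.4f\n",
                  label, coefname, setname, p$estimate, p$ci_lb, p$ci_ub,
                  p$pval, p$tau2))
    }
  }
}
write.csv(do.call(rbind, rows), "results/second_order_pooled.csv",
          row.names = FALSE)
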