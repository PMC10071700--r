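# Shared fixtures, all built in code.

# Fixed 12-record, 5-study dataset with known sampling variances; values are
# frozen so grid-search oracles are reproducible without simulation.
fixture12 <- function() {
  data.frame(
    es    = c(0.52, 0.31, 0.18, 0.75, 0.62, -0.05, 0.12, 0.44, 0.39,
              0.58, 0.21, 0.35),
    var   = c(0.040, 0.055, 0.030, 0.120, 0.090, 0.045, 0.050, 0.070,
              0.035, 0.100, 0.025, 0.060),
    study = rep(c("s1", "s2", "s3", "s4", "s5"), c(3, 2, 3, 2, 2)),
    year  = c(2001, 2001, 2001, 2004, 2004, 2008, 2008, 2008, 2012,
              2012, 2015, 2015))
}

# One simulated meta-analysis in the analysis-ready per-meta layout.
one_meta <- function(seed = 1, n_studies = 20, metric = "SMD", mu = 0.3,
                     sigma_study = 0.2, sigma_obs = 0.1,
                     selection_strength = 0, decline = FALSE,
                     effects_per_study = c(1, 3)) {
  cfg <- generator_config(n_meta = 1, studies_per_meta = n_studies,
                          effects_per_study = effects_per_study,
                          metric = metric, mu = mu,
                          sigma_study = sigma_study, sigma_obs = sigma_obs,
                          selection_strength = selection_strength,
                          decline = decline, seed = seed)
  g <- generate_corpus(cfg)$corpus
  data.frame(es = g$es, var = g$var, study = g$study_id, year = g$year,
             n_e = g$n_e, n_c = g$n_c)
}
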