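#!/usr/bin/env Rscript
# Build the two synthetic literatures the downstream analyses run on:
#   (a) a null corpus -- no selection, no decline -- used to check calibration;
#   (b) a biased corpus -- significance-driven selection that relaxes over
#       time -- which carries both signatures the bias models look for
#       (small-study effect and decline effect).
# Ground truth sidecars are written next to each corpus.

library(pubbias)

dir.create("results", showWarnings = FALSE)

null_cfg <- generator_config(n_meta = 15, studies_per_meta = 30,
                             effects_per_study = c(1, 3), metric = "SMD",
                             mu = 0.3, sigma_study = 0.2, sigma_obs = 0.1,
                             selection_strength = 0, seed = 20240101)
null_corpus <- generate_corpus(null_cfg)
write_corpus(null_corpus$corpus, "results/corpus_null.csv",
             truth = null_corpus$truth)

biased_cfg <- generator_config(n_meta = 15, studies_per_meta = 40,
                               effects_per_study = c(1, 3), metric = "SMD",
                               mu = 0.1, sigma_study = 0.2, sigma_obs = 0.1,
                               group_size_range = c(5, 80),
                               selection_strength = 2, decline = TRUE,
                               seed = 20240102)
biased_corpus <- generate_corpus(biased_cfg)
write_corpus(biased_corpus$corpus, "results/corpus_biased.csv",
             truth = biased_corpus$truth)

cat("null corpus:  ", nrow(null_corpus$corpus), "effect sizes across",
    null_cfg$n_meta, "meta-analyses\n")
cat("biased corpus:", nrow(biased_corpus$corpus), "effect sizes across",
    biased_cfg$n_meta, "meta-analyses; selection removed",
    "the non-significant records of early years preferentially\n")
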