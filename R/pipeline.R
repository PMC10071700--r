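#' Pipeline configuration
#'
#' Collects every analysis toggle in one place so no variant requires a code
#' edit.
#'
#' @param alpha Two-sided significance level.
#' @param predictor_mode `"auto"` (effective-sample predictor where group
#'   sizes allow) or `"se"`.
#' @param correction_variant Decision-tree mapping: `"main_text"` or
#'   `"figure_caption"` (see [apply_decision_tree()]).
#' @param truth_mode Corrected-effect flavour used as the "true" effect in
#'   design calculations: `"type2"` (decision tree, default) or `"type1"`
#'   (full model).
#' @param min_k Minimum effect sizes for a meta-analysis to be analysed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = 0.05, predictor_mode = "auto",
                            correction_variant = "main_text",
                            truth_mode = c("type2", "type1"), min_k = 4) {
  truth_mode <- match.arg(truth_mode)
  structure(list(alpha = alpha, predictor_mode = predictor_mode,
                 correction_variant = correction_variant,
                 truth_mode = truth_mode, min_k = min_k),
            class = "pipeline_config")
}

## Pool one standardized coefficient over the full and reduced
## (expected-direction) case sets, overall and by metric.
.pool_variants <- function(est, se, expected, metric) {
  full <- pool_coefficients(est, se, metric)
  ok <- !is.na(est) & !is.na(expected) & sign(est) == expected
  reduced <- if (sum(ok, na.rm = TRUE) >= 2)
    suppressWarnings(pool_coefficients(est[ok], se[ok], metric[ok])) else NULL
  list(full = full, reduced = reduced)
}

#' Run the complete publication-bias pipeline on a corpus
#'
#' Per meta-analysis: the intercept-only multilevel fit, the bias detection
#' and correction models with the sign decision tree, and the standardized
#' counterparts. Across meta-analyses: second-order pooling of the
#' standardized small-study and decline slopes (full and expected-direction
#' reduced case sets, with an effect-size-type moderator), folded-normal
#' shrinkage estimates pooled and back-transformed, and power / Type M /
#' Type S errors under uncorrected and bias-corrected truths at the
#' sampling and meta-analysis levels (the latter with and without the
#' post hoc significance filter). Deterministic given corpus and config.
#'
#' @param corpus A corpus data frame (see [load_corpus()]); validated here.
#' @param config A [pipeline_config()].
#' @return A list of class `"results_bundle"`: `cases`, `standardized`,
#'   `pooled` (per-coefficient second-order summaries), `folded` +
#'   `pooled_D` + `backtransformed`, `design_sampling`, `design_meta`,
#'   `aggregates`, `counts`, `skipped`, `config`.
#' @export
run_pipeline <- function(corpus, config = pipeline_config()) {
  corpus <- validate_corpus(corpus)
  ids <- unique(corpus$meta_id)
  cases <- list(); std <- list(); skipped <- list()
  for (id in ids) {
    sub <- corpus[corpus$meta_id == id, , drop = FALSE]
    metric <- sub$metric[1]
    dat <- data.frame(es = sub$es, var = sub$var, study = sub$study_id,
                      year = sub$year, n_e = sub$n_e, n_c = sub$n_c)
    if (nrow(dat) < config$min_k || length(unique(dat$study)) < 2 ||
        stats::sd(dat$es) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(meta_id = id, reason = if (nrow(dat) < config$min_k)
          "k too small" else if (length(unique(dat$study)) < 2)
            "fewer than 2 studies" else "zero response variance")
      next
    }
    res <- tryCatch(
      list(case = analyze_meta(dat, metric, meta_id = id,
                               predictor_mode = config$predictor_mode,
                               variant = config$correction_variant,
                               alpha = config$alpha),
           std = standardize_case(dat, metric, meta_id = id,
                                  predictor_mode = config$predictor_mode,
                                  variant = config$correction_variant)),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(meta_id = id, reason = conditionMessage(res))
      next
    }
    cases[[length(cases) + 1L]] <- res$case
    std[[length(std) + 1L]] <- res$std
  }
  if (!length(cases)) stop("no analysable meta-analyses in the corpus")
  cases <- do.call(rbind, cases)
  std <- do.call(rbind, std)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(meta_id = character(0), reason = character(0))

  ## second-order pooling of standardized slopes
  pooled <- list(
    eta1 = .pool_variants(std$eta1, std$eta1_se,
                          cases$expected_sign_beta1, std$metric),
    eta2 = .pool_variants(std$eta2, std$eta2_se,
                          cases$expected_sign_beta2, std$metric))

  ## folded shrinkage: full dataset uses the full-model (type 1) corrected
  ## intercepts, the reduced dataset the decision-tree (type 2) ones
  fold_tab <- function(eta_c, se_c) {
    do.call(rbind, lapply(seq_len(nrow(std)), function(i) {
      f <- difference_and_fold(std$eta0_overall[i], std$eta0_overall_se[i],
                               eta_c[i], se_c[i])
      data.frame(meta_id = std$meta_id[i], metric = std$metric[i],
                 D = f$D, var_D = f$var_D, D_f = f$D_f, var_D_f = f$var_D_f)
    }))
  }
  folded_full <- fold_tab(std$eta0_corrected1, std$eta0_corrected1_se)
  folded_red <- fold_tab(std$eta0_corrected2, std$eta0_corrected2_se)
  pooled_D <- list(
    full = pool_differences(folded_full$D_f, folded_full$var_D_f,
                            folded_full$metric),
    reduced = pool_differences(folded_red$D_f, folded_red$var_D_f,
                               folded_red$metric))
  which_fold <- if (config$truth_mode == "type2") folded_red else folded_full
  backtr <- backtransform(which_fold$D_f, std$sd_response, std$metric)

  ## design metrics
  corr_col <- if (config$truth_mode == "type2") "beta0_corrected2"
              else "beta0_corrected1"
  truth_of <- function(mode) {
    if (mode == "uncorrected") cases$beta0_overall else cases[[corr_col]]
  }
  design_sampling <- list(); design_meta <- list(); aggregates <- list()
  for (mode in c("uncorrected", "corrected")) {
    tr <- truth_of(mode)
    m <- match(corpus$meta_id, cases$meta_id)
    keep <- !is.na(m)
    dm <- design_metrics(tr[m[keep]], sqrt(corpus$var[keep]), config$alpha)
    tab <- data.frame(meta_id = corpus$meta_id[keep],
                      study = paste(corpus$meta_id, corpus$study_id,
                                    sep = ":")[keep],
                      metric = corpus$metric[keep],
                      power = dm$power, type_s = dm$type_s,
                      type_m = dm$type_m)
    design_sampling[[mode]] <- tab
    dmm <- design_metrics(tr, cases$beta0_overall_se, config$alpha)
    mtab <- data.frame(meta_id = cases$meta_id, metric = cases$metric,
                       k = cases$k, power = dmm$power, type_s = dmm$type_s,
                       type_m = dmm$type_m,
                       p_overall = cases$beta0_overall_p)
    design_meta[[mode]] <- mtab
    for (stat in c("power", "type_s", "type_m")) {
      aggregates[[paste("sampling", mode, stat, sep = ".")]] <-
        aggregate_sampling_level(tab[[stat]], tab$study)
      aggregates[[paste("meta", mode, stat, sep = ".")]] <-
        aggregate_meta_level(mtab[[stat]], mtab$k)
      aggregates[[paste("meta_filtered", mode, stat, sep = ".")]] <-
        aggregate_meta_level(mtab[[stat]], mtab$k, mtab$p_overall,
                             post_hoc_filter = TRUE, alpha = config$alpha)
    }
  }

  bundle <- list(cases = cases, standardized = std, pooled = pooled,
                 folded = list(full = folded_full, reduced = folded_red),
                 pooled_D = pooled_D, backtransformed = backtr,
                 design_sampling = design_sampling,
                 design_meta = design_meta, aggregates = aggregates,
                 skipped = skipped, config = config)
  bundle$counts <- summarize_counts(bundle)
  class(bundle) <- "results_bundle"
  bundle
}

#' Count summaries of bias evidence across a results bundle
#'
#' Tallies, over the analysed meta-analyses: significant small-study slopes,
#' slopes in the expected direction, the same for the time-lag slopes,
#' initially significant overall effects, and how many of those became
#' non-significant after bias correction. Percentages are rounded to whole
#' numbers.
#'
#' @param bundle A [run_pipeline()] result (or any list with a `cases`
#'   table and `config`).
#' @return A data frame with `quantity`, `count`, `total`, `percent`.
#' @export
summarize_counts <- function(bundle) {
  ca <- bundle$cases
  alpha <- bundle$config$alpha
  n <- nrow(ca)
  corr_p <- if (bundle$config$truth_mode == "type1")
    ca$beta0_corrected1_p else ca$beta0_corrected2_p
  sig0 <- !is.na(ca$beta0_overall_p) & ca$beta0_overall_p < alpha
  rows <- list(
    c("significant_beta1", sum(ca$beta1_p < alpha, na.rm = TRUE), n),
    c("expected_direction_beta1",
      sum(sign(ca$beta1) == ca$expected_sign_beta1, na.rm = TRUE), n),
    c("significant_beta2", sum(ca$beta2_p < alpha, na.rm = TRUE), n),
    c("expected_direction_beta2",
      sum(sign(ca$beta2) == ca$expected_sign_beta2, na.rm = TRUE), n),
    c("significant_overall", sum(sig0), n),
    c("significant_to_nonsignificant",
      sum(sig0 & corr_p >= alpha, na.rm = TRUE), sum(sig0)))
  out <- data.frame(quantity = vapply(rows, `[`, "", 1),
                    count = as.integer(vapply(rows, `[`, "", 2)),
                    total = as.integer(vapply(rows, `[`, "", 3)))
  out$percent <- ifelse(out$total > 0,
                        as.integer(round(100 * out$count / out$total)), NA)
  out
}
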