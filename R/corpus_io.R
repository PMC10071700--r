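#' Load a meta-analytic corpus from CSV
#'
#' The canonical schema has one row per effect size with columns `meta_id`,
#' `study_id`, `obs_id`, `metric` (SMD / lnRR / Zr), `es`, `var` and/or
#' `se`, optional `n_e`, `n_c`, `n_total`, and `year`. Validation enforces
#' unique (meta_id, study_id, obs_id) keys, a single metric per
#' meta-analysis, positive variances, and se = sqrt(var) to 1e-8 when both
#' are present; missing group sizes are permitted (bias models then fall
#' back to the se / var predictor).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
load_corpus <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_corpus(tab)
}

#' @rdname load_corpus
#' @param tab An in-memory corpus data frame to validate.
#' @export
validate_corpus <- function(tab) {
  need <- c("meta_id", "study_id", "obs_id", "metric", "year")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!("var" %in% names(tab)) && !("se" %in% names(tab)))
    stop("missing required columns: var or se")
  if (!("var" %in% names(tab))) tab$var <- tab$se^2
  if (!("es" %in% names(tab))) stop("missing required columns: es")
  if ("se" %in% names(tab)) {
    bad <- which(abs(tab$se - sqrt(tab$var)) > 1e-8)
    if (length(bad))
      stop("se and var inconsistent in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(tab$meta_id, tab$study_id, tab$obs_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (meta_id, study_id, obs_id) key in row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  if (any(!is.finite(tab$var)) || any(tab$var <= 0))
    stop("non-positive sampling variance in row(s): ",
         paste(utils::head(which(!(tab$var > 0)), 5), collapse = ", "))
  if (!all(tab$metric %in% c("SMD", "lnRR", "Zr")))
    stop("unknown metric value(s): ",
         paste(unique(setdiff(tab$metric, c("SMD", "lnRR", "Zr"))),
               collapse = ", "))
  mixed <- tapply(tab$metric, tab$meta_id, function(x) length(unique(x)))
  if (any(mixed > 1))
    stop("mixed metrics within meta-analysis: ",
         paste(names(mixed)[mixed > 1], collapse = ", "))
  for (col in c("n_e", "n_c", "n_total"))
    if (!(col %in% names(tab))) tab[[col]] <- NA_real_
  tab
}

#' Write a corpus (and optional truth sidecar) to CSV
#'
#' @param corpus Corpus data frame.
#' @param path Output CSV path.
#' @param truth Optional generator truth table; written next to `path` with
#'   a `_truth.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, truth = NULL) {
  utils::write.csv(corpus, path, row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(truth, sub("\\.csv$", "_truth.csv", path),
                     row.names = FALSE)
  invisible(path)
}
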