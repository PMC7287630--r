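#' Model-build pipeline configuration
#'
#' Freezes everything the shuffle test must re-run per permutation: the
#' candidate regions, whether the collinearity screen and recursive
#' feature elimination are re-applied, the split ratio, and the covariate
#' set.  A seed policy is mandatory: every internal randomization is
#' derived from the single seed handed to the runner.
#'
#' @param candidates candidate region columns (default: all regions).
#' @param outcome metadata column (default `"group"`).
#' @param ratio training fraction of the stratified split (default 0.7).
#' @param screen apply [screen_three_way()] at `r_max` first (default TRUE).
#' @param rfe re-run [recursive_feature_elimination()] on each training
#'   partition (default TRUE -- the full model build; setting FALSE is a
#'   fast mode that is *not* the full build and is labelled as such in the
#'   result).
#' @param r_max collinearity gate (default 0.9).
#' @param covariates as in [fit_logistic()].
#' @param inner_k inner folds for RFE (default 5).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(candidates = NULL, outcome = "group",
                            ratio = 0.7, screen = TRUE, rfe = TRUE,
                            r_max = 0.9,
                            covariates = c("age", "sex", "bmi"),
                            inner_k = 5) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must be in (0, 1)")
  structure(list(candidates = candidates, outcome = outcome, ratio = ratio,
                 screen = screen, rfe = rfe, r_max = r_max,
                 covariates = covariates, inner_k = inner_k),
            class = "pipeline_config")
}

#' Run the full model build once
#'
#' Stratified split at the configured ratio, optional three-way
#' collinearity screen, optional RFE on the training partition, fit, and
#' held-out evaluation.
#'
#' @param table a [feature_table()].
#' @param config a [pipeline_config()].
#' @param seed RNG seed governing the split, the screen splits and RFE.
#' @return list with `model`, `report`, `accuracy`, `selected`, `split`.
#' @export
run_pipeline <- function(table, config, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  candidates <- config$candidates
  if (is.null(candidates)) candidates <- region_names(table)
  labels <- table$meta[[config$outcome]]
  sp <- stratified_split(labels, config$ratio, seed)
  if (config$screen)
    candidates <- intersect(
      candidates, screen_three_way(table, sp$train, config$r_max)$retained)
  train <- subset_feature_table(table, sp$train)
  test <- subset_feature_table(table, sp$test)
  selected <- candidates
  if (config$rfe)
    selected <- recursive_feature_elimination(
      train, config$outcome, candidates, covariates = config$covariates,
      inner_k = config$inner_k, seed = seed)$selected
  model <- suppressWarnings(fit_logistic(train, config$outcome, selected,
                                         covariates = config$covariates))
  report <- evaluate(model, test)
  list(model = model, report = report,
       accuracy = unname(report$metrics["accuracy"]),
       selected = selected, split = sp)
}

#' Label-shuffling permutation significance test
#'
#' Re-runs the entire model build (fresh stratified split, screen, RFE,
#' fit, held-out accuracy -- per the configuration) on outcome labels
#' permuted uniformly at random, `n` times.  If no shuffled run reaches
#' the observed accuracy after `n` runs, the test escalates and keeps
#' running up to `max_n`.  The empirical p-value is
#' `exceedances / n_runs` by default, matching the published arithmetic;
#' `plus_one = TRUE` switches to the (k+1)/(n+1) small-sample variant.
#' Per-run seeds come from a counter-based child-seed scheme, so runs are
#' independent yet the whole test reproduces bit-for-bit from `seed`.
#'
#' @param table a [feature_table()].
#' @param config a [pipeline_config()].
#' @param observed_accuracy accuracy of the unshuffled build, in [0, 1].
#' @param n permutations (default 1000).
#' @param max_n escalation ceiling (default 10000).
#' @param seed master seed.
#' @param plus_one use the (k+1)/(n+1) estimator (default FALSE).
#' @return an object of class `permutation_result`: observed accuracy,
#'   `n_runs`, `exceedance_count` (runs with shuffled accuracy >=
#'   observed), `empirical_p`, `escalated`, `run_accuracy`, `seed`.
#' @export
shuffle_test <- function(table, config, observed_accuracy, n = 1000,
                         max_n = 10000, seed = 1L, plus_one = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.numeric(observed_accuracy) || observed_accuracy < 0 ||
      observed_accuracy > 1)
    stop("observed_accuracy must be in [0, 1]")
  if (n < 1 || max_n < n) stop("need 1 <= n <= max_n")
  child <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, max_n))
  labels <- as.character(table$meta[[config$outcome]])

  one_run <- function(run) {
    s <- child[run]
    shuffled <- table
    shuffled$meta[[config$outcome]] <-
      .with_seed(s, sample(labels))
    run_pipeline(shuffled, config, seed = s + 1L)$accuracy
  }

  acc <- vapply(seq_len(n), one_run, numeric(1))
  exceed <- sum(acc >= observed_accuracy)
  escalated <- FALSE
  if (exceed == 0L && max_n > n) {
    escalated <- TRUE
    extra <- vapply(seq(n + 1L, max_n), one_run, numeric(1))
    acc <- c(acc, extra)
    exceed <- sum(acc >= observed_accuracy)
  }
  n_runs <- length(acc)
  p <- if (plus_one) (exceed + 1) / (n_runs + 1) else exceed / n_runs
  structure(list(observed_accuracy = observed_accuracy, n_runs = n_runs,
                 exceedance_count = exceed, empirical_p = p,
                 escalated = escalated, run_accuracy = acc,
                 plus_one = plus_one, seed = seed,
                 full_build = isTRUE(config$rfe)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result>", x$exceedance_count, "of", x$n_runs,
      "shuffled builds reached the observed accuracy of",
      round(x$observed_accuracy, 4), "-> empirical p =",
      signif(x$empirical_p, 4),
      if (x$escalated) "(escalated)" else "", "\n")
  invisible(x)
}

#' Significance verdict for a permutation result
#'
#' Significant iff the empirical p-value is strictly below `alpha`.
#'
#' @param result a `permutation_result`.
#' @param alpha significance level (default 0.05).
#' @return list with `significant` (logical) and `narrative` (character).
#' @export
significance_verdict <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "permutation_result"))
  sig <- result$empirical_p < alpha
  narrative <- sprintf(
    paste0("%d of %d label-shuffled model builds reached the observed ",
           "accuracy of %.3f (empirical p = %.4g); the model %s ",
           "significant at alpha = %g."),
    result$exceedance_count, result$n_runs, result$observed_accuracy,
    result$empirical_p, if (sig) "is" else "is not", alpha)
  list(significant = sig, narrative = narrative)
}

#' Serialize a permutation result as JSON (and per-run accuracies as CSV)
#' @param result a `permutation_result`; @param path JSON path.
#' @param runs_csv optional path for the single-column per-run accuracies.
#' @export
write_permutation_result <- function(result, path, runs_csv = NULL) {
  x <- result[c("observed_accuracy", "n_runs", "exceedance_count",
                "empirical_p", "escalated", "plus_one", "seed",
                "full_build")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(runs_csv))
    utils::write.csv(data.frame(accuracy = result$run_accuracy), runs_csv,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
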