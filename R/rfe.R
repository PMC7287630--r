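#' Recursive feature elimination over region features
#'
#' Greedy backward elimination: the model is fitted on all current
#' candidates (plus the exempt covariates), the feature with the smallest
#' importance -- the absolute standardized coefficient, |beta_j| * sd(x_j)
#' (averaged over classes for multi-class outcomes) -- is dropped, and the
#' cycle repeats down to one feature.  The retained count is then chosen
#' to maximize inner stratified cross-validated accuracy along the
#' elimination path, ties broken toward fewer features.
#'
#' @param table a [feature_table()] (training rows only; run RFE inside an
#'   outer resampling loop yourself if nested selection is wanted).
#' @param outcome metadata column (default `"group"`).
#' @param candidates character vector of candidate region columns.
#' @param covariates always included, never eliminated.
#' @param inner_k folds for the inner accuracy estimate (default 5).
#' @param min_features smallest model size considered (default 1).
#' @param seed RNG seed for the inner folds.
#' @return list with `selected` (region names), `path` (data.frame:
#'   size, dropped feature, inner CV accuracy), `elimination_order`, and
#'   the arguments used, recorded as training metadata.
#' @export
recursive_feature_elimination <- function(table, outcome = "group",
                                          candidates,
                                          covariates = c("age", "sex",
                                                         "bmi"),
                                          inner_k = 5, min_features = 1,
                                          seed = 1L) {
  if (!length(candidates)) stop("no candidate features supplied")
  miss <- setdiff(candidates, region_names(table))
  if (length(miss))
    stop("unknown candidate(s): ", paste(miss, collapse = ", "))
  min_features <- max(1L, min_features)
  sds <- apply(table$counts[, candidates, drop = FALSE], 2L, stats::sd)

  current <- candidates
  order_dropped <- character(0)
  sets <- list()
  sets[[length(current)]] <- current
  while (length(current) > min_features) {
    fit <- suppressWarnings(fit_logistic(table, outcome, current,
                                         covariates = covariates))
    imp <- if (!is.null(fit$per_class)) {
      rowMeans(vapply(fit$per_class,
                      function(co) abs(co[current]) * sds[current],
                      numeric(length(current))))
    } else {
      abs(fit$coefficients[current]) * sds[current]
    }
    worst <- current[order(imp, seq_along(current))[1L]]
    order_dropped <- c(order_dropped, worst)
    current <- setdiff(current, worst)
    sets[[length(current)]] <- current
  }

  sizes <- seq(min_features, length(candidates))
  cv_acc <- vapply(sizes, function(sz) {
    kfold_cv(table, outcome, sets[[sz]], k = inner_k,
             seed = seed, covariates = covariates)$mean_accuracy
  }, numeric(1))
  # max accuracy, ties toward fewer features
  best_size <- sizes[which.max(cv_acc)]
  selected <- sets[[best_size]]
  path <- data.frame(size = sizes, inner_cv_accuracy = cv_acc)
  list(selected = selected, path = path,
       elimination_order = order_dropped,
       settings = list(outcome = outcome, covariates = covariates,
                       inner_k = inner_k, min_features = min_features,
                       seed = seed,
                       importance = "absolute standardized coefficient"))
}
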