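#' Stratified train/test split with largest-remainder rounding
#'
#' Allocates `round(ratio * n)` training subjects across classes by
#' largest remainder, so class proportions are preserved as closely as
#' integer counts allow (e.g. 111 subjects split 80/31 at 70:30 give a
#' training set of 78 = 56 + 22).  Membership is random within class,
#' deterministic given the seed.
#'
#' @param labels character/factor vector of class labels.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with integer vectors `train` and `test`, and `ratio`.
#' @export
stratified_split <- function(labels, ratio, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must be in (0, 1)")
  labels <- as.character(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  n_c <- table(labels)[classes]
  target <- ratio * n_c
  alloc <- floor(target)
  extra <- round(ratio * n) - sum(alloc)
  if (extra > 0) {
    ord <- order(target - alloc, decreasing = TRUE)
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
  }
  train <- .with_seed(seed, unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, alloc[[cl]])
  }), use.names = FALSE))
  train <- sort(train)
  if (any(alloc < 1L) || any(n_c - alloc < 1L))
    stop("infeasible ratio ", ratio, ": a class would have an empty ",
         "training or test partition")
  list(train = train, test = setdiff(seq_len(n), train), ratio = ratio)
}

# stratified fold assignment: shuffle within class, deal round-robin with
# a cycle that continues across classes so every fold is non-empty for
# any k <= n (k = n gives leave-one-out)
.stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  ord <- .with_seed(seed, unlist(lapply(sort(unique(labels)), function(cl)
    sample(which(labels == cl))), use.names = FALSE))
  fold <- integer(length(labels))
  fold[ord] <- rep_len(seq_len(k), length(ord))
  fold
}

#' Stratified k-fold cross-validated accuracy
#'
#' Each fold is held out exactly once; the model (given features plus the
#' standard covariates) is refitted on the remaining folds and accuracy
#' measured on the held-out fold.  Separation warnings from individual
#' fold fits are suppressed (the ridge-stabilized refit is the intended
#' behaviour during resampling).
#'
#' @param table a [feature_table()].
#' @param outcome metadata column (default `"group"`).
#' @param features region columns to use.
#' @param k number of folds (default 10); requires `n >= k`.
#' @param seed RNG seed for fold assignment.
#' @param covariates as in [fit_logistic()].
#' @return list with `mean_accuracy`, `fold_accuracy`, `k`, `seed`.
#' @export
kfold_cv <- function(table, outcome = "group", features, k = 10, seed = 1L,
                     covariates = c("age", "sex", "bmi")) {
  n <- nrow(table$counts)
  if (n < k) stop("n = ", n, " < k = ", k, " folds")
  fold <- .stratified_folds(table$meta[[outcome]], k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- subset_feature_table(table, which(fold != f))
    te <- subset_feature_table(table, which(fold == f))
    fit <- suppressWarnings(fit_logistic(tr, outcome, features,
                                         covariates = covariates))
    mean(predict(fit, te) == as.character(te$meta[[outcome]]))
  }, numeric(1))
  list(mean_accuracy = mean(acc), fold_accuracy = acc, k = k, seed = seed)
}

#' Search the training:testing split ratio
#'
#' For each candidate ratio (default 50:50 to 90:10 by 10), repeated
#' stratified splits are drawn, the model is refitted on each training
#' partition and scored on its test partition.  The chosen ratio
#' maximizes mean test accuracy, with ties broken toward the most stable
#' ratio (lowest SD), then toward the smaller ratio.  Ratios infeasible
#' for the class sizes are skipped with a warning.
#'
#' @param table a [feature_table()].
#' @param outcome metadata column (default `"group"`).
#' @param features region columns to use.
#' @param ratios candidate training fractions.
#' @param repeats stratified splits per ratio (default 20).
#' @param seed RNG seed.
#' @param covariates as in [fit_logistic()].
#' @return list with `chosen_ratio`, `summary` (per-ratio mean/sd) and
#'   `accuracies` (matrix of per-repeat accuracies).
#' @export
split_search <- function(table, outcome = "group", features,
                         ratios = seq(0.5, 0.9, by = 0.1), repeats = 20,
                         seed = 1L, covariates = c("age", "sex", "bmi")) {
  lab <- table$meta[[outcome]]
  acc <- matrix(NA_real_, length(ratios), repeats,
                dimnames = list(sprintf("%.0f:%.0f", 100 * ratios,
                                        100 * (1 - ratios)), NULL))
  for (i in seq_along(ratios)) {
    feasible <- tryCatch({
      stratified_split(lab, ratios[i], seed)
      TRUE
    }, error = function(e) FALSE)
    if (!feasible) {
      warning("ratio ", ratios[i], " infeasible for these class sizes; ",
              "skipped")
      next
    }
    for (r in seq_len(repeats)) {
      sp <- stratified_split(lab, ratios[i], seed + 1000L * i + r)
      tr <- subset_feature_table(table, sp$train)
      te <- subset_feature_table(table, sp$test)
      fit <- suppressWarnings(fit_logistic(tr, outcome, features,
                                           covariates = covariates))
      acc[i, r] <- mean(predict(fit, te) == as.character(te$meta[[outcome]]))
    }
  }
  mean_acc <- rowMeans(acc)
  sd_acc <- apply(acc, 1L, stats::sd)
  usable <- which(!is.na(mean_acc))
  if (!length(usable)) stop("no feasible ratio")
  best <- usable[order(-mean_acc[usable], sd_acc[usable], ratios[usable])[1L]]
  list(chosen_ratio = ratios[best],
       summary = data.frame(ratio = ratios, mean_accuracy = mean_acc,
                            sd_accuracy = sd_acc, row.names = NULL),
       accuracies = acc)
}
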