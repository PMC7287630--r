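#' @section Model:
#' The classifier is the logistic model
#' \deqn{p(x) = 1 / (1 + e^{-(\beta_0 + \beta_1 x_1 + ... + \beta_i x_i)})}
#' over per-region suprathreshold voxel counts, with age, sex (male
#' indicator) and BMI always included as covariates.  Coefficients maximize
#' the binomial log-likelihood; the default solver is deterministic
#' iteratively-reweighted least squares (Newton), with a stochastic
#' gradient descent mode (polished by Newton to the same tolerance) for
#' fidelity to descriptions of SGD-trained logistic models.
#' @name roilogit-model
#' @keywords internal
NULL

# IRLS maximum likelihood for binary logit, optional ridge (intercept
# unpenalized).  Returns coefficients, convergence flag, score vector.
.logit_irls <- function(X, y, lambda = 0, tol = 1e-10, maxit = 200,
                        start = NULL) {
  p <- ncol(X)
  beta <- if (is.null(start)) rep(0, p) else start
  pen <- c(0, rep(lambda, p - 1L))          # column 1 is the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step))
      step <- drop(MASS_ginv(H) %*% grad)
    # dampen huge steps to keep Newton stable under near-separation
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(grad)) < tol && max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  grad <- drop(crossprod(X, y - mu)) - pen * beta
  list(coef = beta, gradient = grad, converged = max(abs(grad)) < 1e-6,
       fitted = mu, lambda = lambda)
}

# Moore-Penrose pseudoinverse (small helper; avoids a MASS dependency)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1L]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# plain SGD epochs used as a starting point for the Newton polish
.logit_sgd <- function(X, y, epochs = 60, rate = 0.05, seed = 1L) {
  n <- nrow(X)
  beta <- rep(0, ncol(X))
  sc <- pmax(apply(X, 2L, function(c) max(abs(c))), 1)
  .with_seed(seed, for (e in seq_len(epochs)) {
    lr <- rate / (1 + 0.1 * e)
    for (i in sample.int(n)) {
      mu <- stats::plogis(sum(X[i, ] * beta))
      beta <- beta + lr * (y[i] - mu) * X[i, ] / sc^2
    }
  })
  beta
}

.design_matrix <- function(table, features, covariates) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(features, region_names(table))
  if (length(miss))
    stop("unknown feature column(s): ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             table$counts[, features, drop = FALSE])
  for (cv in covariates) {
    col <- switch(cv,
                  sex = as.numeric(table$meta$sex == "M"),
                  table$meta[[cv]])
    if (is.null(col)) stop("unknown covariate: ", cv)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

.outcome_vector <- function(table, outcome, positive = NULL) {
  y <- table$meta[[outcome]]
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  lev <- sort(unique(as.character(y)))
  if (length(lev) < 2L)
    stop("degenerate outcome: only one class ('", lev, "') present")
  if (length(lev) == 2L) {
    if (is.null(positive))
      positive <- if ("case" %in% lev) "case" else lev[2L]
    lev <- c(setdiff(lev, positive), positive)   # negative class first
  }
  list(y = as.character(y), levels = lev)
}

#' Fit the logistic model with demographic covariates
#'
#' Binary outcomes are fitted by maximum likelihood; a 3-class (or any
#' multi-class) outcome is fitted one-vs-rest, returning one coefficient
#' set per class over a shared feature support.  Age, sex and BMI are
#' included in every regression unless `covariates` is overridden.  Under
#' (quasi-)separation the fit is flagged with a convergence warning and
#' refitted with a small ridge penalty so finite coefficients are still
#' returned.
#'
#' @param table a [feature_table()].
#' @param outcome metadata column name, default `"group"`.
#' @param features character vector of region columns to use.
#' @param covariates covariate columns; default `c("age","sex","bmi")`.
#'   `NULL` fits regions only (for toy problems without metadata signal).
#' @param method `"irls"` (deterministic Newton, default) or `"sgd"`
#'   (stochastic gradient descent epochs followed by a Newton polish; both
#'   satisfy the same score tolerance at the optimum).
#' @param positive label of the positive class for binary outcomes
#'   (default `"case"` when present).
#' @param ridge penalty used only for the stabilized refit under
#'   separation.
#' @param seed RNG seed (used by the SGD mode only).
#' @return an object of class `fitted_logit`: intercept(s), named
#'   coefficients (per class for multi-class), raw and Sidak-adjusted Wald
#'   p-values, score vector, and training metadata including the training
#'   subject ids.
#' @export
fit_logistic <- function(table, outcome = "group", features,
                         covariates = c("age", "sex", "bmi"),
                         method = c("irls", "sgd"), positive = NULL,
                         ridge = 1e-3, seed = 1L) {
  method <- match.arg(method)
  out <- .outcome_vector(table, outcome, positive)
  X <- .design_matrix(table, features, covariates)
  n_class <- length(out$levels)

  fit_one <- function(y01) {
    start <- if (method == "sgd") .logit_sgd(X, y01, seed = seed) else NULL
    fit <- .logit_irls(X, y01, lambda = 0, start = start)
    separated <- any(fit$fitted > 1 - 1e-8 & y01 == 1) &&
      any(fit$fitted < 1e-8 & y01 == 0) && max(abs(fit$coef)) > 10
    if (!fit$converged || separated) {
      warning("possible separation / non-convergence; ",
              "returning ridge-stabilized fit (lambda = ", ridge, ")")
      fit <- .logit_irls(X, y01, lambda = ridge, start = start)
      fit$stabilized <- TRUE
    } else fit$stabilized <- FALSE
    fit
  }

  wald_p <- function(fit) {
    w <- pmax(fit$fitted * (1 - fit$fitted), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + c(0, rep(fit$lambda, ncol(X) - 1L))
    se <- sqrt(pmax(diag(MASS_ginv(H)), 0))
    z <- ifelse(se > 0, fit$coef / se, NA_real_)
    2 * stats::pnorm(-abs(z))
  }

  m_regions <- length(features)
  if (n_class == 2L) {
    y01 <- as.numeric(out$y == out$levels[2L])
    fit <- fit_one(y01)
    coefs <- stats::setNames(fit$coef, colnames(X))
    p_raw <- stats::setNames(wald_p(fit), colnames(X))
    coef_list <- NULL
    p_list <- NULL
    score <- fit$gradient
    stabilized <- fit$stabilized
  } else {
    fits <- lapply(out$levels, function(cl) fit_one(as.numeric(out$y == cl)))
    coef_list <- lapply(fits, function(f) stats::setNames(f$coef,
                                                          colnames(X)))
    p_list <- lapply(fits, function(f) stats::setNames(wald_p(f),
                                                       colnames(X)))
    names(coef_list) <- names(p_list) <- out$levels
    coefs <- coef_list[[1L]]
    p_raw <- p_list[[1L]]
    score <- do.call(cbind, lapply(fits, `[[`, "gradient"))
    stabilized <- any(vapply(fits, `[[`, logical(1), "stabilized"))
  }
  structure(list(
    intercept = unname(coefs["(Intercept)"]),
    coefficients = coefs[setdiff(names(coefs), "(Intercept)")],
    per_class = coef_list,
    classes = out$levels, outcome = outcome, positive = out$levels[n_class],
    features = features, covariates = covariates,
    p_values = p_raw, p_values_per_class = p_list,
    p_sidak = sidak_adjust(p_raw, max(m_regions, 1L)),
    m_regions = m_regions,
    score = score, stabilized = stabilized, method = method,
    train_ids = table$meta$subject_id),
    class = "fitted_logit")
}

#' @export
print.fitted_logit <- function(x, ...) {
  cat("<fitted_logit>", length(x$classes), "classes (",
      paste(x$classes, collapse = "/"), "),", length(x$features),
      "region feature(s) +", length(x$covariates), "covariate(s);",
      if (x$stabilized) "ridge-stabilized;" else "", "solver:", x$method,
      "\n")
  invisible(x)
}

#' Evaluate the logit at a named feature vector
#'
#' Returns \eqn{1/(1+e^{-\eta})} with \eqn{\eta} the intercept plus the
#' coefficient-weighted sum of the supplied inputs; strictly inside (0,1)
#' for finite inputs.  For a multi-class model, one one-vs-rest
#' probability per class is returned.
#'
#' @param model a `fitted_logit`, or any list with elements `intercept`
#'   and named `coefficients` (printed models from [load_printed_model()]
#'   qualify).
#' @param features named numeric vector covering every model input.
#' @return probability (binary) or named probability vector (multi-class).
#' @export
logistic_probability <- function(model, features) {
  eval_one <- function(intercept, coefs) {
    miss <- setdiff(names(coefs), names(features))
    if (length(miss))
      stop("missing feature value(s): ", paste(miss, collapse = ", "))
    stats::plogis(intercept + sum(coefs * features[names(coefs)]))
  }
  if (!is.null(model$per_class)) {
    vapply(model$classes, function(cl) {
      co <- model$per_class[[cl]]
      eval_one(unname(co["(Intercept)"]),
               co[setdiff(names(co), "(Intercept)")])
    }, numeric(1))
  } else {
    eval_one(model$intercept, model$coefficients)
  }
}

# probabilities for every row of a feature table
.predict_prob <- function(model, table) {
  X <- .design_matrix(table, model$features, model$covariates)
  if (!is.null(model$per_class)) {
    sapply(model$classes, function(cl)
      stats::plogis(drop(X %*% model$per_class[[cl]][colnames(X)])))
  } else {
    co <- c("(Intercept)" = model$intercept, model$coefficients)
    stats::plogis(drop(X %*% co[colnames(X)]))
  }
}

#' Predicted class labels for a feature table
#'
#' Binary models classify at probability 0.5 with the tie (exactly 0.5)
#' going to the negative class; multi-class models take the class with the
#' highest one-vs-rest probability (first-listed class on exact ties).
#'
#' @param object a `fitted_logit`; @param table a [feature_table()].
#' @param ... unused.
#' @export
predict.fitted_logit <- function(object, table, ...) {
  pr <- .predict_prob(object, table)
  if (is.matrix(pr)) {
    object$classes[apply(pr, 1L, which.max)]
  } else {
    ifelse(pr > 0.5, object$positive,
           setdiff(object$classes, object$positive)[1L])
  }
}

#' Confusion-matrix evaluation on held-out subjects
#'
#' Asserts that the evaluation rows are disjoint from the training rows
#' (by subject id), classifies at the 0.5 threshold, and reports the
#' confusion counts with the derived metrics: accuracy (fraction
#' correct), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' PPV TP/(TP+FP), NPV TN/(TN+FN).  Multi-class models get per-class
#' one-vs-rest counts plus overall accuracy.
#'
#' @param model a `fitted_logit`.
#' @param table held-out [feature_table()].
#' @param allow_overlap set TRUE only for resubstitution (training-set)
#'   accuracy, where the leakage check must be bypassed deliberately.
#' @return an object of class `evaluation_report`.
#' @export
evaluate <- function(model, table, allow_overlap = FALSE) {
  overlap <- intersect(model$train_ids, table$meta$subject_id)
  if (length(overlap) && !allow_overlap)
    stop("train/test leakage: ", length(overlap),
         " subject id(s) appear in both (first: ", overlap[1L], ")")
  truth <- as.character(table$meta[[model$outcome]])
  pred <- predict(model, table)
  n <- length(truth)
  if (length(model$classes) == 2L) {
    pos <- model$positive
    tp <- sum(pred == pos & truth == pos)
    fp <- sum(pred == pos & truth != pos)
    tn <- sum(pred != pos & truth != pos)
    fn <- sum(pred != pos & truth == pos)
    counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
    metrics <- c(accuracy = (tp + tn) / n,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
    per_class <- NULL
  } else {
    per_class <- t(vapply(model$classes, function(cl) {
      c(TP = sum(pred == cl & truth == cl),
        FP = sum(pred == cl & truth != cl),
        TN = sum(pred != cl & truth != cl),
        FN = sum(pred != cl & truth == cl))
    }, numeric(4)))
    counts <- colSums(per_class)
    metrics <- c(accuracy = mean(pred == truth))
  }
  structure(list(counts = counts, per_class = per_class,
                 metrics = metrics, n = n, classes = model$classes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n =", x$n, "\n ",
      paste(names(x$counts), x$counts, collapse = "  "), "\n ",
      paste(names(x$metrics), round(x$metrics, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusts each p-value for `m` comparisons as
#' \eqn{p_{adj} = 1 - (1 - p)^m}, clipped to [0, 1].  Always at least the
#' raw p and never above the Bonferroni bound `m * p`.
#'
#' @param p_values numeric vector in [0, 1] (NAs pass through).
#' @param m number of comparisons (>= 1).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("m must be a count >= 1")
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok))
    stop("p-values must lie in [0, 1]")
  pmin(pmax(1 - (1 - p_values)^m, 0), 1)
}

#' Serialize a fitted model as JSON
#' @param model a `fitted_logit`; @param path output path.
#' @export
write_model_json <- function(model, path) {
  x <- model[c("intercept", "coefficients", "per_class", "classes",
               "outcome", "positive", "features", "covariates",
               "p_values", "p_sidak", "m_regions", "stabilized", "method")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
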