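test_that("logistic_probability evaluates the logit equation", {
  m <- list(intercept = 0, coefficients = c(r1 = 0, r2 = 0))
  expect_equal(logistic_probability(m, c(r1 = 5, r2 = -3)), 0.5)

  day1 <- load_printed_model("Day1")
  zeros <- setNames(rep(0, length(day1$coefficients)),
                    names(day1$coefficients))
  expect_equal(logistic_probability(day1, zeros), 1 / (1 + exp(-0.36)))

  big <- list(intercept = 500, coefficients = c(r1 = 0))
  expect_equal(logistic_probability(big, c(r1 = 0)), 1)

  expect_error(logistic_probability(day1, zeros[-1]), "Calcarine_R|missing")
  # monotone link: raising a positive-coefficient input raises p
  m2 <- list(intercept = -1, coefficients = c(r1 = 0.4, r2 = -0.2))
  p <- sapply(0:5, function(v)
    logistic_probability(m2, c(r1 = v, r2 = 2)))
  expect_true(all(diff(p) > 0))
})

test_that("fit_logistic maximizes the likelihood (oracle + gradient)", {
  compared <- 0L
  for (seed in 1:8) {
    set.seed(seed)
    n <- 30
    p <- 1L + seed %% 3             # 1..3 region features
    counts <- matrix(rpois(n * p, 10), n, p,
                     dimnames = list(NULL, sprintf("region_%03d", 1:p)))
    eta <- scale(counts[, 1]) * 1.2 - 0.3
    tab <- toy_table(counts,
                     group = ifelse(runif(n) < plogis(eta), "case",
                                    "control"))
    if (length(unique(tab$meta$group)) < 2) next
    fit <- suppressWarnings(fit_logistic(tab, features = colnames(counts)))
    expect_lt(max(abs(fit$score)), 1e-6)           # score at the optimum
    if (fit$stabilized) next      # separated: no finite ML optimum exists
    X <- cbind(1, counts, age = tab$meta$age,
               sex = as.numeric(tab$meta$sex == "M"), bmi = tab$meta$bmi)
    y <- as.numeric(tab$meta$group == "case")
    oracle <- oracle_logit(X, y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
                 tolerance = 1e-3)
    compared <- compared + 1L
  }
  expect_gte(compared, 3L)
})

test_that("two-point toy problem recovers the closed-form log-odds", {
  # x=0: 9 control + 1 case ; x=1: 9 case + 1 control -> log-odds log(9)
  counts <- matrix(rep(c(0, 1), each = 10), ncol = 1,
                   dimnames = list(NULL, "region_001"))
  grp <- c(rep("control", 9), "case", rep("case", 9), "control")
  tab <- toy_table(counts, group = grp)
  fit <- fit_logistic(tab, features = "region_001", covariates = NULL)
  expect_equal(unname(fit$intercept), log(1 / 9), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["region_001"]), 2 * log(9),
               tolerance = 1e-6)
  expect_equal(logistic_probability(fit, c(region_001 = 1)), 0.9,
               tolerance = 1e-6)
})

test_that("degenerate outcomes error; separation is flagged but finite", {
  tab <- toy_table(matrix(rpois(20, 5), 10, 2), group = rep("case", 10))
  expect_error(fit_logistic(tab, features = "region_001"),
               "degenerate")
  sep <- toy_table(matrix(c(rep(0, 5), rep(50, 5)), ncol = 1,
                          dimnames = list(NULL, "region_001")),
                   group = rep(c("control", "case"), each = 5))
  expect_warning(fit <- fit_logistic(sep, features = "region_001",
                                     covariates = NULL),
                 "separation|non-convergence")
  expect_true(fit$stabilized)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
})

test_that("the SGD mode reaches the same optimum as IRLS", {
  set.seed(8)
  counts <- matrix(rpois(60, 12), 30, 2,
                   dimnames = list(NULL, c("region_001", "region_002")))
  grp <- ifelse(runif(30) < plogis(scale(counts[, 1])), "case", "control")
  tab <- toy_table(counts, group = grp)
  irls <- fit_logistic(tab, features = colnames(counts))
  sgd <- fit_logistic(tab, features = colnames(counts), method = "sgd")
  expect_lt(max(abs(sgd$score)), 1e-6)
  expect_equal(sgd$coefficients, irls$coefficients, tolerance = 1e-5)
})

test_that("three-class fits share support and report per-class sets", {
  set.seed(12)
  tab <- generate_feature_table(cohort_spec(
    n_per_group = c(case = 60, control = 30), n_regions = 6,
    subgroup_effects = list(region_001 = c(START = 25, STOPP = -10,
                                           POTS = 40)),
    seed = 44))
  cases <- subset_feature_table(tab, which(tab$meta$group == "case"))
  fit <- suppressWarnings(fit_logistic(cases, outcome = "subgroup",
                                       features = c("region_001",
                                                    "region_002")))
  expect_equal(fit$classes, c("POTS", "START", "STOPP"))
  expect_length(fit$per_class, 3)
  for (cl in fit$classes)
    expect_setequal(names(fit$per_class[[cl]]),
                    c("(Intercept)", "region_001", "region_002",
                      "age", "sex", "bmi"))
  pr <- logistic_probability(fit, c(region_001 = 30, region_002 = 20,
                                    age = 45, sex = 1, bmi = 29))
  expect_length(pr, 3)
  expect_true(all(pr > 0 & pr < 1))
  pred <- predict(fit, cases)
  expect_true(all(pred %in% fit$classes))
})

test_that("evaluate computes defining ratios and guards leakage", {
  # hand-built predictions: TP=5 FN=5 TN=9 FP=1
  counts <- matrix(c(rep(10, 5), rep(0, 5), rep(0, 9), 10), ncol = 1,
                   dimnames = list(NULL, "region_001"))
  truth <- c(rep("case", 10), rep("control", 10))
  tab <- toy_table(counts, group = truth)
  model <- structure(list(intercept = -5, coefficients = c(region_001 = 1),
                          classes = c("control", "case"),
                          positive = "case", outcome = "group",
                          features = "region_001", covariates = NULL,
                          per_class = NULL, train_ids = "ghost"),
                     class = "fitted_logit")
  rep1 <- evaluate(model, tab)
  expect_equal(rep1$counts, c(TP = 5, FP = 1, TN = 9, FN = 5))
  expect_equal(unname(rep1$metrics["sensitivity"]), 0.5)
  expect_equal(unname(rep1$metrics["specificity"]), 0.9)
  expect_equal(unname(rep1$metrics["accuracy"]), 0.7)
  expect_equal(unname(rep1$metrics["ppv"]), 5 / 6)
  expect_equal(unname(rep1$metrics["npv"]), 9 / 14)

  leaky <- model; leaky$train_ids <- tab$meta$subject_id[1]
  expect_error(evaluate(leaky, tab), "leakage")
  expect_silent(evaluate(leaky, tab, allow_overlap = TRUE))

  # probability exactly 0.5 goes to the negative class
  tie_model <- model; tie_model$intercept <- 0
  tie_model$coefficients <- c(region_001 = 0)
  expect_true(all(predict(tie_model, tab) == "control"))

  # a cleanly separated table: every prediction correct -> all metrics 1
  clean <- toy_table(matrix(c(rep(10, 8), rep(0, 8)), ncol = 1,
                            dimnames = list(NULL, "region_001")),
                     group = rep(c("case", "control"), each = 8))
  rep2 <- evaluate(model, clean)
  expect_equal(unname(rep2$metrics[c("accuracy", "sensitivity",
                                     "specificity", "ppv", "npv")]),
               rep(1, 5))
})

test_that("random predictions sit near chance at large n", {
  set.seed(77)
  n <- 1000
  counts <- matrix(rbinom(n, 1, 0.5) * 100, ncol = 1,
                   dimnames = list(NULL, "region_001"))
  truth <- sample(c("case", "control"), n, TRUE)
  tab <- toy_table(counts, group = truth)
  model <- structure(list(intercept = -50,
                          coefficients = c(region_001 = 1),
                          classes = c("control", "case"),
                          positive = "case", outcome = "group",
                          features = "region_001", covariates = NULL,
                          per_class = NULL, train_ids = "none"),
                     class = "fitted_logit")
  acc <- evaluate(model, tab)$metrics["accuracy"]
  expect_lt(abs(acc - 0.5), 4 * sqrt(0.25 / n))
})

test_that("Sidak adjustment: closed form, bounds, validation", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(0.01, 29), 1 - 0.99^29)
  expect_equal(sidak_adjust(0.01, 29), 0.2528, tolerance = 1e-3)
  set.seed(4)
  p <- runif(50)
  for (m in c(1, 5, 29, 117)) {
    adj <- sidak_adjust(p, m)
    expect_true(all(adj >= p))               # never below raw
    expect_true(all(adj <= pmin(1, m * p)))  # Bonferroni dominance
  }
  expect_error(sidak_adjust(1.2, 3), "0, 1")
  expect_error(sidak_adjust(0.5, 0), "m must be")
})

test_that("stratified splits use largest-remainder arithmetic", {
  lab <- rep(c("case", "control"), c(80, 31))
  sp <- stratified_split(lab, 0.7, seed = 1)
  expect_length(sp$train, 78)
  expect_equal(sum(lab[sp$train] == "case"), 56)
  expect_equal(sum(lab[sp$train] == "control"), 22)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(lab))
  # determinism
  expect_identical(sp, stratified_split(lab, 0.7, seed = 1))
  expect_false(identical(sp$train,
                         stratified_split(lab, 0.7, seed = 2)$train))
  expect_error(stratified_split(rep(c("a", "b"), 2), 0.9),
               "infeasible")
})

test_that("split_search scores ratios and skips infeasible ones", {
  tab <- generate_feature_table(cohort_spec(
    n_per_group = c(case = 40, control = 30), n_regions = 5,
    effect_regions = list(region_002 = 30), dispersion = 5, seed = 6))
  res <- split_search(tab, features = region_names(tab), repeats = 4,
                      seed = 2)
  expect_true(res$chosen_ratio %in% seq(0.5, 0.9, 0.1))
  expect_equal(dim(res$accuracies), c(5L, 4L))
  best <- which(res$summary$ratio == res$chosen_ratio)
  expect_equal(max(res$summary$mean_accuracy, na.rm = TRUE),
               res$summary$mean_accuracy[best])

  tiny <- generate_feature_table(cohort_spec(
    n_per_group = c(case = 2, control = 2), n_regions = 3, seed = 1))
  expect_warning(
    res2 <- split_search(tiny, features = region_names(tiny),
                         ratios = c(0.5, 0.9), repeats = 2, seed = 3),
    "infeasible")
  expect_true(is.na(res2$summary$mean_accuracy[2]))
})

test_that("planted effects beat the null by a clear CV margin", {
  # published cohort sizes; standardized region effect >= 1
  feats <- c("region_010", "region_050", "region_090")
  gaps <- vapply(1:25, function(s) {
    eff <- generate_feature_table(cohort_spec(
      effect_regions = list(region_010 = 25, region_050 = -20,
                            region_090 = 18),
      dispersion = 4, seed = 5000 + s))
    nul <- generate_feature_table(cohort_spec(dispersion = 4,
                                              seed = 6000 + s))
    kfold_cv(eff, features = feats, k = 10, seed = s)$mean_accuracy -
      suppressWarnings(kfold_cv(nul, features = feats, k = 10,
                                seed = s)$mean_accuracy)
  }, numeric(1))
  expect_gte(median(gaps), 0.15)

  # effect monotonicity: larger planted shifts never reduce the median
  # (paired seeds across shift levels)
  med_acc <- vapply(c(0, 12, 25), function(shift) {
    acc <- vapply(1:25, function(s) {
      tab <- generate_feature_table(cohort_spec(
        n_per_group = c(case = 60, control = 60), n_regions = 10,
        effect_regions = list(region_003 = shift),
        dispersion = 4, seed = 7000 + s))
      suppressWarnings(kfold_cv(tab, features = "region_003", k = 10,
                                seed = s)$mean_accuracy)
    }, numeric(1))
    median(acc)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= 0))
})

test_that("k-fold CV: separable data, determinism, LOO oracle", {
  counts <- matrix(c(rep(0, 10), rep(60, 10)), ncol = 1,
                   dimnames = list(NULL, "region_001"))
  tab <- toy_table(counts, group = rep(c("control", "case"), each = 10))
  cv <- kfold_cv(tab, features = "region_001", k = 5, seed = 1,
                 covariates = NULL)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_identical(cv, kfold_cv(tab, features = "region_001", k = 5,
                                seed = 1, covariates = NULL))
  expect_error(kfold_cv(tab, features = "region_001", k = 21), "folds")

  # k = n equals an explicit leave-one-out loop
  set.seed(9)
  counts <- matrix(rpois(18 * 2, 10), 18, 2,
                   dimnames = list(NULL, c("region_001", "region_002")))
  grp <- ifelse(runif(18) < plogis(scale(counts[, 1]) * 2), "case",
                "control")
  tab2 <- toy_table(counts, group = grp)
  cv_loo <- kfold_cv(tab2, features = colnames(counts), k = 18, seed = 4,
                     covariates = NULL)
  loo <- vapply(seq_len(18), function(i) {
    fit <- suppressWarnings(fit_logistic(
      subset_feature_table(tab2, setdiff(1:18, i)),
      features = colnames(counts), covariates = NULL))
    predict(fit, subset_feature_table(tab2, i)) == tab2$meta$group[i]
  }, logical(1))
  expect_equal(cv_loo$mean_accuracy, mean(loo))
})
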