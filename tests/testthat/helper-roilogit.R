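# fixtures built in code, shared across test files

# a small feature table with hand-chosen counts and metadata
toy_table <- function(counts, group = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("region_%03d", seq_len(ncol(counts)))
  n <- nrow(counts)
  if (is.null(group)) group <- rep(c("case", "control"), length.out = n)
  meta <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     group = group, subgroup = "none",
                     age = 30 + ((seq_len(n) * 7) %% 23),
                     sex = rep(c("M", "F"), length.out = n),
                     bmi = 22 + ((seq_len(n) * 5) %% 11) / 2,
                     stringsAsFactors = FALSE)
  feature_table(counts, meta)
}

# independent oracle: count suprathreshold voxels by an explicit
# triple loop over the voxel grid
brute_force_counts <- function(map, atlas, t_threshold) {
  d <- dim(map$values)
  out <- stats::setNames(rep(0L, nrow(atlas$regions)), atlas$regions$name)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- map$values[i, j, k]
    lab <- atlas$labels[i, j, k]
    if (lab > 0L && is.finite(v) && v > t_threshold) {
      nm <- atlas$regions$name[match(lab, atlas$regions$id)]
      out[nm] <- out[nm] + 1L
    }
  }
  out
}

# independent oracle: maximum-likelihood logit by coarse random
# multi-start + general-purpose optimizer polish (no IRLS involved)
oracle_logit <- function(X, y, n_starts = 5) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta)))
  }
  gr <- function(b) -drop(crossprod(X, y - stats::plogis(drop(X %*% b))))
  best <- NULL
  set.seed(42)
  starts <- c(list(rep(0, ncol(X))),
              replicate(n_starts, stats::rnorm(ncol(X), 0, 0.5),
                        simplify = FALSE))
  for (s in starts) {
    fit <- stats::optim(s, nll, gr, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# build a deterministic random stat map over a toy atlas
random_map_instance <- function(seed, max_dim = 16) {
  set.seed(seed)
  d <- sample(3:max_dim, 3, replace = TRUE)
  n_regions <- sample(2:6, 1)
  atlas <- generate_toy_atlas(toy_atlas_spec(d, n_regions, 1))
  vals <- array(stats::rnorm(prod(d), mean = 2, sd = 2), d)
  vals[sample(length(vals), ceiling(length(vals) / 50))] <- NA  # missing
  list(map = stat_map(vals, subject_id = paste0("I", seed)), atlas = atlas)
}
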