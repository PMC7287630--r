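#' Pearson correlation matrix over region features
#'
#' Product-moment correlations between region count columns across
#' subjects.  Columns with zero variance cannot carry a correlation; they
#' are flagged in `zero_variance` and their rows/columns set to `NA`
#' rather than left as silent `NaN`s, and they are excluded from
#' screening decisions.
#'
#' @param table a [feature_table()] (or plain numeric matrix with column
#'   names) with at least 3 subjects.
#' @return an object of class `correlation_matrix`: list with `values`
#'   (symmetric matrix, unit diagonal on non-degenerate columns),
#'   `n_subjects`, `region_names`, `zero_variance` (logical vector).
#' @export
correlation_matrix <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  if (nrow(m) < 3L)
    stop("need at least 3 subjects to estimate correlations, got ", nrow(m))
  zv <- apply(m, 2L, stats::sd) == 0
  vals <- suppressWarnings(stats::cor(m))
  vals[zv, ] <- NA_real_
  vals[, zv] <- NA_real_
  diag(vals)[!zv] <- 1
  structure(list(values = vals, n_subjects = nrow(m),
                 region_names = colnames(m), zero_variance = zv),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", length(x$region_names), "regions, n =",
      x$n_subjects, "subjects,", sum(x$zero_variance),
      "zero-variance column(s)\n")
  invisible(x)
}

#' Multicollinearity screen at |R| < r_max
#'
#' Greedy deterministic elimination: regions are visited in table order and
#' a region is dropped when its absolute correlation with any
#' earlier-retained region reaches `r_max`, so of a violating pair the
#' later-ordered member is removed.  After screening no retained pair has
#' |R| >= r_max.  Zero-variance columns are exempt (they carry no
#' correlation).  The absolute value is used even though only positive
#' near-collinearity was observed in the data this gate was designed for:
#' strong negative correlation is equally collinear.
#'
#' @param cm a [correlation_matrix()].
#' @param r_max gate in (0, 1]; default 0.9.
#' @return list with `retained` (region names), `dropped` (data.frame:
#'   region, because_of, r) and `r_max`.
#' @export
multicollinearity_screen <- function(cm, r_max = 0.9) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!is.numeric(r_max) || r_max <= 0 || r_max > 1)
    stop("r_max must be in (0, 1]")
  rn <- cm$region_names
  keep <- rep(TRUE, length(rn))
  dropped <- list()
  for (j in seq_along(rn)) {
    if (cm$zero_variance[j]) next
    earlier <- which(keep[seq_len(j - 1L)] &
                       !cm$zero_variance[seq_len(j - 1L)])
    if (!length(earlier)) next
    r <- cm$values[j, earlier]
    bad <- which(abs(r) >= r_max)
    if (length(bad)) {
      keep[j] <- FALSE
      dropped[[length(dropped) + 1L]] <-
        data.frame(region = rn[j], because_of = rn[earlier[bad[1L]]],
                   r = unname(r[bad[1L]]), stringsAsFactors = FALSE)
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(region = character(0), because_of = character(0),
               r = numeric(0))
  list(retained = rn[keep], dropped = dropped, r_max = r_max)
}

#' Screen across training, test and full data
#'
#' The gate is applied three times -- on the training split, the test
#' split, and the combined table -- and a region is dropped globally if it
#' fails in any of the three.
#'
#' @param table a [feature_table()].
#' @param train_idx integer row indices of the training split.
#' @param r_max gate (default 0.9).
#' @return list with `retained`, per-split screen results, and `r_max`.
#' @export
screen_three_way <- function(table, train_idx, r_max = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$counts)
  test_idx <- setdiff(seq_len(n), train_idx)
  screens <- list(
    train = multicollinearity_screen(
      correlation_matrix(table$counts[train_idx, , drop = FALSE]), r_max),
    test = multicollinearity_screen(
      correlation_matrix(table$counts[test_idx, , drop = FALSE]), r_max),
    full = multicollinearity_screen(correlation_matrix(table), r_max))
  dropped <- unique(unlist(lapply(screens, function(s) s$dropped$region)))
  list(retained = setdiff(region_names(table), dropped),
       screens = screens, r_max = r_max)
}

#' Census of strong correlations
#'
#' Counts unordered off-diagonal pairs with R strictly above each cutoff
#' (signed, matching the "R > 0.7 / 0.8 / 0.9" convention of heatmap
#' summaries), plus the number of pairs with R strictly below
#' `negative_cutoff`.
#'
#' @param cm a [correlation_matrix()].
#' @param cutoffs increasing positive cutoffs (default 0.7, 0.8, 0.9).
#' @param negative_cutoff default -0.5.
#' @return list with `above` (named count per cutoff), `below_negative`,
#'   `n_pairs`.
#' @export
strong_correlation_census <- function(cm, cutoffs = c(0.7, 0.8, 0.9),
                                      negative_cutoff = -0.5) {
  stopifnot(inherits(cm, "correlation_matrix"))
  v <- cm$values[upper.tri(cm$values)]
  v <- v[!is.na(v)]
  above <- vapply(cutoffs, function(ct) sum(v > ct), numeric(1))
  names(above) <- paste0("R>", format(cutoffs))
  list(above = above, below_negative = sum(v < negative_cutoff),
       n_pairs = length(v))
}

#' Write a correlation matrix as CSV with a region-name header
#' @param cm a [correlation_matrix()]; @param path file path.
#' @export
write_correlation_matrix <- function(cm, path) {
  df <- as.data.frame(cm$values)
  names(df) <- cm$region_names
  utils::write.csv(cbind(region = cm$region_names, df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
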