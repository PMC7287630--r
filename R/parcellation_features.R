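#' Count suprathreshold voxels per atlas region
#'
#' For each region in the parcellation, counts the voxels whose t-statistic
#' is strictly greater than `t_threshold` ("exceeding" the cut, so a voxel
#' exactly at the threshold is not counted).  Background (label 0) and
#' non-finite voxels are never counted.  The default threshold 3.17
#' corresponds to an uncorrected upper tail probability below 1e-3 under a
#' normal reference (see [suggest_t_threshold()]).
#'
#' @param map a [stat_map()].
#' @param atlas an [atlas_parcellation()] on the identical voxel grid.
#' @param t_threshold finite scalar threshold (default 3.17).
#' @return named integer vector of counts, one per atlas region, in the
#'   atlas region-table order.
#' @export
count_suprathreshold <- function(map, atlas, t_threshold = 3.17) {
  stopifnot(inherits(map, "stat_map"), inherits(atlas, "atlas_parcellation"))
  if (!is.numeric(t_threshold) || length(t_threshold) != 1L ||
      !is.finite(t_threshold))
    stop("t_threshold must be a finite scalar")
  if (!identical(dim(map$values), dim(atlas$labels)))
    stop("grid mismatch: map is ", paste(dim(map$values), collapse = "x"),
         ", atlas is ", paste(dim(atlas$labels), collapse = "x"))
  v <- as.vector(map$values)
  lab <- as.vector(atlas$labels)
  hit <- is.finite(v) & v > t_threshold & lab > 0L
  tab <- tabulate(lab[hit], nbins = max(atlas$regions$id))
  stats::setNames(tab[atlas$regions$id], atlas$regions$name)
}

#' Total suprathreshold voxels as a function of threshold
#'
#' The diagnostic curve used to pick the activation threshold: the total
#' number of voxels (summed over all maps, all regions including
#' background) strictly exceeding each candidate t.  Totals are
#' non-increasing in t by construction.
#'
#' @param maps non-empty list of [stat_map()] objects.
#' @param t_grid strictly increasing numeric vector of candidate cuts.
#' @return data.frame with columns `t` and `total_voxels`.
#' @export
threshold_curve <- function(maps, t_grid) {
  if (!length(maps)) stop("maps must be a non-empty list")
  if (!length(t_grid)) stop("t_grid must be non-empty")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  vals <- unlist(lapply(maps, function(m) {
    stopifnot(inherits(m, "stat_map"))
    v <- as.vector(m$values)
    v[is.finite(v)]
  }))
  totals <- vapply(t_grid, function(t) sum(vals > t), numeric(1))
  data.frame(t = t_grid, total_voxels = totals)
}

#' Smallest grid threshold with normal-reference tail probability <= alpha
#'
#' The published pipeline chose t = 3.17 from the threshold curve, labelled
#' "p < 0.001 uncorrected"; the degrees of freedom behind that equivalence
#' are not part of this package's contract, so the helper documents the
#' normal-reference check only: the upper tail beyond 3.17 is about
#' 7.6e-4.  Given a grid it returns the smallest t whose normal upper-tail
#' probability is at most `alpha`; with no grid it returns the fixed
#' default 3.17.
#'
#' @param t_grid optional increasing candidate thresholds.
#' @param alpha nominal uncorrected tail probability (default 1e-3).
#' @return a scalar threshold.
#' @export
suggest_t_threshold <- function(t_grid = NULL, alpha = 1e-3) {
  if (is.null(t_grid)) return(3.17)
  ok <- stats::pnorm(t_grid, lower.tail = FALSE) <= alpha
  if (!any(ok)) stop("no grid threshold reaches tail probability <= ", alpha)
  t_grid[which(ok)[1L]]
}

#' Assemble the subjects-by-regions feature table from maps
#'
#' Stacks [count_suprathreshold()] over subjects, joining on subject id.
#' Row order follows the metadata; column order follows the atlas region
#' table.
#'
#' @param maps list of [stat_map()] objects.
#' @param atlas an [atlas_parcellation()].
#' @param meta data.frame of subject metadata (columns as in
#'   [feature_table()]); exactly one row per map, matched by `subject_id`.
#' @param t_threshold scalar threshold (default 3.17).
#' @return a [feature_table()].
#' @export
build_feature_table <- function(maps, atlas, meta, t_threshold = 3.17) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject id in metadata: ",
         meta$subject_id[duplicated(meta$subject_id)][1L])
  map_ids <- vapply(maps, function(m) m$subject_id, character(1))
  if (anyDuplicated(map_ids))
    stop("duplicate subject id among maps: ",
         map_ids[duplicated(map_ids)][1L])
  missing_meta <- setdiff(map_ids, meta$subject_id)
  if (length(missing_meta))
    stop("no metadata for subject(s): ", paste(missing_meta, collapse = ", "))
  missing_map <- setdiff(meta$subject_id, map_ids)
  if (length(missing_map))
    stop("no map for subject(s): ", paste(missing_map, collapse = ", "))
  maps <- maps[match(meta$subject_id, map_ids)]
  counts <- t(vapply(maps, count_suprathreshold, atlas = atlas,
                     t_threshold = t_threshold,
                     FUN.VALUE = numeric(nrow(atlas$regions))))
  colnames(counts) <- atlas$regions$name
  feature_table(counts, meta)
}

#' Write a threshold curve as two-column TSV
#' @param curve output of [threshold_curve()]; @param path file path.
#' @export
write_threshold_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
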