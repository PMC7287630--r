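#' Per-subject statistical map
#'
#' A 3D grid of voxelwise t-statistics with a voxel-to-world affine, the
#' subject-level output of a first-level task contrast (here, the
#' high-minus-low working-memory load contrast).  Non-finite voxels are
#' treated as missing and never counted by downstream feature extraction.
#'
#' @param values 3D numeric array of t-statistics; `NA`/non-finite allowed.
#' @param affine 4x4 invertible voxel-to-world matrix.
#' @param subject_id scalar identifier.
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(values, affine = diag(c(2, 2, 2, 1)), subject_id = "s1") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(values = values, affine = affine,
                 subject_id = as.character(subject_id)[1L]),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> subject", x$subject_id, ":",
      paste(dim(x$values), collapse = "x"), "voxels,",
      sum(!is.finite(x$values)), "missing\n")
  invisible(x)
}

#' Atlas parcellation
#'
#' An integer label volume on the same voxel grid as the statistical maps,
#' with a region lookup table.  Label 0 is background and is never counted.
#'
#' @param labels 3D array of non-negative integers.
#' @param regions data.frame with columns `id` (positive integer, unique)
#'   and `name` (unique character). Every non-zero label in `labels` must
#'   appear in `regions$id`.
#' @param affine 4x4 voxel-to-world matrix.
#' @return an object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(labels, regions,
                               affine = diag(c(2, 2, 2, 1))) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  regions <- as.data.frame(regions)
  if (!all(c("id", "name") %in% names(regions)))
    stop("regions must have columns 'id' and 'name'")
  regions$id <- as.integer(regions$id)
  if (anyDuplicated(regions$id)) stop("duplicate region ids")
  if (anyDuplicated(regions$name)) stop("duplicate region names")
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, regions$id)
  if (length(unknown))
    stop("labels not in region table: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, regions = regions,
                 affine = as.matrix(affine)),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat("<atlas_parcellation>", nrow(x$regions), "regions on a",
      paste(dim(x$labels), collapse = "x"), "grid\n")
  invisible(x)
}

#' Region voxel counts per label, by exhaustive tabulation
#' @noRd
.label_voxel_counts <- function(atlas) {
  tab <- tabulate(as.vector(atlas$labels), nbins = max(atlas$regions$id))
  stats::setNames(tab[atlas$regions$id], atlas$regions$name)
}

.ft_meta_cols <- c("subject_id", "group", "subgroup", "age", "sex", "bmi")

#' Subjects-by-regions feature table
#'
#' The central data container: a matrix of suprathreshold voxel counts (one
#' row per subject, one column per atlas region) joined to subject metadata
#' (case/control group, phenotype subgroup, age, sex, BMI).
#'
#' @param counts integer matrix, subjects x regions, non-negative; column
#'   names are the region names.
#' @param meta data.frame with one row per count row and columns
#'   `subject_id`, `group` ("case"/"control"), `subgroup`
#'   ("START"/"STOPP"/"POTS"/"none"), `age` (years), `sex` ("M"/"F"),
#'   `bmi` (kg/m2).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have region column names")
  if (anyDuplicated(colnames(counts))) stop("duplicate region names")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ft_meta_cols, names(meta))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(meta) != nrow(counts))
    stop("metadata rows (", nrow(meta), ") != count rows (", nrow(counts), ")")
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject_id in metadata: ",
         meta$subject_id[duplicated(meta$subject_id)][1L])
  bad_group <- setdiff(unique(meta$group), c("case", "control"))
  if (length(bad_group))
    stop("group must be 'case' or 'control', got: ",
         paste(bad_group, collapse = ", "))
  rownames(counts) <- meta$subject_id
  structure(list(counts = counts, meta = meta[.ft_meta_cols]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$counts), "subjects x", ncol(x$counts),
      "regions (", sum(x$meta$group == "case"), "case /",
      sum(x$meta$group == "control"), "control )\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
region_names <- function(x) colnames(x$counts)

#' Subset a feature table by subjects and/or regions
#' @param x a `feature_table`.
#' @param i subject (row) index; @param j region (column) index.
#' @export
subset_feature_table <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$counts))
  if (is.null(j)) j <- seq_len(ncol(x$counts))
  if (anyDuplicated(i)) stop("duplicate subject selection")
  # invariants survive subsetting; skip the full constructor re-check
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 meta = x$meta[i, , drop = FALSE]),
            class = "feature_table")
}

#' Read and write the feature-table CSV dialect
#'
#' Header is `subject_id,group,subgroup,age,sex,bmi,<region names...>`.
#'
#' @param x a `feature_table`; @param path CSV file path.
#' @export
write_feature_table <- function(x, path) {
  df <- cbind(x$meta, as.data.frame(x$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ft_meta_cols, names(df))
  if (length(missing_cols))
    stop("not a feature-table CSV; missing: ",
         paste(missing_cols, collapse = ", "))
  region_cols <- setdiff(names(df), .ft_meta_cols)
  feature_table(as.matrix(df[region_cols]), df[.ft_meta_cols])
}
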