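#' Synthetic parcellated-activation cohorts
#'
#' Generates cohorts with the statistical structure the downstream analysis
#' assumes: per-region suprathreshold voxel counts drawn from a negative
#' binomial with optional planted class effects, demographic covariates
#' matched to published case/control moments, a 3-level phenotype subgroup
#' over cases, and (optionally) full voxel-level t-maps over a toy atlas
#' that reproduce the counts exactly when re-extracted.
#'
#' Defaults mirror the cohort the pipeline was designed around: 80 cases
#' vs. 31 sedentary controls, 117 atlas regions, case subgroups of
#' 23/46/11 (START/STOPP/POTS), case age 46.9 +/- 7.8 vs. control
#' 43.9 +/- 16.3 years, BMI 29.6 +/- 5.6 vs. 28.4 +/- 4.5 kg/m2, and male
#' proportions 0.738 vs. 0.613.
#'
#' @param n_per_group named integer vector of subjects per class; names are
#'   the class labels and the first name is the positive ("case") class.
#' @param n_regions number of atlas regions (default 117).
#' @param effect_regions named list: region name (or index given as a name
#'   like `"7"`) -> mean shift in expected count. A scalar shifts the first
#'   class only; a vector of length `length(n_per_group)` gives one shift
#'   per class in `n_per_group` order.
#' @param baseline_mean expected suprathreshold voxel count in null regions.
#' @param dispersion negative-binomial size parameter (> 0); variance is
#'   `mu + mu^2/dispersion`, so small values mean strong overdispersion.
#' @param covariate_params per-class list of lists with elements
#'   `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`, `prop_male`.
#' @param subgroup_n named integer vector partitioning the first class into
#'   phenotype subgroups (default `c(START = 23, STOPP = 46, POTS = 11)`,
#'   rescaled to the class size if it differs from 80).
#' @param subgroup_effects named list like `effect_regions` but with one
#'   shift per subgroup (vector named by subgroup), applied on top of the
#'   class mean for case subjects.
#' @param correlation_block optional list of `list(i, j, rho)` entries
#'   requesting latent (Gaussian copula) correlation `rho` between regions
#'   `i` and `j` (names or indices).
#' @param seed integer RNG seed stored in the spec; all generation is
#'   reproducible from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(case = 80, control = 31),
                        n_regions = 117,
                        effect_regions = list(),
                        baseline_mean = 30,
                        dispersion = 2,
                        covariate_params = NULL,
                        subgroup_n = NULL,
                        subgroup_effects = list(),
                        correlation_block = NULL,
                        seed = 1L) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("case", "control", "extra")[seq_along(n_per_group)]
  n_per_group <- vapply(n_per_group, as.integer, integer(1))
  if (length(n_per_group) < 2L || any(n_per_group < 1L))
    stop("n_per_group: need >= 2 classes, every class non-empty")
  if (!is.numeric(n_regions) || n_regions < 1L)
    stop("n_regions must be a positive count")
  if (!is.numeric(baseline_mean) || baseline_mean < 0)
    stop("baseline_mean must be >= 0")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("dispersion must be > 0")
  if (is.null(covariate_params)) {
    covariate_params <- list(
      list(age_mean = 46.9, age_sd = 7.8, bmi_mean = 29.6, bmi_sd = 5.6,
           prop_male = 0.738),
      list(age_mean = 43.9, age_sd = 16.3, bmi_mean = 28.4, bmi_sd = 4.5,
           prop_male = 0.613))
    covariate_params <- rep(covariate_params,
                            length.out = length(n_per_group))
  }
  names(covariate_params) <- names(n_per_group)
  for (cls in names(covariate_params)) {
    cp <- covariate_params[[cls]]
    if (cp$prop_male < 0 || cp$prop_male > 1)
      stop("covariate_params$", cls, "$prop_male must be in [0,1]")
    if (cp$age_sd < 0 || cp$bmi_sd < 0)
      stop("covariate_params$", cls, ": SDs must be >= 0")
  }
  if (is.null(subgroup_n)) {
    base <- c(START = 23, STOPP = 46, POTS = 11)
    n1 <- n_per_group[[1L]]
    subgroup_n <- round(base / sum(base) * n1)
    subgroup_n[1L] <- n1 - sum(subgroup_n[-1L])
  }
  if (sum(subgroup_n) != n_per_group[[1L]])
    stop("subgroup_n must sum to the first class size")
  spec <- structure(list(
    n_per_group = n_per_group, n_regions = as.integer(n_regions),
    effect_regions = effect_regions, baseline_mean = baseline_mean,
    dispersion = dispersion, covariate_params = covariate_params,
    subgroup_n = subgroup_n, subgroup_effects = subgroup_effects,
    correlation_block = correlation_block, seed = as.integer(seed)),
    class = "cohort_spec")
  # validate effect maps against the region set now, not at draw time
  .resolve_region_refs(names(spec$effect_regions), spec$n_regions)
  .resolve_region_refs(names(spec$subgroup_effects), spec$n_regions)
  spec
}

.default_region_names <- function(n) sprintf("region_%03d", seq_len(n))

.resolve_region_refs <- function(refs, n_regions,
                                 region_names = .default_region_names(n_regions)) {
  if (is.null(refs) || !length(refs)) return(integer(0))
  idx <- match(refs, region_names)
  numeric_ref <- suppressWarnings(as.integer(refs))
  idx[is.na(idx)] <- numeric_ref[is.na(idx)]
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_regions))
    stop("effect_regions: unknown region reference(s): ",
         paste(refs[is.na(idx) | idx < 1L | idx > n_regions], collapse = ", "))
  idx
}

#' Evaluate code with a locally-set RNG seed, restoring global state
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a subjects-by-regions count table from a cohort specification
#'
#' Counts are negative binomial with mean `baseline_mean` plus any planted
#' class/subgroup shift (clamped at zero) and size `dispersion`; requested
#' correlation blocks are induced through a Gaussian copula so marginals
#' are preserved.  Age and BMI are truncated normal (ages 18-90 years, BMI
#' 15-60 kg/m2), sex is Bernoulli male.  Identical spec and seed give an
#' identical table.
#'
#' @param spec a [cohort_spec()].
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    classes <- names(spec$n_per_group)
    n <- sum(spec$n_per_group)
    group_vec <- rep(classes, spec$n_per_group)
    rn <- .default_region_names(spec$n_regions)

    subgroup <- rep("none", n)
    sg_labels <- rep(names(spec$subgroup_n), spec$subgroup_n)
    subgroup[group_vec == classes[1L]] <- sample(sg_labels)

    mu <- matrix(spec$baseline_mean, n, spec$n_regions)
    if (length(spec$effect_regions)) {
      idx <- .resolve_region_refs(names(spec$effect_regions), spec$n_regions)
      for (k in seq_along(idx)) {
        shift <- spec$effect_regions[[k]]
        if (length(shift) == 1L)
          shift <- c(shift, rep(0, length(classes) - 1L))
        mu[, idx[k]] <- mu[, idx[k]] + shift[match(group_vec, classes)]
      }
    }
    if (length(spec$subgroup_effects)) {
      idx <- .resolve_region_refs(names(spec$subgroup_effects),
                                  spec$n_regions)
      for (k in seq_along(idx)) {
        shift <- spec$subgroup_effects[[k]]
        hit <- subgroup %in% names(shift)
        mu[hit, idx[k]] <- mu[hit, idx[k]] + shift[subgroup[hit]]
      }
    }
    mu[mu < 0] <- 0

    # latent Gaussian field -> copula transform keeps the NB marginal
    z <- matrix(stats::rnorm(n * spec$n_regions), n, spec$n_regions)
    for (blk in spec$correlation_block) {
      i <- .resolve_region_refs(as.character(blk[[1L]]), spec$n_regions)
      j <- .resolve_region_refs(as.character(blk[[2L]]), spec$n_regions)
      rho <- blk[[3L]]
      if (abs(rho) > 1) stop("correlation_block rho must be in [-1,1]")
      z[, j] <- rho * z[, i] + sqrt(1 - rho^2) * z[, j]
    }
    counts <- matrix(stats::qnbinom(stats::pnorm(z), size = spec$dispersion,
                                    mu = mu),
                     n, spec$n_regions, dimnames = list(NULL, rn))
    counts[mu == 0] <- 0L

    cp <- spec$covariate_params[group_vec]
    age <- round(mapply(function(p) .rtruncnorm(1, p$age_mean, p$age_sd,
                                                18, 90), cp), 1)
    bmi <- round(mapply(function(p) .rtruncnorm(1, p$bmi_mean, p$bmi_sd,
                                                15, 60), cp), 1)
    sex <- ifelse(stats::runif(n) <
                    vapply(cp, `[[`, numeric(1), "prop_male"), "M", "F")
    grp <- ifelse(group_vec == classes[1L], "case", "control")
    meta <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       group = grp, subgroup = subgroup, age = age,
                       sex = sex, bmi = bmi, stringsAsFactors = FALSE)
    feature_table(counts, meta)
  })
}

#' Toy atlas specification and deterministic construction
#'
#' Tiles a 3D grid into `n_regions` contiguous blocks of near-equal size
#' (column-major order), a stand-in for a real anatomical parcellation so
#' the extraction stage can be tested without external atlas files.
#'
#' @param grid_shape integer vector of 3 voxel dimensions.
#' @param n_regions number of regions to tile.
#' @param voxels_per_region minimum voxels each region must receive.
#' @return `toy_atlas_spec()` returns a spec object; `generate_toy_atlas()`
#'   an [atlas_parcellation()].
#' @export
toy_atlas_spec <- function(grid_shape = c(10, 10, 10), n_regions = 8,
                           voxels_per_region = 10) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (n_regions < 1L || voxels_per_region < 1L)
    stop("n_regions and voxels_per_region must be positive")
  if (prod(grid_shape) < n_regions * voxels_per_region)
    stop("grid too small: ", prod(grid_shape), " voxels < ",
         n_regions, " regions x ", voxels_per_region, " voxels each")
  structure(list(grid_shape = grid_shape, n_regions = as.integer(n_regions),
                 voxels_per_region = as.integer(voxels_per_region)),
            class = "toy_atlas_spec")
}

#' @rdname toy_atlas_spec
#' @param spec a `toy_atlas_spec`.
#' @export
generate_toy_atlas <- function(spec) {
  stopifnot(inherits(spec, "toy_atlas_spec"))
  nvox <- prod(spec$grid_shape)
  # near-equal contiguous runs; every region gets >= voxels_per_region
  sizes <- rep(nvox %/% spec$n_regions, spec$n_regions)
  extra <- nvox %% spec$n_regions
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- array(rep(seq_len(spec$n_regions), sizes),
                  dim = spec$grid_shape)
  regions <- data.frame(id = seq_len(spec$n_regions),
                        name = .default_region_names(spec$n_regions),
                        stringsAsFactors = FALSE)
  atlas_parcellation(labels, regions)
}

#' Generate statistical maps jointly with their count table
#'
#' Per subject, background voxels are drawn from a standard normal
#' truncated at `t_threshold` and, for each region, exactly the tabled
#' number of voxels receive values from the normal tail above
#' `t_threshold`, so re-extracting counts from the maps reproduces the
#' returned table cell-for-cell.  Counts are clamped at each region's
#' voxel capacity (relevant only for tiny toy atlases).
#'
#' @param spec a [cohort_spec()]; its `n_regions` must not exceed the
#'   atlas region count.
#' @param atlas an [atlas_parcellation()].
#' @param t_threshold finite suprathreshold cut (default 3.17).
#' @return list with `maps` (list of [stat_map()]), `table` (the
#'   [feature_table()] the maps encode) and `t_threshold`.
#' @export
generate_statmaps <- function(spec, atlas, t_threshold = 3.17) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(atlas, "atlas_parcellation"))
  if (!is.numeric(t_threshold) || !is.finite(t_threshold))
    stop("t_threshold must be finite")
  if (spec$n_regions > nrow(atlas$regions))
    stop("atlas has ", nrow(atlas$regions), " regions but cohort needs ",
         spec$n_regions)
  tab <- generate_feature_table(spec)
  # align table region names to the atlas's first n_regions names
  atlas_names <- atlas$regions$name[seq_len(spec$n_regions)]
  colnames(tab$counts) <- atlas_names
  capacity <- .label_voxel_counts(atlas)[atlas_names]
  over <- sweep(tab$counts, 2L, capacity, `>`)
  if (any(over)) {
    tab$counts[over] <- matrix(capacity, nrow(tab$counts),
                               length(capacity), byrow = TRUE)[over]
    warning("counts clamped to region voxel capacity in ",
            sum(over), " cell(s)")
  }
  tab <- feature_table(tab$counts, tab$meta)

  vox_by_region <- split(seq_along(atlas$labels), as.vector(atlas$labels))
  vox_by_region <- vox_by_region[as.character(atlas$regions$id)]
  names(vox_by_region) <- atlas$regions$name
  p_bg <- stats::pnorm(t_threshold)

  maps <- .with_seed(spec$seed + 1L, lapply(seq_len(nrow(tab$counts)),
    function(s) {
      vals <- stats::qnorm(stats::runif(length(atlas$labels), 0, p_bg))
      for (r in atlas_names) {
        k <- tab$counts[s, r]
        if (k > 0L) {
          hit <- sample(vox_by_region[[r]], k)
          vals[hit] <- stats::qnorm(stats::runif(k, p_bg, 1))
        }
      }
      dim(vals) <- dim(atlas$labels)
      stat_map(vals, atlas$affine, tab$meta$subject_id[s])
    }))
  list(maps = maps, table = tab, t_threshold = t_threshold)
}

#' Serialize a cohort specification as JSON
#' @param spec a [cohort_spec()]; @param path output file.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  # named atomic vectors must become JSON objects, not bare arrays
  x$n_per_group <- as.list(x$n_per_group)
  x$subgroup_n <- as.list(x$subgroup_n)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(n_per_group = unlist(x$n_per_group),
              n_regions = x$n_regions,
              effect_regions = as.list(x$effect_regions),
              baseline_mean = x$baseline_mean,
              dispersion = x$dispersion,
              covariate_params = x$covariate_params,
              subgroup_n = unlist(x$subgroup_n),
              subgroup_effects = as.list(x$subgroup_effects),
              correlation_block = x$correlation_block,
              seed = x$seed)
}
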