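test_that("cohort_spec validates its fields by name", {
  expect_error(cohort_spec(n_per_group = c(case = 80)), "n_per_group")
  expect_error(cohort_spec(dispersion = 0), "dispersion")
  expect_error(cohort_spec(baseline_mean = -1), "baseline_mean")
  expect_error(cohort_spec(effect_regions = list(nope = 5)),
               "effect_regions")
  expect_error(cohort_spec(covariate_params = list(
    list(age_mean = 40, age_sd = 5, bmi_mean = 25, bmi_sd = 3,
         prop_male = 1.4),
    list(age_mean = 40, age_sd = 5, bmi_mean = 25, bmi_sd = 3,
         prop_male = 0.5))), "prop_male")
})

test_that("default cohort has the published shape: 111 x 117 + metadata", {
  tab <- generate_feature_table(cohort_spec(seed = 5))
  expect_equal(dim(tab$counts), c(111L, 117L))
  expect_equal(sum(tab$meta$group == "case"), 80L)
  expect_equal(sum(tab$meta$group == "control"), 31L)
  expect_equal(as.vector(table(tab$meta$subgroup)[c("START", "STOPP",
                                                    "POTS")]),
               c(23L, 46L, 11L))
  expect_true(all(tab$meta$subgroup[tab$meta$group == "control"] == "none"))
  expect_named(tab$meta, c("subject_id", "group", "subgroup", "age",
                           "sex", "bmi"))
})

test_that("null cohort region means stay within 4 SE; zero mean is exact", {
  spec <- cohort_spec(n_per_group = c(case = 120, control = 80),
                      n_regions = 40, baseline_mean = 30, dispersion = 2,
                      seed = 21)
  tab <- generate_feature_table(spec)
  mu <- 30
  se <- sqrt((mu + mu^2 / 2) / nrow(tab$counts))
  expect_true(all(abs(colMeans(tab$counts) - mu) < 4 * se))

  zero <- generate_feature_table(cohort_spec(baseline_mean = 0,
                                             dispersion = 7, seed = 2))
  expect_true(all(zero$counts == 0L))
})

test_that("identical spec and seed reproduce the table bitwise", {
  spec <- cohort_spec(effect_regions = list(region_005 = 12), seed = 9)
  expect_identical(generate_feature_table(spec),
                   generate_feature_table(spec))
  other <- generate_feature_table(cohort_spec(
    effect_regions = list(region_005 = 12), seed = 10))
  expect_false(identical(other$counts,
                         generate_feature_table(spec)$counts))
})

test_that("correlation_block induces the requested association", {
  spec <- cohort_spec(n_per_group = c(case = 150, control = 150),
                      n_regions = 10,
                      correlation_block = list(list(1, 2, 0.9)),
                      seed = 31)
  tab <- generate_feature_table(spec)
  r <- cor(tab$counts[, 1], tab$counts[, 2])
  expect_gt(r, 0.7)            # copula attenuates, but must stay strong
  expect_lt(abs(cor(tab$counts[, 3], tab$counts[, 4])), 0.3)
})

test_that("toy atlas tiles the grid deterministically", {
  spec <- toy_atlas_spec(c(6, 6, 6), 4, 10)
  atlas <- generate_toy_atlas(spec)
  sizes <- table(atlas$labels)
  expect_equal(sort(as.integer(names(sizes))), 1:4)
  expect_true(all(sizes >= 10))
  expect_equal(sum(sizes), 216)              # labels partition the grid
  expect_error(toy_atlas_spec(c(2, 2, 2), 117, 1), "grid too small")
  # histogram of labels equals an exhaustive voxel loop
  brute <- integer(4)
  for (v in as.vector(atlas$labels)) brute[v] <- brute[v] + 1L
  expect_equal(unname(as.integer(sizes)), brute)
  expect_identical(atlas$labels, generate_toy_atlas(spec)$labels)
})

test_that("generate_statmaps round-trips exactly through extraction", {
  atlas <- generate_toy_atlas(toy_atlas_spec(c(10, 10, 10), 8, 20))
  spec <- cohort_spec(n_per_group = c(case = 5, control = 4),
                      n_regions = 8, baseline_mean = 6, dispersion = 3,
                      effect_regions = list(region_002 = 10), seed = 13)
  out <- generate_statmaps(spec, atlas)
  rebuilt <- build_feature_table(out$maps, atlas, out$table$meta,
                                 t_threshold = out$t_threshold)
  expect_identical(rebuilt$counts, out$table$counts)
  expect_identical(rebuilt$meta, out$table$meta)
})

test_that("zero-count maps have no voxel above threshold", {
  atlas <- generate_toy_atlas(toy_atlas_spec(c(5, 5, 5), 3, 5))
  spec <- cohort_spec(n_per_group = c(case = 2, control = 2),
                      n_regions = 3, baseline_mean = 0, seed = 4)
  out <- generate_statmaps(spec, atlas, t_threshold = 3.17)
  expect_true(all(out$table$counts == 0L))
  for (m in out$maps) expect_true(all(m$values <= 3.17))
  expect_error(generate_statmaps(spec, atlas, t_threshold = Inf),
               "finite")
})

test_that("cohort spec JSON round trip preserves the generated table", {
  tmp <- withr::local_tempfile(fileext = ".json")
  spec <- cohort_spec(n_per_group = c(case = 10, control = 8),
                      n_regions = 6, effect_regions = list(region_003 = 9),
                      seed = 17)
  write_cohort_spec(spec, tmp)
  spec2 <- read_cohort_spec(tmp)
  expect_identical(generate_feature_table(spec)$counts,
                   generate_feature_table(spec2)$counts)
})

test_that("feature table CSV dialect round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- generate_feature_table(cohort_spec(
    n_per_group = c(case = 6, control = 5), n_regions = 4, seed = 3))
  write_feature_table(tab, tmp)
  header <- readLines(tmp, n = 1)
  expect_match(header, "^subject_id,group,subgroup,age,sex,bmi,region_001")
  back <- read_feature_table(tmp)
  expect_identical(back$counts, tab$counts)
  expect_equal(back$meta, tab$meta)
})
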