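Package: roilogit
Title: Region-of-Interest Voxel-Count Logistic Classification for Task fMRI
Version: 0.1.0
Authors@R: person("Maintainer", "roilogit", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying subjects from parcellated functional
    imaging activation counts. Voxelwise t-statistic maps are reduced to
    per-region suprathreshold voxel counts over an integer atlas
    parcellation; region features pass a Pearson multicollinearity screen
    and recursive feature elimination before a logistic model with
    demographic covariates is fitted, evaluated by stratified split search
    and k-fold cross-validation, and tested for significance by a
    label-shuffling permutation ("shuffle") test. Includes a synthetic
    cohort generator with planted group effects for end-to-end validation,
    a minimal NIfTI-1 reader/writer, and machine-readable transcriptions of
    published case/control and subgroup model coefficient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
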