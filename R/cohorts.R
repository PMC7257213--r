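#' Built-in example cohorts
#'
#' Deterministic record sets shaped like the cohorts a TOF-MRA aneurysm
#' screening study reports, used in examples and tests of the evaluation
#' module. `example_external_cohort()` has 35 single-aneurysm patients
#' (22 female / 13 male, 18 with hypertension), aneurysm size bins
#' `<3.0 / 3.0-4.9 / 5.0-9.9 / >=10.0` mm holding 2 / 11 / 17 / 5
#' aneurysms (diameters spanning 2.00-23.10 mm), and locations
#' ICA 19, MCA 5, ACA 8, PCA 3. The records carry no voxel sets (counts and
#' metadata only), so they exercise cohort summaries and subgroup tables,
#' not voxel matching.
#'
#' `example_case_multiplicities()` returns the per-case aneurysm counts of a
#' 76-case training-style cohort (4 double + 72 single = 80 aneurysms) and a
#' 20-case internal-test-style cohort (4 double + 1 triple + 14 single = 25
#' aneurysms; the remaining examination carries no annotated aneurysm, which
#' is how the stated per-case breakdown reconciles with 20 examinations).
#'
#' @return `example_external_cohort()`: a list of 35
#'   [annotation_record()]s. `example_case_multiplicities()`: a list with
#'   integer vectors `training` (length 76) and `internal_test` (length 20).
#' @export
example_external_cohort <- function() {
  diameters <- c(
    2.00, 2.60,                                          # < 3.0
    3.0, 3.2, 3.4, 3.6, 3.8, 4.0, 4.2, 4.4, 4.5, 4.7, 4.9, # 3.0-4.9
    5.0, 5.3, 5.6, 5.9, 6.2, 6.5, 6.8, 7.1, 7.4, 7.7, 8.0,
    8.3, 8.6, 8.9, 9.2, 9.5, 9.8,                        # 5.0-9.9
    10.0, 11.5, 13.0, 16.0, 23.10)                       # >= 10.0
  locations <- rep(c("ICA", "MCA", "ACA", "PCA"), times = c(19, 5, 8, 3))
  sex <- rep(c("female", "male"), times = c(22, 13))
  # deterministic age grids: normal quantiles truncated to the stated ranges
  ages <- c(pmin(pmax(stats::qnorm(stats::ppoints(22), 55, 15), 17), 76),
            pmin(pmax(stats::qnorm(stats::ppoints(13), 59, 10), 42), 75))
  hypertension <- rep(c(TRUE, FALSE), times = c(18, 17))
  lapply(seq_along(diameters), function(i)
    annotation_record(case_id = sprintf("ext-%02d", i),
                      aneurysm_voxels = list(matrix(0, 0, 3)),
                      diameters_mm = diameters[i],
                      locations = locations[i],
                      age = round(ages[i]), sex = sex[i],
                      hypertension = hypertension[i]))
}

#' @rdname example_external_cohort
#' @export
example_case_multiplicities <- function() {
  list(training = c(rep(2L, 4), rep(1L, 72)),
       internal_test = c(rep(2L, 4), 3L, rep(1L, 14), 0L))
}
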