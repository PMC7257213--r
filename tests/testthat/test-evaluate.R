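# build a record whose single aneurysm has `n` voxels along the x axis
line_record <- function(id = "c1", n = 10, start = 0) {
  vox <- cbind(start + seq_len(n) - 1, 0, 0)
  annotation_record(id, list(vox), diameters_mm = n, locations = "ICA",
                    age = 50, sex = "female", hypertension = FALSE)
}

det_row <- function(wx, r, score = 0.9) {
  data.frame(wx = wx, wy = 0, wz = 0, radius_mm = r, score = score)
}

test_that("the strict >30% overlap rule decides TP vs FP", {
  rec <- line_record(n = 100)
  # sphere centred at x = 14.5 with radius 15 covers x in [0, 29.5]: 30 voxels
  m30 <- match_detections(det_row(14.5, 15), rec)
  expect_identical(m30$detections$verdict, "FP") # exactly 30% is not enough
  expect_identical(m30$n_detected, 0L)
  # covering 31 voxels is a true positive
  m31 <- match_detections(det_row(15, 15.2), rec)
  expect_identical(m31$detections$verdict, "TP")
  expect_identical(m31$aneurysms$detected, TRUE)
  # no detections: one missed aneurysm, no FPs
  m0 <- match_detections(NULL, rec)
  expect_identical(c(m0$n_tp, m0$n_fp, m0$n_detected, m0$n_aneurysms),
                   c(0L, 0L, 0L, 1L))
})

test_that("one sphere can detect two aneurysms but counts once", {
  vox_a <- cbind(1:4, 0, 0)
  vox_b <- cbind(6:9, 0, 0)
  rec <- annotation_record("c2", list(vox_a, vox_b), diameters_mm = c(4, 4),
                           locations = c("ICA", "MCA"), age = 61,
                           sex = "male", hypertension = TRUE)
  m <- match_detections(det_row(5, 5), rec)
  expect_identical(m$n_tp, 1L)
  expect_identical(m$n_fp, 0L)
  expect_identical(m$n_detected, 2L)
})

test_that("match agrees with brute-force voxel counting on random cases", {
  set.seed(123)
  for (trial in 1:100) {
    nvox <- sample(5:40, 1)
    vox <- matrix(stats::runif(3 * nvox, 0, 16), ncol = 3)
    rec <- annotation_record("t", list(vox), diameters_mm = 5,
                             locations = "ACA", age = 40, sex = "female",
                             hypertension = FALSE)
    ctr <- stats::runif(3, 0, 16)
    r <- stats::runif(1, 2, 8)
    det <- data.frame(wx = ctr[1], wy = ctr[2], wz = ctr[3], radius_mm = r,
                      score = 1)
    m <- match_detections(det, rec)
    frac_bf <- mean(sqrt(colSums((t(vox) - ctr)^2)) <= r)
    expect_equal(m$detections$best_fraction, frac_bf)
    expect_identical(m$detections$verdict,
                     if (frac_bf > 0.30) "TP" else "FP")
  }
})

test_that("sensitivity and FP/case follow the printed precisions", {
  expect_identical(sensitivity(detected = 29, total = 35), 82.9)
  expect_identical(sensitivity(detected = 0, total = 7), 0)
  expect_identical(sensitivity(detected = 7, total = 7), 100)
  expect_error(sensitivity(detected = 0, total = 0), "no aneurysms")
  fake <- function(fp) structure(list(n_fp = fp, n_detected = 0L,
                                      n_aneurysms = 1L, case_id = "x"),
                                 class = "match_result")
  expect_identical(fp_per_case(lapply(1:10, function(i) fake(0L))), 0)
  expect_identical(fp_per_case(list(fake(3L), fake(4L))), 3.5)
  expect_identical(fp_per_case(list(fake(1L), fake(0L), fake(0L))), 0.33)
  expect_error(fp_per_case(list()), "no cases")
})

test_that("accounting identities hold for every match result", {
  set.seed(77)
  results <- lapply(1:10, function(i) {
    rec <- line_record(paste0("c", i), n = sample(5:20, 1))
    ndet <- sample(0:3, 1)
    det <- if (ndet > 0)
      do.call(rbind, lapply(seq_len(ndet), function(j)
        det_row(stats::runif(1, -10, 30), stats::runif(1, 1, 10))))
    else NULL
    match_detections(det, rec)
  })
  for (m in results) {
    ndet <- if (is.null(m$detections)) 0L else nrow(m$detections)
    expect_identical(m$n_tp + m$n_fp, ndet)
    expect_identical(m$n_detected + sum(!m$aneurysms$detected),
                     m$n_aneurysms)
  }
  # sensitivity is invariant to case ordering
  expect_identical(sensitivity(results), sensitivity(rev(results)))
})

test_that("subgroup sensitivities recompose the overall sensitivity", {
  cohort <- example_external_cohort()
  # deterministic outcome: detect every aneurysm >= 5 mm
  results <- lapply(cohort, function(rec) {
    det <- if (rec$diameters_mm >= 5) det_row(0, 10) else NULL
    rec2 <- rec
    rec2$aneurysm_voxels <- list(cbind(0, 0, 0)) # single-voxel target
    match_detections(det, rec2)
  })
  tab <- subgroup_analysis(results, cohort)
  expect_true(all(c("sex", "age", "hypertension", "size", "location") %in%
                    tab$axis))
  sz <- tab[tab$axis == "size", ]
  expect_identical(sz$sensitivity[sz$stratum == "<3.0"], 0)
  expect_identical(sz$sensitivity[sz$stratum == "3.0-4.9"], 0)
  expect_identical(sz$sensitivity[sz$stratum == "5.0-9.9"], 100)
  expect_identical(sz$sensitivity[sz$stratum == ">=10.0"], 100)
  # empty strata are undefined, not zero
  loc <- tab[tab$axis == "location", ]
  expect_true(is.na(loc$sensitivity[loc$stratum == "basilar"]))
  expect_identical(loc$n_aneurysms[loc$stratum == "basilar"], 0L)
  # count-weighted recomposition equals the overall sensitivity
  for (ax in unique(tab$axis)) {
    sub <- tab[tab$axis == ax & tab$n_aneurysms > 0, ]
    overall <- 100 * sum(sub$n_detected) / sum(sub$n_aneurysms)
    expect_equal(overall, 100 * 22 / 35, tolerance = 1e-9)
  }
})

test_that("the cohort summary reproduces table-style characteristics", {
  cohort <- example_external_cohort()
  cs <- summarize_cohort(cohort)
  expect_identical(cs$n_patients, 35L)
  expect_identical(cs$n_aneurysms, 35L)
  expect_identical(cs$size_bins, c(2L, 11L, 17L, 5L))
  expect_identical(cs$locations, c(19L, 5L, 8L, 3L, 0L, 0L))
  expect_identical(cs$n_hypertension, 18L)
  expect_identical(cs$pct_hypertension, 51.4)
  expect_identical(c(cs$n_female, cs$n_male), c(22L, 13L))
  expect_identical(sum(cs$size_bins), cs$n_aneurysms)
  # a single 4 mm aneurysm falls in the 3.0-4.9 bin alone
  one <- summarize_cohort(list(line_record(n = 4)))
  expect_identical(one$size_bins, c(0L, 1L, 0L, 0L))
  expect_error(summarize_cohort(list()), "no records")
})

test_that("per-case multiplicities add up across example cohorts", {
  mult <- example_case_multiplicities()
  expect_identical(length(mult$training), 76L)
  expect_identical(sum(mult$training), 80L)       # 4 x 2 + 72 x 1
  expect_identical(length(mult$internal_test), 20L)
  expect_identical(sum(mult$internal_test), 25L)  # 4 x 2 + 1 x 3 + 14 x 1
  recs <- lapply(seq_along(mult$training), function(i) {
    k <- mult$training[i]
    annotation_record(paste0("tr", i),
                      rep(list(cbind(0, 0, 0)), k),
                      diameters_mm = rep(5, k),
                      locations = rep("ICA", k), age = 50, sex = "female",
                      hypertension = FALSE)
  })
  expect_identical(count_aneurysms(recs), 80L)
})

test_that("cross-validation folds are balanced, disjoint and seeded", {
  folds <- crossval_split(paste0("c", 1:20), k = 5, seed = 3)
  expect_identical(length(folds), 5L)
  val <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(val) == 4L))
  expect_setequal(unlist(val), paste0("c", 1:20))
  expect_identical(anyDuplicated(unlist(val)), 0L)
  for (f in folds) expect_length(intersect(f$train, f$validation), 0)
  expect_identical(crossval_split(paste0("c", 1:20), 5, seed = 3), folds)
  expect_false(identical(crossval_split(paste0("c", 1:20), 5, seed = 4),
                         folds))
  expect_error(crossval_split(paste0("c", 1:3), k = 5), "fewer")
})

test_that("annotation records validate their metadata", {
  expect_error(annotation_record("x", list(cbind(0, 0, 0)),
                                 diameters_mm = 5, locations = "femoral"),
               "location")
  expect_error(annotation_record("x", list(cbind(0, 0, 0)),
                                 diameters_mm = -1, locations = "ICA"),
               "diameters")
  expect_error(annotation_record("x", list(cbind(0, 0, 0)),
                                 diameters_mm = numeric(0),
                                 locations = character(0)), "per aneurysm")
})
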