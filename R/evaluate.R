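ANEURYSM_LOCATIONS <- c("ICA", "MCA", "ACA", "PCA", "basilar", "vertebral")
SIZE_BIN_LABELS <- c("<3.0", "3.0-4.9", "5.0-9.9", ">=10.0")

#' Size bin of an aneurysm diameter
#'
#' Bins in mm: `[0, 3.0)`, `[3.0, 5.0)`, `[5.0, 10.0)`, `[10.0, Inf)`.
#'
#' @param diameter_mm numeric vector of max diameters.
#' @return Factor with the four bin labels.
#' @export
size_bin <- function(diameter_mm) {
  cut(diameter_mm, breaks = c(0, 3, 5, 10, Inf), labels = SIZE_BIN_LABELS,
      right = FALSE)
}

#' Per-case annotation record
#'
#' Ground-truth annotations and patient metadata for one imaging case. Each
#' aneurysm carries its annotated voxel set as world coordinates (mm), its
#' max diameter (mm) and an arterial location label.
#'
#' @param case_id case identifier.
#' @param aneurysm_voxels list of numeric matrices (one per aneurysm, rows =
#'   world mm coordinates of annotated voxels); may be empty.
#' @param diameters_mm numeric vector of max diameters, one per aneurysm,
#'   all > 0.
#' @param locations character vector of location labels from
#'   `ICA, MCA, ACA, PCA, basilar, vertebral`.
#' @param age years; `sex` `"male"`/`"female"`; `hypertension` logical.
#' @param sex,hypertension patient metadata.
#' @return An object of class `annotation_record`.
#' @export
annotation_record <- function(case_id, aneurysm_voxels = list(),
                              diameters_mm = numeric(0),
                              locations = character(0), age = NA_real_,
                              sex = NA_character_, hypertension = NA) {
  n <- length(aneurysm_voxels)
  if (length(diameters_mm) != n || length(locations) != n)
    stop("one diameter and one location per aneurysm required", call. = FALSE)
  if (n > 0 && any(diameters_mm <= 0)) stop("diameters must be > 0",
                                            call. = FALSE)
  if (n > 0 && !all(locations %in% ANEURYSM_LOCATIONS))
    stop("unknown location label; use one of ",
         paste(ANEURYSM_LOCATIONS, collapse = ", "), call. = FALSE)
  structure(list(case_id = case_id,
                 aneurysm_voxels = lapply(aneurysm_voxels, function(m) {
                   m <- as.matrix(m); storage.mode(m) <- "double"; m
                 }),
                 diameters_mm = as.numeric(diameters_mm),
                 locations = as.character(locations),
                 age = age, sex = sex, hypertension = hypertension),
            class = "annotation_record")
}

#' Match detection spheres against annotated aneurysms
#'
#' For every detection sphere the fraction of each aneurysm's annotated
#' voxels lying inside the sphere is computed. A detection is a true
#' positive if its best fraction is strictly greater than `overlap_rule`
#' (default 0.30 -- "more than 30% of the aneurysm inside the sphere"),
#' otherwise a false positive. An aneurysm is detected if at least one
#' detection captures it above the rule; one sphere covering two aneurysms
#' counts as a single TP but marks both detected.
#'
#' @param detections data.frame with `wx, wy, wz, radius_mm` (world mm), as
#'   produced by [run_pipeline()].
#' @param record an [annotation_record()] in the same world frame.
#' @param overlap_rule strict lower bound on the captured fraction.
#' @return An object of class `match_result`: list with `detections`
#'   (verdict and best fraction per detection), `aneurysms` (detected flag
#'   per aneurysm), `n_tp`, `n_fp`, `n_detected`, `n_aneurysms`, `case_id`.
#' @export
match_detections <- function(detections, record, overlap_rule = 0.30) {
  stopifnot(inherits(record, "annotation_record"))
  nd <- if (is.null(detections)) 0L else nrow(detections)
  na <- length(record$aneurysm_voxels)
  frac <- matrix(0, nrow = nd, ncol = na)
  if (nd > 0 && na > 0) {
    for (i in seq_len(nd)) {
      ctr <- c(detections$wx[i], detections$wy[i], detections$wz[i])
      r <- detections$radius_mm[i]
      for (j in seq_len(na)) {
        vx <- record$aneurysm_voxels[[j]]
        d2 <- (vx[, 1] - ctr[1])^2 + (vx[, 2] - ctr[2])^2 +
          (vx[, 3] - ctr[3])^2
        frac[i, j] <- mean(d2 <= r^2)
      }
    }
  }
  det_tp <- if (nd > 0) apply(frac, 1, function(f)
    length(f) > 0 && max(f) > overlap_rule) else logical(0)
  an_det <- if (na > 0) apply(frac, 2, function(f)
    length(f) > 0 && max(f) > overlap_rule) else logical(0)
  ddf <- if (nd > 0)
    cbind(detections,
          verdict = ifelse(det_tp, "TP", "FP"),
          best_fraction = if (na > 0) apply(frac, 1, max) else 0)
  else NULL
  structure(list(detections = ddf,
                 aneurysms = data.frame(
                   aneurysm = seq_len(na),
                   diameter_mm = record$diameters_mm,
                   location = record$locations,
                   detected = as.logical(an_det)),
                 overlap = frac,
                 n_tp = sum(det_tp), n_fp = sum(!det_tp),
                 n_detected = sum(an_det), n_aneurysms = na,
                 case_id = record$case_id),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> case %s: %d/%d aneurysm(s) detected, %d FP\n",
              x$case_id, x$n_detected, x$n_aneurysms, x$n_fp))
  invisible(x)
}

#' Detection sensitivity over a set of cases
#'
#' `100 * detected / total aneurysms`, reported to one decimal.
#'
#' @param results list of [match_detections()] results (or a single one); or
#'   give `detected` and `total` directly.
#' @param detected,total direct counts, bypassing `results`.
#' @return Sensitivity in percent (1 decimal).
#' @export
sensitivity <- function(results = NULL, detected = NULL, total = NULL) {
  if (is.null(detected)) {
    if (inherits(results, "match_result")) results <- list(results)
    detected <- sum(vapply(results, `[[`, 0L, "n_detected"))
    total <- sum(vapply(results, `[[`, 0L, "n_aneurysms"))
  }
  if (total < 1) stop("no aneurysms to evaluate", call. = FALSE)
  round(100 * detected / total, 1)
}

#' False positives per case
#'
#' Total FP detections divided by the number of cases, to two decimals.
#'
#' @param results list of [match_detections()] results.
#' @return FP/case rate (2 decimals).
#' @export
fp_per_case <- function(results) {
  if (inherits(results, "match_result")) results <- list(results)
  if (length(results) < 1) stop("no cases", call. = FALSE)
  round(sum(vapply(results, `[[`, 0L, "n_fp")) / length(results), 2)
}

# one row per aneurysm with stratifiers and its detection outcome
per_aneurysm_table <- function(results, records) {
  ids_r <- vapply(records, `[[`, "", "case_id")
  rows <- lapply(results, function(m) {
    rec <- records[[match(m$case_id, ids_r)]]
    na <- m$n_aneurysms
    if (na == 0) return(NULL)
    data.frame(case_id = rec$case_id,
               detected = m$aneurysms$detected,
               diameter_mm = rec$diameters_mm,
               location = rec$locations,
               sex = rec$sex, age = rec$age,
               hypertension = rec$hypertension,
               size_bin = size_bin(rec$diameters_mm))
  })
  do.call(rbind, rows)
}

#' Subgroup sensitivity analysis
#'
#' Sensitivity per stratum of sex, age band (`<60` / `>=60`), hypertension,
#' size bin and arterial location. Strata containing no aneurysms are
#' reported as `NA` (undefined), never as 0.
#'
#' @param results list of [match_detections()] results.
#' @param records the corresponding [annotation_record()]s.
#' @return data.frame with `axis`, `stratum`, `n_aneurysms`, `n_detected`,
#'   `sensitivity`.
#' @export
subgroup_analysis <- function(results, records) {
  tab <- per_aneurysm_table(results, records)
  strata <- list(
    sex = factor(tab$sex, levels = c("female", "male")),
    age = factor(ifelse(tab$age < 60, "<60", ">=60"),
                 levels = c("<60", ">=60")),
    hypertension = factor(ifelse(tab$hypertension, "yes", "no"),
                          levels = c("no", "yes")),
    size = factor(tab$size_bin, levels = SIZE_BIN_LABELS),
    location = factor(tab$location, levels = ANEURYSM_LOCATIONS))
  out <- lapply(names(strata), function(ax) {
    f <- strata[[ax]]
    lv <- levels(f)
    n <- as.integer(table(f))
    det <- vapply(lv, function(s) sum(tab$detected[!is.na(f) & f == s]), 0L)
    data.frame(axis = ax, stratum = lv, n_aneurysms = n, n_detected = det,
               sensitivity = ifelse(n > 0, round(100 * det / n, 1), NA_real_))
  })
  do.call(rbind, out)
}

#' Count annotated aneurysms in a set of records
#'
#' @param records list of [annotation_record()]s.
#' @return Integer total.
#' @export
count_aneurysms <- function(records) {
  sum(vapply(records, function(r) length(r$diameters_mm), 0L))
}

#' Cohort characterization table
#'
#' Patient counts by sex, mean and sd of age (overall and per sex),
#' hypertension count and percentage, aneurysm counts by size bin and by
#' arterial location, and mean and sd of aneurysm size.
#'
#' @param records nonempty list of [annotation_record()]s with complete
#'   diameters.
#' @return An object of class `cohort_summary` (a named list).
#' @export
summarize_cohort <- function(records) {
  if (length(records) == 0) stop("no records", call. = FALSE)
  diam <- unlist(lapply(records, `[[`, "diameters_mm"))
  if (anyNA(diam)) stop("missing diameters", call. = FALSE)
  loc <- unlist(lapply(records, `[[`, "locations"))
  sex <- vapply(records, `[[`, "", "sex")
  age <- vapply(records, `[[`, 0, "age")
  hyp <- vapply(records, `[[`, NA, "hypertension")
  bins <- table(size_bin(diam))
  locs <- table(factor(loc, levels = ANEURYSM_LOCATIONS))
  out <- list(
    n_patients = length(records),
    n_male = sum(sex == "male"), n_female = sum(sex == "female"),
    age_mean = mean(age), age_sd = stats::sd(age),
    age_mean_male = mean(age[sex == "male"]),
    age_mean_female = mean(age[sex == "female"]),
    n_hypertension = sum(hyp, na.rm = TRUE),
    pct_hypertension = round(100 * mean(hyp, na.rm = TRUE), 1),
    n_aneurysms = length(diam),
    size_mean = mean(diam), size_sd = stats::sd(diam),
    size_bins = as.integer(bins),
    size_bin_labels = names(bins),
    locations = as.integer(locs),
    location_labels = names(locs))
  stopifnot(sum(out$size_bins) == out$n_aneurysms,
            sum(out$locations) == out$n_aneurysms)
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients (%d F / %d M), age %.0f +/- %.0f\n",
              x$n_patients, x$n_female, x$n_male, x$age_mean, x$age_sd))
  cat(sprintf("  hypertension: %d (%.1f%%)\n", x$n_hypertension,
              x$pct_hypertension))
  cat(sprintf("  %d aneurysms, size %.2f +/- %.2f mm\n", x$n_aneurysms,
              x$size_mean, x$size_sd))
  cat("  size bins: ", paste(sprintf("%s: %d", x$size_bin_labels,
                                     x$size_bins), collapse = ", "), "\n")
  cat("  locations: ", paste(sprintf("%s: %d", x$location_labels,
                                     x$locations), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic k-fold cross-validation split
#'
#' Disjoint folds covering all cases, sizes differing by at most one,
#' reproducible under the seed.
#'
#' @param cases vector of case identifiers (>= k of them).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return List of `k` lists with `train` and `validation` case vectors.
#' @export
crossval_split <- function(cases, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (length(cases) < k) stop("fewer cases than folds", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(cases)
  fold <- rep_len(seq_len(k), length(cases))
  lapply(seq_len(k), function(i)
    list(train = perm[fold != i], validation = perm[fold == i]))
}
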