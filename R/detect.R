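#' Binarize a likelihood volume
#'
#' Strictly-greater thresholding at `threshold` (default 0.5): a voxel with
#' likelihood exactly equal to the threshold stays background.
#'
#' @param l a likelihood [volume()] (values in `[0, 1]`).
#' @param threshold in `[0, 1]`.
#' @return Logical mask array.
#' @export
binarize_likelihood <- function(l, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]",
                                           call. = FALSE)
  array(as.vector(l) > threshold, dim = dim(l))
}

#' Turn predicted components into sphere-marker detections
#'
#' Each 26-connected component of the binarized prediction with at least
#' `min_component_size` voxels yields one detection: a sphere marker at the
#' component centroid (rounded to the nearest voxel) with the shared
#' annotation radius, scored by the component's maximum likelihood.
#'
#' @param mask logical mask (binarized likelihood).
#' @param radius marker radius in voxels.
#' @param min_component_size smallest component (voxels) kept as a
#'   detection; suppresses single-voxel noise.
#' @param likelihood optional likelihood [volume()] for scores; if missing,
#'   scores are `NA`.
#' @param spacing,origin grid metadata used to report world coordinates.
#' @return A data.frame of detections, one row per component, sorted by
#'   score descending: voxel center (`cx`, `cy`, `cz`), world center in mm
#'   (`wx`, `wy`, `wz`), `radius_voxels`, `radius_mm`, `score`,
#'   `component_voxels`.
#' @export
components_to_detections <- function(mask, radius, min_component_size = 5L,
                                     likelihood = NULL,
                                     spacing = c(1, 1, 1),
                                     origin = c(0, 0, 0)) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0",
                                               call. = FALSE)
  d <- dim(mask)
  empty <- data.frame(cx = integer(0), cy = integer(0), cz = integer(0),
                      wx = numeric(0), wy = numeric(0), wz = numeric(0),
                      radius_voxels = numeric(0), radius_mm = numeric(0),
                      score = numeric(0), component_voxels = integer(0))
  if (!any(mask)) return(empty)
  lab <- cpp_label_components(as.vector(mask), d, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component_size)
  if (length(keep) == 0) return(empty)
  lvals <- if (!is.null(likelihood)) as.numeric(likelihood) else NULL
  rows <- lapply(keep, function(k) {
    vox <- which(lab == k)
    ctr <- as.integer(round(colMeans(arrayInd(vox, d))))
    ctr <- pmin(pmax(ctr, 1L), d)
    w <- origin + (ctr - 1) * spacing
    data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
               wx = w[1], wy = w[2], wz = w[3],
               radius_voxels = radius, radius_mm = radius * mean(spacing),
               score = if (is.null(lvals)) NA_real_ else max(lvals[vox]),
               component_voxels = sizes[k])
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$score), -Inf, out$score),
            out$cx, out$cy, out$cz), , drop = FALSE]
}

#' Render detections as a sphere-marker label mask
#'
#' Shares the lattice-ball kernel with [dilate_voi()], so a marker of radius
#' r contains exactly the integer offsets with Euclidean norm at most r.
#'
#' @param detections a [components_to_detections()] data.frame.
#' @param dim grid dimensions.
#' @return Logical mask with all marker spheres stamped in.
#' @export
detections_to_mask <- function(detections, dim) {
  m <- array(FALSE, dim = dim)
  for (i in seq_len(nrow(detections))) {
    s <- array(FALSE, dim = dim)
    s[detections$cx[i], detections$cy[i], detections$cz[i]] <- TRUE
    m <- m | array(cpp_dilate_ball(as.vector(s), dim,
                                   detections$radius_voxels[i]), dim = dim)
  }
  m
}

#' Detection-count behaviour across binarization thresholds
#'
#' Applies [binarize_likelihood()] and [components_to_detections()] at each
#' threshold. Raising the threshold can only shrink the binarized set, so
#' the detection count is non-increasing. This measures (not enforces) how
#' threshold-sensitive a model's detections are.
#'
#' @param l likelihood [volume()].
#' @param thresholds numeric vector in `[0, 1]`.
#' @param ... passed to [components_to_detections()].
#' @inheritParams components_to_detections
#' @return Named list of detection data.frames, one per threshold.
#' @export
threshold_sweep <- function(l, thresholds = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            radius = annotation_radius(dim(l)[1]), ...) {
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be in [0, 1]", call. = FALSE)
  out <- lapply(thresholds, function(t)
    components_to_detections(binarize_likelihood(l, t), radius = radius,
                             likelihood = l, spacing = vol_spacing(l),
                             origin = vol_origin(l), ...))
  names(out) <- sprintf("%.3g", thresholds)
  out
}

# wrap a stage so failures carry the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full CAD pipeline on one case
#'
#' Executes the whole chain: read (if `input` is a path), preprocess
#' (bias-field correction, optional histogram normalization, sigmoid
#' enhancement), skull stripping, automatic vessel segmentation, surface
#' meshing, VOI dilation, block preparation, network prediction, likelihood
#' binarization and sphere-marker extraction. Detections are reported in
#' block voxels and in original-resolution world millimetres (the marker
#' radius is rescaled by the spacing ratio).
#'
#' @param input a [volume()], a NIfTI path, or a DICOM directory.
#' @param model a trained `model_state`.
#' @param config a [pipeline_config()].
#' @param reference optional [histogram_normalize()] reference.
#' @return List: `detections` (data.frame, world coordinates of the original
#'   grid), `mesh` ([surface_mesh()]), `voi`, `vessel_mask`, `likelihood`,
#'   `stripped`, `block`.
#' @export
run_pipeline <- function(input, model, config = pipeline_config(),
                         reference = NULL) {
  v <- stage("read", {
    if (inherits(input, "volume")) input
    else if (dir.exists(input)) read_dicom_series(input)
    else read_nifti(input)
  })
  pre <- stage("preprocess", {
    p <- correct_bias_field(v, iterations = config$bias_iterations,
                            levels = config$bias_levels)
    if (!is.null(reference)) p <- histogram_normalize(p, reference)
    p
  })
  st <- stage("strip_skull",
              strip_skull(pre, lower_fraction = config$skull_lower_fraction,
                          smooth_radius = config$skull_smooth_radius,
                          connectivity = config$connectivity))
  st$volume <- stage("enhance",
                     sigmoid_enhance(st$volume,
                                     sigmoid_params(config$sigmoid_alpha,
                                                    config$sigmoid_beta)))
  vm <- stage("segment_vessels",
              segment_vessels(st$volume, n_top = config$n_seed_components,
                              connectivity = config$connectivity))
  mesh <- stage("extract_mesh",
                extract_mesh(vm, vol_spacing(v), vol_origin(v)))
  voi <- stage("dilate_voi", dilate_voi(vm, radius = config$voi_radius))
  blk <- stage("prepare_block", {
    img <- st$volume
    lab <- label_volume(array(as.integer(voi$mask), dim = dim(v)),
                        vol_spacing(v), vol_origin(v),
                        legend = c(background = 0L, vessel = 1L,
                                   aneurysm = 2L))
    bt <- stats::quantile(as.numeric(img), 0.5)
    b <- prepare_block(list(image = img, labels = lab),
                       size = model$config$input_size,
                       background_threshold = bt)
    b
  })
  voi_block <- array(as.vector(blk$labels) == 1L, dim = dim(blk$labels))
  lik <- stage("predict", predict_likelihood(model, blk$image, voi_block))
  mask <- stage("binarize",
                binarize_likelihood(lik, config$likelihood_threshold))
  r_block <- annotation_radius(model$config$input_size)
  det <- stage("detect",
               components_to_detections(mask, radius = r_block,
                                        min_component_size =
                                          config$min_component_size,
                                        likelihood = lik,
                                        spacing = vol_spacing(blk$image),
                                        origin = vol_origin(blk$image)))
  # marker radius in original-resolution mm: block radius x block spacing
  det$radius_mm <- rep(r_block * mean(vol_spacing(blk$image)), nrow(det))
  list(detections = det, mesh = mesh, voi = voi, vessel_mask = vm,
       likelihood = lik, stripped = st$volume, block = blk)
}
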