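#' Flip a volume through the transverse section
#'
#' Reverses the slice (superior-inferior) axis; voxel `(x, y, z)` maps to
#' `(x, y, Z + 1 - z)`. Grid metadata is unchanged, and the operation is its
#' own inverse.
#'
#' @param v a [volume()] or [label_volume()].
#' @return Same class as `v`.
#' @export
flip_transverse <- function(v) {
  d <- dim(v)
  dat <- v[, , d[3]:1, drop = FALSE]
  if (inherits(v, "label_volume"))
    label_volume(array(dat, dim = d), vol_spacing(v), vol_origin(v),
                 label_legend(v))
  else vol_like(dat, v)
}

#' Discrete Gaussian smoothing filter
#'
#' Separable convolution with a sampled, normalized Gaussian kernel of the
#' given variance (in voxel units), truncated to at most `max_kernel_width`
#' taps per axis, with replicate (constant-extension) boundaries. With
#' `variance = 0` the volume is returned unchanged.
#'
#' @param v a [volume()].
#' @param variance Gaussian variance, >= 0 (default 4.0).
#' @param max_kernel_width maximum taps per axis (default 32).
#' @return Smoothed [volume()].
#' @export
discrete_gaussian <- function(v, variance = 4.0, max_kernel_width = 32L) {
  if (!is.numeric(variance) || variance < 0)
    stop("`variance` must be >= 0", call. = FALSE)
  if (variance == 0) return(v)
  out <- cpp_gauss_smooth(as.numeric(v), dim(v), sqrt(variance),
                          as.integer(max_kernel_width))
  vol_like(out, v)
}

#' Eight-fold augmentation of an image/label pair
#'
#' Emits all `2^3 = 8` apply/skip combinations of the three augmentation
#' filters -- transverse flip, discrete Gaussian smoothing, histogram
#' equalization -- applied in that order. Labels undergo only the geometric
#' transform (the flip); intensity filters never touch them. The identity
#' variant (no filter) is always included, so `n` input pairs become exactly
#' `8 n` output pairs.
#'
#' @param pair list of `image` ([volume()]) and `labels` ([label_volume()]).
#' @param variance,max_kernel_width passed to [discrete_gaussian()].
#' @param intensity_filter third filter: `"equalize"` (default) or
#'   `"normalize"` (decile matching against the unfiltered image).
#' @return An object of class `augmented_set`: list with `items` (list of
#'   pairs) and `provenance` (character tags like `"flip+gaussian"`).
#' @export
augment_variants <- function(pair, variance = 4.0, max_kernel_width = 32L,
                             intensity_filter = c("equalize", "normalize")) {
  intensity_filter <- match.arg(intensity_filter)
  stopifnot(is.list(pair), inherits(pair$image, "volume"),
            inherits(pair$labels, "label_volume"))
  ref <- histogram_landmarks(pair$image)
  items <- list()
  tags <- character(0)
  for (do_flip in c(FALSE, TRUE))
    for (do_gauss in c(FALSE, TRUE))
      for (do_hist in c(FALSE, TRUE)) {
        img <- pair$image
        lab <- pair$labels
        if (do_flip) { img <- flip_transverse(img); lab <- flip_transverse(lab) }
        if (do_gauss) img <- discrete_gaussian(img, variance, max_kernel_width)
        if (do_hist) img <- switch(intensity_filter,
                                   equalize = histogram_equalize(img),
                                   normalize = histogram_normalize(img, ref))
        tag <- paste(c(if (do_flip) "flip", if (do_gauss) "gaussian",
                       if (do_hist) "histeq"), collapse = "+")
        if (tag == "") tag <- "identity"
        items[[length(items) + 1L]] <- list(image = img, labels = lab)
        tags <- c(tags, tag)
      }
  structure(list(items = items, provenance = tags), class = "augmented_set")
}

#' @rdname augment_variants
#' @param pairs list of pairs; each is augmented independently and the
#'   results concatenated (so the output size is `8 * length(pairs)`).
#' @param ... passed on to [augment_variants()].
#' @export
augment_set <- function(pairs, ...) {
  sets <- lapply(pairs, augment_variants, ...)
  items <- do.call(c, c(lapply(sets, `[[`, "items"), list(list())))
  prov <- unlist(mapply(function(s, i) paste0("src", i, ":", s$provenance),
                        sets, seq_along(sets), SIMPLIFY = FALSE))
  structure(list(items = items, provenance = as.character(prov)),
            class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("<augmented_set> %d items (%d per source)\n", length(x$items),
              if (length(x$items)) 8L else 0L))
  invisible(x)
}

#' Sphere annotation radius rule
#'
#' The shared sphere radius used both to dilate training annotations and to
#' draw detection markers: strictly above 3 voxels at a 128-voxel block axis,
#' i.e. `max(4, ceiling(0.03 * axis_length))`.
#'
#' @param axis_length block axis length in voxels.
#' @return Integer radius in voxels.
#' @export
annotation_radius <- function(axis_length) {
  max(4L, as.integer(ceiling(0.03 * axis_length)))
}

#' Replace aneurysm annotations by fixed-radius spheres
#'
#' Each 26-connected aneurysm-labelled component is replaced by a filled
#' digital sphere of the shared [annotation_radius()] centered on the
#' component centroid (rounded to the nearest voxel). Vessel labels elsewhere
#' are preserved; spheres are clipped at the volume border.
#'
#' @param lv a [label_volume()] containing at least one aneurysm component.
#' @param axis_length the block axis length the radius rule refers to
#'   (default: the largest axis of `lv`).
#' @return A [label_volume()] with attribute `centers` (matrix of sphere
#'   centers) and `radius`.
#' @export
annotation_to_sphere <- function(lv, axis_length = max(dim(lv))) {
  legend <- label_legend(lv)
  an_lab <- legend[["aneurysm"]]
  d <- dim(lv)
  an <- array(as.vector(lv) == an_lab, dim = d)
  if (!any(an)) stop("no aneurysm label present", call. = FALSE)
  r <- annotation_radius(axis_length)
  comp <- cpp_label_components(as.vector(an), d, 26L)
  ncomp <- max(comp)
  out <- array(as.integer(lv), dim = d)
  out[out == an_lab] <- legend[["vessel"]] # old extent returns to vessel
  centers <- matrix(0L, ncomp, 3)
  for (k in seq_len(ncomp)) {
    idx <- arrayInd(which(comp == k), d)
    ctr <- as.integer(round(colMeans(idx)))
    centers[k, ] <- ctr
    sph <- array(FALSE, dim = d)
    sph[ctr[1], ctr[2], ctr[3]] <- TRUE
    sph <- array(cpp_dilate_ball(as.vector(sph), d, r), dim = d)
    out[sph] <- an_lab
  }
  res <- label_volume(out, vol_spacing(lv), vol_origin(lv), legend)
  attr(res, "centers") <- centers
  attr(res, "radius") <- r
  res
}

#' Crop and resample a pair to a fixed cubic block
#'
#' Crops the image (and its labels, with the same box) to the content
#' bounding box, then resamples both to `size^3` -- trilinear for the image,
#' nearest for the labels, so no new label values appear.
#'
#' @param pair list of `image` and `labels` on one grid.
#' @param size block axis length (default 128; >= 8).
#' @param background_threshold content threshold for the crop.
#' @return List of `image`, `labels`, both exactly `size^3`.
#' @export
prepare_block <- function(pair, size = 128L, background_threshold = 0) {
  size <- as.integer(size)
  if (size < 8L) stop("`size` must be >= 8", call. = FALSE)
  img <- crop_to_content(pair$image, background_threshold)
  box <- attr(img, "crop_box")
  lab <- crop_to_content(pair$labels, box = box)
  list(image = resize_to(img, rep(size, 3), "linear"),
       labels = resize_to(lab, rep(size, 3), "nearest"))
}
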