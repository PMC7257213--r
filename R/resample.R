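#' Resample a volume to isotropic spacing
#'
#' Axis lengths become `round(len * spacing / target)` (at least 1), so the
#' physical extent is preserved to within one voxel. The world position of
#' voxel (1,1,1) is kept fixed. Label volumes must use `mode = "nearest"`,
#' which can only ever reproduce label values already present.
#'
#' @param v a [volume()] or [label_volume()].
#' @param target_spacing target isotropic spacing in mm, > 0.
#' @param mode `"linear"` (intensities) or `"nearest"` (labels).
#' @return Object of the same class as `v` with spacing
#'   `c(target, target, target)`.
#' @export
resample_isotropic <- function(v, target_spacing,
                               mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1 ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be a single positive number", call. = FALSE)
  is_label <- inherits(v, "label_volume")
  if (is_label && mode != "nearest")
    stop("label volumes must be resampled with mode = \"nearest\"",
         call. = FALSE)
  sp <- vol_spacing(v)
  if (all(abs(sp - target_spacing) < 1e-9)) return(v)
  odim <- pmax(1L, as.integer(round(dim(v) * sp / target_spacing)))
  scale <- target_spacing / sp
  out <- cpp_resample(as.numeric(v), dim(v), odim, scale, c(0, 0, 0),
                      if (mode == "nearest") 1L else 0L)
  out <- array(out, dim = odim)
  if (is_label)
    label_volume(out, spacing = rep(target_spacing, 3),
                 origin = vol_origin(v), legend = label_legend(v))
  else
    volume(out, spacing = rep(target_spacing, 3), origin = vol_origin(v))
}

# resize to an exact target shape (center-aligned), used for block prep
resize_to <- function(v, odim, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  odim <- as.integer(odim)
  is_label <- inherits(v, "label_volume")
  scale <- dim(v) / odim
  offset <- (scale - 1) / 2
  out <- array(cpp_resample(as.numeric(v), dim(v), odim, scale, offset,
                            if (mode == "nearest") 1L else 0L), dim = odim)
  sp <- vol_spacing(v) * scale
  o <- vol_origin(v) + (sp - vol_spacing(v)) / 2
  if (is_label) label_volume(out, spacing = sp, origin = o,
                             legend = label_legend(v))
  else volume(out, spacing = sp, origin = o)
}

#' Crop a volume to its content bounding box
#'
#' Returns the tight bounding box of voxels strictly above
#' `background_threshold`. The origin is shifted so retained voxels keep
#' their world coordinates.
#'
#' @param v a [volume()] or [label_volume()].
#' @param background_threshold intensity; voxels `> threshold` are content.
#' @param box optional precomputed bounding box (list of `lo`, `hi` index
#'   vectors) to apply instead, e.g. the image box reused for its labels.
#' @return Cropped object of the same class, with attribute `crop_box`.
#' @export
crop_to_content <- function(v, background_threshold = 0, box = NULL) {
  if (!is.finite(background_threshold))
    stop("`background_threshold` must be finite", call. = FALSE)
  if (is.null(box)) {
    idx <- which(array(as.vector(v) > background_threshold, dim = dim(v)),
                 arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty content: no voxel above threshold",
                             call. = FALSE)
    box <- list(lo = unname(apply(idx, 2, min)),
                hi = unname(apply(idx, 2, max)))
  }
  lo <- box$lo; hi <- box$hi
  dat <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  o <- vol_origin(v) + (lo - 1) * vol_spacing(v)
  out <- if (inherits(v, "label_volume"))
    label_volume(array(dat, dim = hi - lo + 1L), spacing = vol_spacing(v),
                 origin = o, legend = label_legend(v))
  else
    volume(array(dat, dim = hi - lo + 1L), spacing = vol_spacing(v), origin = o)
  attr(out, "crop_box") <- box
  out
}
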