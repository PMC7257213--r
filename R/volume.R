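#' 3D image volume
#'
#' The universal image carrier of the pipeline: a 3D numeric array with voxel
#' spacing (mm) and world origin (mm) attached. Axes are indexed `(x, y, z)`
#' with `z` the slice (superior-inferior) axis; the world position of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`. Direction
#' cosines are assumed axis-aligned.
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing numeric length-3, mm per voxel along each axis, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("each axis length must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("all intensities must be finite", call. = FALSE)
  storage.mode(data) <- "double"
  structure(data, spacing = spacing, origin = origin,
            axes = "xyz (z = slice axis)", class = "volume")
}

#' @rdname volume
#' @param v a `volume` or `label_volume`.
#' @export
vol_spacing <- function(v) attr(v, "spacing", exact = TRUE)

#' @rdname volume
#' @export
vol_origin <- function(v) attr(v, "origin", exact = TRUE)

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing %s mm, origin (%s)\n",
              paste(dim(x), collapse = "x"),
              paste(signif(vol_spacing(x), 4), collapse = "x"),
              paste(signif(vol_origin(x), 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# rebuild a volume from raw array + template metadata
vol_like <- function(data, template, spacing = vol_spacing(template),
                     origin = vol_origin(template)) {
  volume(array(as.numeric(data), dim = dim(template)), spacing, origin)
}

#' Integer label volume on a parent grid
#'
#' A mask of integer labels sharing a [volume()]'s grid. The legend maps each
#' label to its role; the conventional legend is `0` background, `1` vessel,
#' `2` aneurysm.
#'
#' @param labels 3D integer array.
#' @param spacing,origin grid metadata, as in [volume()].
#' @param legend named integer vector mapping role -> label.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         legend = c(background = 0L, vessel = 1L,
                                    aneurysm = 2L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must be non-missing", call. = FALSE)
  if (!all(unique(as.vector(labels)) %in% legend))
    stop("every voxel's label must be in the legend", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values", call. = FALSE)
  structure(labels, spacing = spacing, origin = origin, legend = legend,
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = attr(x, "legend")))
  names(tab) <- names(attr(x, "legend"))
  cat(sprintf("<label_volume> %s voxels, spacing %s mm\n",
              paste(dim(x), collapse = "x"),
              paste(signif(vol_spacing(x), 4), collapse = "x")))
  print(tab)
  invisible(x)
}

#' @rdname label_volume
#' @param lv a `label_volume`.
#' @export
label_legend <- function(lv) attr(lv, "legend", exact = TRUE)

# check two grids match (shape + spacing within float tolerance)
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    all(abs(vol_spacing(a) - vol_spacing(b)) < tol) &&
    all(abs(vol_origin(a) - vol_origin(b)) < tol)
}

#' Triangle surface mesh in world coordinates
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be Nx3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be Mx3", call. = FALSE)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("faces must reference 3 distinct vertices", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n", nrow(x$vertices),
              nrow(x$faces)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param m a `surface_mesh`.
#' @export
mesh_area <- function(m) {
  if (nrow(m$faces) == 0) return(0)
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# logical 3D mask helper (bare array, no metadata)
as_mask <- function(x) {
  m <- x
  if (inherits(m, "volume") || inherits(m, "label_volume"))
    m <- array(as.vector(m) != 0, dim = dim(m))
  storage.mode(m) <- "logical"
  m
}
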