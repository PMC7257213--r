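#' Region-growing parameters
#'
#' @param lower,upper inclusive intensity band; `lower <= upper`.
#' @param connectivity voxel neighbourhood: 6, 18 or 26.
#' @return An object of class `region_grow_params`.
#' @export
region_grow_params <- function(lower, upper, connectivity = 26L) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower > upper)
    stop("need lower <= upper", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(lower = lower, upper = upper, connectivity = connectivity),
            class = "region_grow_params")
}

#' Seed points with provenance
#'
#' @param points integer matrix, one row per seed (1-based voxel indices).
#' @param provenance `"skull-contact"` or `"component-rank"`.
#' @param source per-point metadata (cube face or component rank).
#' @return An object of class `seed_point_set`.
#' @export
seed_point_set <- function(points, provenance = c("skull-contact",
                                                  "component-rank"),
                           source = NULL) {
  provenance <- match.arg(provenance)
  points <- matrix(as.integer(points), ncol = 3)
  if (nrow(points) == 0) stop("seed set must be non-empty", call. = FALSE)
  structure(list(points = points, provenance = provenance,
                 source = source %||% rep(NA, nrow(points))),
            class = "seed_point_set")
}

#' Automatic skull seed selection by the shrinking bounding box
#'
#' From the center of each of the six bounding-box faces, a ray marches
#' inward along the face normal; the first voxel whose intensity reaches
#' `contact_threshold` becomes a seed ("the cube's face touches the skull").
#' Faces whose ray never reaches a bright voxel contribute no seed.
#'
#' @param v a [volume()].
#' @param contact_threshold intensity at which a ray is considered to touch
#'   the skull; default 30% of the volume maximum.
#' @return A [seed_point_set()] with up to 6 seeds.
#' @export
select_skull_seeds <- function(v, contact_threshold = 0.30 * max(v)) {
  d <- dim(v)
  ctr <- pmax(1L, as.integer(round(d / 2)))
  seeds <- NULL
  faces <- character(0)
  march <- function(start, step_axis, dir) {
    idx <- start
    while (idx[step_axis] >= 1 && idx[step_axis] <= d[step_axis]) {
      val <- v[idx[1], idx[2], idx[3]]
      if (val >= contact_threshold && val > 0) return(idx)
      idx[step_axis] <- idx[step_axis] + dir
    }
    NULL
  }
  specs <- list(list(c(1L, ctr[2], ctr[3]), 1L, 1L, "x-"),
                list(c(d[1], ctr[2], ctr[3]), 1L, -1L, "x+"),
                list(c(ctr[1], 1L, ctr[3]), 2L, 1L, "y-"),
                list(c(ctr[1], d[2], ctr[3]), 2L, -1L, "y+"),
                list(c(ctr[1], ctr[2], 1L), 3L, 1L, "z-"),
                list(c(ctr[1], ctr[2], d[3]), 3L, -1L, "z+"))
  for (s in specs) {
    hit <- march(s[[1]], s[[2]], s[[3]])
    if (!is.null(hit)) { seeds <- rbind(seeds, hit); faces <- c(faces, s[[4]]) }
  }
  if (is.null(seeds))
    stop("no skull contact: no ray reached the contact threshold",
         call. = FALSE)
  seed_point_set(seeds, "skull-contact", faces)
}

#' Threshold-band region growing from seed points
#'
#' Flood-fills the set of voxels connected to at least one seed through
#' voxels whose intensity lies in `[p$lower, p$upper]`. Seeds outside the
#' band are dropped with a warning; if all are dropped an error is raised.
#'
#' @param v a [volume()].
#' @param seeds a [seed_point_set()].
#' @param p a [region_grow_params()].
#' @return Logical 3D mask array.
#' @export
grow_region <- function(v, seeds, p) {
  stopifnot(inherits(seeds, "seed_point_set"),
            inherits(p, "region_grow_params"))
  pts <- seeds$points
  vals <- v[pts]
  ok <- vals >= p$lower & vals <= p$upper
  if (!all(ok)) {
    warning(sum(!ok), " seed(s) outside the intensity band were dropped")
    pts <- pts[ok, , drop = FALSE]
  }
  if (nrow(pts) == 0) stop("all seeds fall outside [lower, upper]",
                           call. = FALSE)
  mask <- cpp_flood_fill(as.numeric(v), dim(v), pts - 1L, p$lower, p$upper,
                         p$connectivity)
  array(mask, dim = dim(v))
}

# binary morphological closing with a Euclidean ball (dilate then erode)
closing_ball <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  dil <- array(cpp_dilate_ball(as.vector(mask), d, radius), dim = d)
  # erosion = complement of dilation of the complement
  ero <- !array(cpp_dilate_ball(as.vector(!dil), d, radius), dim = d)
  ero
}

#' Skull stripping by auto-threshold region growing
#'
#' Seeds are selected on the skull with [select_skull_seeds()]; the region
#' grows through the band `[0.30 * max(v), max(v)]`; the grown mask is
#' smoothed by binary closing and the covered voxels are cut out (set to the
#' background value).
#'
#' @param v a preprocessed [volume()].
#' @param lower_fraction lower growing threshold as a fraction of the
#'   maximum intensity.
#' @param smooth_radius closing radius (voxels) applied to the skull mask.
#' @param background_value intensity written into removed voxels.
#' @param connectivity neighbourhood for growing.
#' @return List with `volume` (stripped) and `skull_mask` (logical array).
#' @export
strip_skull <- function(v, lower_fraction = 0.30, smooth_radius = 2,
                        background_value = min(v), connectivity = 26L) {
  mx <- max(v)
  thr <- lower_fraction * mx
  seeds <- select_skull_seeds(v, contact_threshold = thr)
  mask <- grow_region(v, seeds, region_grow_params(thr, mx, connectivity))
  mask <- closing_ball(mask, smooth_radius)
  out <- v
  out[mask] <- background_value
  list(volume = vol_like(out, v), skull_mask = mask)
}

#' Binarize foreground voxels
#'
#' Strictly-greater thresholding: voxels with intensity `> background_value`
#' are set.
#'
#' @param v a [volume()].
#' @param background_value finite threshold intensity.
#' @return Logical mask array.
#' @export
binarize_foreground <- function(v, background_value) {
  if (!is.finite(background_value)) stop("threshold must be finite",
                                         call. = FALSE)
  array(as.vector(v) > background_value, dim = dim(v))
}

# Otsu threshold of a numeric vector (maximizes between-class variance)
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Select vessel seed points from the largest connected domains
#'
#' Labels 26-connected components of the foreground mask, ranks them by
#' voxel count, and returns one seed per component for the top
#' `min(n_top, n_components)` components. The seed is the component's
#' maximum-intensity voxel; ties (in component size or intensity) are broken
#' by the smaller lexicographic index, so the result is deterministic.
#'
#' @param mask logical foreground mask.
#' @param v the [volume()] the mask was derived from.
#' @param n_top number of top-ranked components to seed (default 5).
#' @return A [seed_point_set()] with attribute `components` (logical mask of
#'   the union of the selected components) and `labels` (full labeling).
#' @export
select_vessel_seeds <- function(mask, v, n_top = 5L) {
  d <- dim(mask)
  if (!any(mask)) stop("empty mask: nothing to seed", call. = FALSE)
  lab <- cpp_label_components(as.vector(mask), d, 26L)
  sizes <- tabulate(lab)
  ord <- order(-sizes, seq_along(sizes)) # size desc, then first-seen label id
  top <- ord[seq_len(min(n_top, length(sizes)))]
  pts <- NULL
  for (k in top) {
    vox <- which(lab == k)
    best <- vox[order(-as.numeric(v)[vox], vox)][1]
    pts <- rbind(pts, arrayInd(best, d))
  }
  comp <- array(lab %in% top, dim = d)
  out <- seed_point_set(pts, "component-rank", seq_along(top))
  attr(out, "components") <- comp
  attr(out, "labels") <- array(lab, dim = d)
  attr(out, "top") <- top
  out
}

#' Vessel intensity model
#'
#' Gaussian model of vessel intensity: sample mean and standard deviation
#' (n-1 denominator) over the seed-component voxels. These drive the
#' automatic growing thresholds `mu - sigma` and `mu + sigma`.
#'
#' @param v a [volume()].
#' @param seed_components logical mask of the seed components.
#' @return An object of class `vessel_intensity_model` with fields `mu`,
#'   `sigma`, `n`.
#' @export
estimate_vessel_model <- function(v, seed_components) {
  x <- as.numeric(v)[as.vector(seed_components)]
  if (length(x) < 2) stop("need at least 2 voxels to estimate the model",
                          call. = FALSE)
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0) {
    warning("degenerate vessel intensities; sigma floored")
    sigma <- max(abs(mu), 1) * sqrt(.Machine$double.eps)
  }
  structure(list(mu = mu, sigma = sigma, n = length(x)),
            class = "vessel_intensity_model")
}

#' @export
print.vessel_intensity_model <- function(x, ...) {
  cat(sprintf("<vessel_intensity_model> mu = %.4g, sigma = %.4g (n = %d)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Automatic vessel segmentation
#'
#' The composite step-one segmentation on a skull-stripped volume: binarize
#' the foreground, seed the five largest connected domains, fit the Gaussian
#' vessel intensity model over those domains, and region-grow in the band
#' `[mu - sigma, mu + sigma]` from the seeds.
#'
#' @param v a skull-stripped [volume()].
#' @param background_value binarization threshold; default the Otsu
#'   threshold of `v`.
#' @param n_top number of seed components.
#' @param connectivity growing neighbourhood.
#' @return Logical vessel mask with attributes `model`
#'   (the [estimate_vessel_model()] fit) and `seeds`.
#' @export
segment_vessels <- function(v, background_value = NULL, n_top = 5L,
                            connectivity = 26L) {
  if (is.null(background_value)) background_value <- otsu_threshold(
    as.numeric(v))
  fg <- binarize_foreground(v, background_value)
  if (!any(fg)) stop("empty foreground after binarization", call. = FALSE)
  seeds <- select_vessel_seeds(fg, v, n_top)
  model <- estimate_vessel_model(v, attr(seeds, "components"))
  lo <- model$mu - model$sigma; hi <- model$mu + model$sigma
  # a component's single brightest voxel usually sits above mu + sigma; the
  # usable seed is its brightest voxel inside the growing band
  lab <- attr(seeds, "labels")
  x <- as.numeric(v)
  pts <- NULL
  for (k in attr(seeds, "top")) {
    vox <- which(lab == k & x >= lo & x <= hi)
    if (length(vox) == 0) next
    best <- vox[order(-x[vox], vox)][1]
    pts <- rbind(pts, arrayInd(best, dim(v)))
  }
  if (is.null(pts))
    stop("no seed component contains voxels inside [mu - sigma, mu + sigma]",
         call. = FALSE)
  seeds_band <- seed_point_set(pts, "component-rank", seq_len(nrow(pts)))
  mask <- grow_region(v, seeds_band,
                      region_grow_params(lo, hi, connectivity))
  attr(mask, "model") <- model
  attr(mask, "seeds") <- seeds
  mask
}

#' Extract the vessel surface mesh
#'
#' Zero-pads the binary mask by one voxel, optionally smooths the 0/1 field,
#' and extracts the 0.5 iso-surface with a table-free marching-tetrahedra
#' scheme (consistent 6-tetrahedra cube decomposition), yielding a watertight
#' triangle mesh in world millimetres. A few Laplacian smoothing passes
#' relax the lattice faceting so digitized spheres measure close to their
#' analytic area.
#'
#' @param mask logical vessel mask.
#' @param spacing voxel spacing (mm).
#' @param origin world origin of the mask grid.
#' @param smooth_iters Laplacian smoothing passes applied to the mesh.
#' @param lambda smoothing step size in (0, 1].
#' @return A [surface_mesh()].
#' @export
extract_mesh <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         smooth_iters = 6, lambda = 0.6) {
  if (!any(mask)) stop("empty mask: no surface to extract", call. = FALSE)
  d <- dim(mask)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  res <- cpp_march_tets(as.numeric(pad), dim(pad), as.numeric(spacing),
                        as.numeric(origin) - as.numeric(spacing), 0.5)
  m <- surface_mesh(res$vertices, res$faces)
  if (smooth_iters > 0 && nrow(m$vertices) > 4)
    m <- smooth_mesh(m, iterations = smooth_iters, lambda = lambda)
  m
}

# uniform Laplacian smoothing over the vertex adjacency graph
smooth_mesh <- function(m, iterations = 6, lambda = 0.6) {
  F <- m$faces
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  V <- m$vertices
  ids <- sort(unique(edges[, 1]))
  deg <- tabulate(edges[, 1], nbins = nrow(V))
  for (it in seq_len(iterations)) {
    nb <- rowsum(V[edges[, 2], , drop = FALSE], edges[, 1])
    mean_nb <- nb / deg[ids]
    V[ids, ] <- (1 - lambda) * V[ids, , drop = FALSE] + lambda * mean_nb
  }
  surface_mesh(V, F)
}

#' Dilate the vessel mask into the volume of interest
#'
#' Morphological dilation with the Euclidean-ball structuring element
#' `{offset : ||offset||_2 <= radius}`. The VOI always contains the vessel
#' mask it was dilated from; the network predicts only inside it.
#'
#' @param vessel_mask logical mask.
#' @param radius ball radius in voxels (default 10).
#' @return An object of class `voi`: list of `mask`, `dilation_radius`.
#' @export
dilate_voi <- function(vessel_mask, radius = 10) {
  if (!is.numeric(radius) || radius < 0) stop("radius must be >= 0",
                                              call. = FALSE)
  d <- dim(vessel_mask)
  out <- if (radius == 0) vessel_mask else
    array(cpp_dilate_ball(as.vector(vessel_mask), d, radius), dim = d)
  structure(list(mask = out, dilation_radius = radius), class = "voi")
}

#' Fraction of a lesion mask covered by the VOI
#'
#' @param voi a [dilate_voi()] result (or a bare logical mask).
#' @param aneurysm_mask logical mask of annotated aneurysm voxels on the
#'   same grid.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(voi, aneurysm_mask) {
  m <- if (inherits(voi, "voi")) voi$mask else voi
  if (!identical(dim(m), dim(aneurysm_mask)))
    stop("masks are on different grids", call. = FALSE)
  n <- sum(aneurysm_mask)
  if (n == 0) stop("empty aneurysm mask", call. = FALSE)
  sum(m & aneurysm_mask) / n
}
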