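#' Sigmoid vessel-enhancement parameters
#'
#' Parameters of the voxelwise contrast remap
#' `f(x) = (out_max - out_min) / (1 + exp(-(x - beta) / alpha)) + out_min`.
#' `alpha` sets the width of the transition (intensity units), `beta` its
#' center. With the defaults `alpha = 400`, `beta = 600` the transition is
#' centered in the bright (vessel/skull) part of a typical TOF-MRA intensity
#' range. When `out_min`/`out_max` are `NULL` they default to the input
#' volume's min/max, so the transform remaps contrast without rescaling the
#' dynamic range.
#'
#' @param alpha positive intensity width.
#' @param beta intensity center.
#' @param out_min,out_max output floor/ceiling, or `NULL` to take them from
#'   the input volume.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(alpha = 400, beta = 600, out_min = NULL,
                           out_max = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0",
                                             call. = FALSE)
  if (!is.null(out_min) && !is.null(out_max) && out_max <= out_min)
    stop("`out_max` must exceed `out_min`", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, out_min = out_min,
                 out_max = out_max), class = "sigmoid_params")
}

#' Sigmoid vessel enhancement
#'
#' Applies the strictly increasing sigmoid remap of [sigmoid_params()] voxel
#' by voxel. Output values lie strictly inside `(out_min, out_max)`.
#'
#' @param v a [volume()].
#' @param p a [sigmoid_params()].
#' @return An enhanced [volume()] on the same grid.
#' @export
sigmoid_enhance <- function(v, p = sigmoid_params()) {
  if (!inherits(p, "sigmoid_params")) stop("`p` must be sigmoid_params",
                                           call. = FALSE)
  lo <- p$out_min %||% min(v)
  hi <- p$out_max %||% max(v)
  if (hi <= lo) hi <- lo + 1 # constant input: keep the map well-defined
  out <- (hi - lo) / (1 + exp(-(as.numeric(v) - p$beta) / p$alpha)) + lo
  vol_like(out, v)
}

#' N4-style multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative intensity field in the log domain by
#' the iterative scheme of the N3/N4 family: each iteration sharpens the
#' current residual's intensity histogram (Wiener deconvolution, then the
#' conditional expectation of the uncorrupted intensity), so the remaining
#' per-voxel residual exposes the shading rather than tissue contrast, and
#' fits the smooth field model to it. The field model is a low-order 3D
#' polynomial: it can represent scanner shading but cannot follow anatomy,
#' so genuine structures are never absorbed. The output's mean intensity
#' over the foreground is restored to the input's.
#'
#' @param v a [volume()] with non-negative intensities.
#' @param iterations maximum field-update iterations.
#' @param degree total degree of the polynomial field model (3 gives 20
#'   basis terms; 1 is a pure gradient).
#' @param shrink integer downsampling factor for field estimation (the field
#'   is smooth by assumption, so it is fit on a coarse grid and upsampled).
#' @param sharpen_fwhm full width at half maximum (log-intensity units) of
#'   the Gaussian deconvolved from the histogram in the sharpening step. It
#'   should sit between the within-tissue log-intensity noise width and the
#'   separation of genuine tissue modes.
#' @param levels retained for call compatibility; the polynomial model has a
#'   single resolution level.
#' @return Corrected [volume()]; the estimated field is attached as attribute
#'   `bias_field`.
#' @export
correct_bias_field <- function(v, iterations = 50, degree = 3L, shrink = 4L,
                               sharpen_fwhm = 0.3, levels = NULL) {
  x <- as.numeric(v)
  if (any(x < 0)) stop("bias correction requires non-negative intensities",
                       call. = FALSE)
  if (all(x == 0)) stop("all-zero volume", call. = FALSE)
  fg <- x > stats::quantile(x[x > 0], 0.05)
  if (!any(fg)) fg <- x > 0
  eps <- max(x) * 1e-6
  d <- dim(v)
  dlr <- pmax(4L, as.integer(ceiling(d / shrink)))
  scale <- d / dlr
  logx <- log(x + eps)
  loglr <- cpp_resample(logx, d, dlr, scale, (scale - 1) / 2, 0L)
  fglr <- cpp_resample(as.numeric(fg), d, dlr, scale, (scale - 1) / 2,
                       1L) > 0.5
  if (sum(fglr) < 4 * poly3d_nterms(degree)) fglr <- rep(TRUE, length(loglr))
  B <- poly3d_basis(dlr, degree)
  Bfg <- B[fglr, , drop = FALSE]
  qrB <- qr(Bfg)
  logfield <- numeric(length(loglr))
  resid <- loglr
  if (stats::sd(loglr[fglr]) > 1e-8) {
    for (it in seq_len(iterations)) {
      # histogram sharpening: the residual against E[u | v] carries the
      # field, not tissue contrast
      r <- resid[fglr] - n4_expectation(resid[fglr], fwhm = sharpen_fwhm)
      coef <- qr.coef(qrB, r)
      sm <- drop(B %*% coef)
      sm <- sm - mean(sm[fglr]) # zero-mean field in log domain
      logfield <- logfield + sm
      # a multiplicative shading field plausibly spans [1/2, 2]
      logfield <- pmin(pmax(logfield, -0.7), 0.7)
      resid <- loglr - logfield
      if (max(abs(sm[fglr])) < 1e-4) break
    }
  }
  # upsample the log-field back to the full grid
  logfield_full <- cpp_resample(logfield, dlr, d, 1 / scale,
                                (1 / scale - 1) / 2, 0L)
  field <- exp(logfield_full)
  corrected <- x / field
  corrected <- corrected * mean(x[fg]) / mean(corrected[fg])
  out <- vol_like(corrected, v)
  attr(out, "bias_field") <- array(field, dim = dim(v))
  out
}

poly3d_nterms <- function(degree) {
  choose(degree + 3, 3)
}

# monomial basis x^i y^j z^k (i + j + k <= degree) on a coarse grid, with
# coordinates scaled to [-1, 1]
poly3d_basis <- function(dlr, degree) {
  cx <- seq(-1, 1, length.out = dlr[1])
  cy <- seq(-1, 1, length.out = dlr[2])
  cz <- seq(-1, 1, length.out = dlr[3])
  g <- expand.grid(x = cx, y = cy, z = cz)
  cols <- list()
  for (deg in 0:degree)
    for (i in 0:deg) for (j in 0:(deg - i)) {
      k <- deg - i - j
      cols[[length(cols) + 1L]] <- g$x^i * g$y^j * g$z^k
    }
  do.call(cbind, cols)
}

# E[u | v] for every element of v: the Wiener-deconvolution histogram
# sharpening at the heart of the N3/N4 family. v is a vector of log
# intensities; returns the expected uncorrupted log intensity per element.
n4_expectation <- function(v, fwhm = 0.15, wiener_noise = 0.001,
                           n_bins = 200L) {
  rng <- range(v)
  if (diff(rng) < 1e-9) return(v)
  binw <- diff(rng) / (n_bins - 1)
  mids <- seq(rng[1], rng[2], length.out = n_bins)
  idx <- pmin(pmax(round((v - rng[1]) / binw) + 1, 1), n_bins)
  h <- tabulate(idx, nbins = n_bins)
  # Gaussian blur kernel on the bin grid (wrapped for FFT)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  off <- c(0:(n_bins %/% 2), -((n_bins - n_bins %/% 2 - 1):1)) * binw
  g <- exp(-0.5 * (off / sigma)^2)
  g <- g / sum(g)
  Hf <- stats::fft(h)
  Gf <- stats::fft(g)
  # Wiener deconvolution of the observed histogram
  f <- Re(stats::fft(Hf * Conj(Gf) / (Mod(Gf)^2 + wiener_noise),
                     inverse = TRUE)) / n_bins
  f <- pmax(f, 0)
  # E[u|v] = conv(f * u, g) / conv(f, g), evaluated on the bin grid
  num <- Re(stats::fft(stats::fft(f * mids) * Gf, inverse = TRUE)) / n_bins
  den <- Re(stats::fft(stats::fft(f) * Gf, inverse = TRUE)) / n_bins
  Eu <- num / pmax(den, 1e-12)
  Eu[den <= 1e-12] <- mids[den <= 1e-12]
  Eu[idx]
}

#' Piecewise-linear histogram normalization
#'
#' Maps the deciles of `v`'s foreground histogram onto the reference's
#' (landmark matching in the Nyul style). The mapping is monotone
#' non-decreasing and extends linearly beyond the outermost landmarks.
#'
#' @param v a [volume()].
#' @param reference a [volume()] supplying the target decile landmarks, or a
#'   numeric vector of stored landmarks (as returned by
#'   `histogram_landmarks()`).
#' @param foreground_quantile voxels above this quantile of the positive
#'   intensities count as foreground for landmark estimation.
#' @return Normalized [volume()].
#' @export
histogram_normalize <- function(v, reference,
                                foreground_quantile = 0.05) {
  src <- histogram_landmarks(v, foreground_quantile)
  tgt <- if (inherits(reference, "volume"))
    histogram_landmarks(reference, foreground_quantile)
  else as.numeric(reference)
  if (length(tgt) != length(src))
    stop("stored landmark profile must have ", length(src), " values",
         call. = FALSE)
  if (length(unique(src)) < 2)
    stop("degenerate (single-valued) histogram", call. = FALSE)
  # enforce strictly increasing source knots for interpolation
  keep <- !duplicated(src)
  src2 <- src[keep]; tgt2 <- tgt[keep]
  tgt2 <- cummax(tgt2) # monotone non-decreasing
  x <- as.numeric(v)
  out <- stats::approx(src2, tgt2, xout = x, rule = 2)$y
  # extend the outermost segments linearly beyond the landmark range
  k <- length(src2)
  slope_lo <- (tgt2[2] - tgt2[1]) / (src2[2] - src2[1])
  slope_hi <- (tgt2[k] - tgt2[k - 1]) / (src2[k] - src2[k - 1])
  below <- x < src2[1]; above <- x > src2[k]
  out[below] <- tgt2[1] + slope_lo * (x[below] - src2[1])
  out[above] <- tgt2[k] + slope_hi * (x[above] - src2[k])
  vol_like(out, v)
}

#' @rdname histogram_normalize
#' @export
histogram_landmarks <- function(v, foreground_quantile = 0.05) {
  x <- as.numeric(v)
  pos <- x[x > min(x)]
  if (length(pos) < 2) stop("degenerate (single-valued) histogram",
                            call. = FALSE)
  lo <- stats::quantile(pos, foreground_quantile)
  fg <- x[x >= lo]
  unname(stats::quantile(fg, seq(0, 1, by = 0.1)))
}

#' Classic CDF-based histogram equalization
#'
#' Remaps intensities through the empirical CDF so the output histogram is
#' approximately uniform over the input's range. Rank order is preserved.
#'
#' @param v a [volume()].
#' @param n_bins number of histogram bins.
#' @return Equalized [volume()] spanning the input's intensity range.
#' @export
histogram_equalize <- function(v, n_bins = 256) {
  x <- as.numeric(v)
  rng <- range(x)
  if (diff(rng) == 0) stop("constant volume cannot be equalized",
                           call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  cdf <- cumsum(tabulate(bin, nbins = n_bins))
  cmin <- min(cdf[cdf > 0])
  out <- (cdf[bin] - cmin) / (length(x) - cmin)
  out <- rng[1] + out * diff(rng)
  vol_like(out, v)
}
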