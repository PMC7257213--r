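#' Synthetic TOF-MRA phantom specification
#'
#' Parameters of the seeded vascular phantom generator. The phantom emulates
#' the intensity statistics the pipeline assumes: a dark noisy background, a
#' bright peripheral skull/scalp shell (the brightest contiguous peripheral
#' structure, geometrically disconnected from the interior), a vessel tree of
#' smoothed 3D random-walk tubes whose voxel intensities are i.i.d.
#' Gaussian, spherical aneurysm bumps attached to vessel walls sharing the
#' vessel intensity law, and an optional smooth multiplicative bias field.
#'
#' @param size voxels per axis (cubic volume).
#' @param spacing isotropic voxel size in mm.
#' @param bg_mean,bg_sd background intensity law (clipped at 0).
#' @param shell_thickness,shell_intensity,shell_sd peripheral shell geometry
#'   (voxels) and intensity law.
#' @param n_branches number of vessel random-walk branches.
#' @param vessel_radius_range tube radius range in voxels (>= 1).
#' @param vessel_mu,vessel_sigma Gaussian vessel intensity law.
#' @param n_aneurysms number of aneurysm bumps.
#' @param aneurysm_radius_range sphere radius range in voxels (>= 2).
#' @param bias_amplitude multiplicative bias field amplitude `a` (field spans
#'   about `1 - a` to `1 + a`); 0 disables it.
#' @param rng_seed integer seed; the same spec is always rendered
#'   bit-identically.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, spacing = 1, bg_mean = 60, bg_sd = 15,
                         shell_thickness = 2, shell_intensity = 900,
                         shell_sd = 40, n_branches = 3L,
                         vessel_radius_range = c(1.5, 2.5), vessel_mu = 600,
                         vessel_sigma = 20, n_aneurysms = 1L,
                         aneurysm_radius_range = c(3, 6),
                         bias_amplitude = 0.15, rng_seed = 1L) {
  if (vessel_radius_range[1] < 1) stop("vessel radii must be >= 1",
                                       call. = FALSE)
  if (aneurysm_radius_range[1] < 2) stop("aneurysm radii must be >= 2",
                                         call. = FALSE)
  if (vessel_sigma <= 0) stop("vessel_sigma must be > 0", call. = FALSE)
  structure(list(size = as.integer(size), spacing = spacing,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 shell_thickness = shell_thickness,
                 shell_intensity = shell_intensity, shell_sd = shell_sd,
                 n_branches = as.integer(n_branches),
                 vessel_radius_range = vessel_radius_range,
                 vessel_mu = vessel_mu, vessel_sigma = vessel_sigma,
                 n_aneurysms = as.integer(n_aneurysms),
                 aneurysm_radius_range = aneurysm_radius_range,
                 bias_amplitude = bias_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# stamp a Euclidean ball of the given radius at (1-based) center into mask
stamp_ball <- function(mask, center, radius) {
  d <- dim(mask)
  s <- array(FALSE, dim = d)
  s[center[1], center[2], center[3]] <- TRUE
  mask | array(cpp_dilate_ball(as.vector(s), d, radius), dim = d)
}

#' Generate one synthetic phantom
#'
#' Renders the [phantom_spec()] into an intensity [volume()], a
#' [label_volume()] (0 background, 1 vessel, 2 aneurysm) and an
#' [annotation_record()] carrying per-aneurysm voxel sets (world mm), max
#' diameters (`2 * radius * spacing`) and randomized patient metadata. The
#' vessel tree stays geometrically separated from the shell by a dark moat,
#' so skull stripping can never remove vessels.
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier for the annotation record.
#' @return List with `image`, `labels`, `record`, and `aneurysm_info`
#'   (data.frame of centers and radii in voxels).
#' @export
generate_phantom <- function(spec = phantom_spec(), case_id = "phantom-1") {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$rng_seed)
  n <- spec$size
  d <- c(n, n, n)
  ctr <- (n + 1) / 2
  # radial coordinate of every voxel (voxel units from the volume center)
  ax <- seq_len(n) - ctr
  r2grid <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  rad <- sqrt(r2grid)
  shell_outer <- n / 2 - 1
  shell_inner <- shell_outer - spec$shell_thickness
  interior_max <- shell_inner - 3 - max(spec$vessel_radius_range) # dark moat
  # vessel centerlines: smoothed random walks confined to the interior ball
  vessel <- array(FALSE, dim = d)
  centerline <- NULL
  for (b in seq_len(spec$n_branches)) {
    pos <- c(ctr, ctr, ctr) + stats::rnorm(3, 0, n / 12)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    rb <- stats::runif(1, spec$vessel_radius_range[1],
                       spec$vessel_radius_range[2])
    steps <- as.integer(2.5 * n)
    for (s in seq_len(steps)) {
      dir <- dir + stats::rnorm(3, 0, 0.25)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + dir
      if (sqrt(sum((cand - ctr)^2)) > interior_max) {
        dir <- (ctr - pos); dir <- dir / sqrt(sum(dir^2)) # turn back inward
        cand <- pos + dir
      }
      pos <- cand
      ip <- as.integer(round(pos))
      if (all(ip >= 1 & ip <= n)) {
        vessel <- stamp_ball(vessel, ip, rb)
        centerline <- rbind(centerline, c(ip, rb))
      }
    }
  }
  # aneurysm bumps tangent to (and overlapping) the vessel wall
  aneurysm <- array(FALSE, dim = d)
  an_masks <- list()
  info <- NULL
  for (a in seq_len(spec$n_aneurysms)) {
    placed <- FALSE
    for (try in seq_len(80)) {
      ra <- stats::runif(1, spec$aneurysm_radius_range[1],
                         spec$aneurysm_radius_range[2])
      k <- sample.int(nrow(centerline), 1)
      p <- centerline[k, 1:3]; rv <- centerline[k, 4]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cen <- as.integer(round(p + u * (rv + ra - 1)))
      if (any(cen < 1 | cen > n)) next
      if (sqrt(sum((cen - ctr)^2)) + ra > interior_max + 2) next
      m <- stamp_ball(array(FALSE, dim = d), cen, ra)
      placed <- TRUE
      aneurysm <- aneurysm | m
      an_masks[[length(an_masks) + 1L]] <- m
      info <- rbind(info, data.frame(cx = cen[1], cy = cen[2], cz = cen[3],
                                     radius_voxels = ra))
      break
    }
    if (!placed) stop("aneurysm placement failed after bounded retries",
                      call. = FALSE)
  }
  shell <- rad >= shell_inner & rad <= shell_outer
  # intensities
  img <- array(pmax(0, stats::rnorm(n^3, spec$bg_mean, spec$bg_sd)), dim = d)
  nv <- sum(vessel | aneurysm)
  img[vessel | aneurysm] <- stats::rnorm(nv, spec$vessel_mu,
                                         spec$vessel_sigma)
  img[shell] <- stats::rnorm(sum(shell), spec$shell_intensity, spec$shell_sd)
  if (spec$bias_amplitude > 0) {
    g <- stats::rnorm(3); g <- g / sqrt(sum(g^2))
    lin <- outer(outer(ax * g[1], ax * g[2], "+"), ax * g[3], "+") / (n / 2)
    img <- img * (1 + spec$bias_amplitude * lin)
  }
  img <- pmax(img, 0)
  labels <- array(0L, dim = d)
  labels[vessel] <- 1L
  labels[aneurysm] <- 2L # aneurysm label wins on the overlap
  sp <- rep(spec$spacing, 3)
  vol <- volume(img, spacing = sp)
  lv <- label_volume(labels, spacing = sp)
  vox_world <- lapply(an_masks, function(m) {
    idx <- arrayInd(which(m & labels == 2L), d)
    sweep(idx - 1, 2, sp, "*")
  })
  rec <- annotation_record(
    case_id = case_id,
    aneurysm_voxels = vox_world,
    diameters_mm = 2 * info$radius_voxels * spec$spacing,
    locations = sample(c("ICA", "MCA", "ACA", "PCA"), nrow(info),
                       replace = TRUE, prob = c(19, 5, 8, 3)),
    age = round(min(max(stats::rnorm(1, 57, 14), 17), 86)),
    sex = sample(c("female", "male"), 1, prob = c(22, 13)),
    hypertension = stats::runif(1) < 0.5)
  list(image = vol, labels = lv, record = rec, aneurysm_info = info)
}

#' Generate a seeded phantom cohort
#'
#' Renders `n` phantoms with per-case jittered specs and metadata. Each case
#' is assigned a target aneurysm max diameter; the voxel radius stays in the
#' detectable range while the voxel spacing absorbs the size difference, so
#' cohorts span all four size bins and several location labels. With
#' `size_bin_quotas` the per-bin aneurysm counts are fixed exactly
#' (single-aneurysm cases only).
#'
#' @param n number of cases (>= 1).
#' @param spec template [phantom_spec()].
#' @param seed cohort seed; case `i` renders with seed `seed * 1000 + i`.
#' @param size_bin_quotas optional integer vector of length 4 summing to a
#'   value >= n: aneurysm counts per size bin (`<3`, `3-4.9`, `5-9.9`,
#'   `>=10` mm).
#' @return List of [generate_phantom()] triples.
#' @export
generate_cohort <- function(n, spec = phantom_spec(), seed = 1L,
                            size_bin_quotas = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bin_ranges <- list(c(1.6, 2.9), c(3.0, 4.9), c(5.0, 9.9), c(10.0, 16.0))
  if (!is.null(size_bin_quotas)) {
    stopifnot(length(size_bin_quotas) == 4, sum(size_bin_quotas) >= n)
    bins <- rep(1:4, times = size_bin_quotas)[seq_len(n)]
  } else {
    bins <- rep_len(sample(1:4), n) # every bin represented for n >= 4
  }
  lapply(seq_len(n), function(i) {
    rng <- bin_ranges[[bins[i]]]
    diameter <- stats::runif(1, rng[1], rng[2])
    r_target <- stats::runif(1, 3.5, 5.5) # voxel radius stays detectable
    sp_i <- diameter / (2 * r_target)
    s <- spec
    s$spacing <- sp_i
    s$aneurysm_radius_range <- c(r_target, r_target)
    s$n_aneurysms <- if (is.null(size_bin_quotas) && stats::runif(1) < 0.1)
      2L else 1L
    s$rng_seed <- as.integer(seed * 1000 + i) %% .Machine$integer.max
    generate_phantom(s, case_id = sprintf("case-%03d", i))
  })
}
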