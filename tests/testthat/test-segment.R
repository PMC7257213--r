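test_that("skull seeds are found where face-center rays meet the target", {
  n <- 64
  v <- volume(array(0, rep(n, 3)))
  ctr <- round(n / 2)
  b <- ball_mask(n, 10, center = rep(ctr, 3))
  v[b] <- 1000
  seeds <- select_skull_seeds(v, contact_threshold = 300)
  expect_identical(nrow(seeds$points), 6L)
  d <- sqrt(rowSums(sweep(seeds$points, 2, ctr)^2))
  expect_true(all(abs(d - 10) <= 1)) # analytic sphere-surface distance
  expect_error(select_skull_seeds(volume(array(0, c(8, 8, 8))),
                                  contact_threshold = 1), "no skull contact")
})

test_that("a shell touching only one face region seeds at most 6 points", {
  n <- 32
  a <- array(0, rep(n, 3))
  a[, , 30] <- 500 # bright plate near the z+ face
  v <- volume(a)
  seeds <- select_skull_seeds(v, contact_threshold = 100)
  expect_lte(nrow(seeds$points), 6L)
  zplus <- seeds$points[seeds$source == "z+", , drop = FALSE]
  expect_identical(unname(zplus[, 3]), 30L)
})

test_that("region growing floods exactly the connected in-band set", {
  v <- box_volume(c(10, 10, 10), lo = c(3, 3, 3), hi = c(7, 7, 7),
                  value = 100)
  s <- seed_point_set(matrix(c(5, 5, 5), 1), "component-rank")
  m <- grow_region(v, s, region_grow_params(50, 150))
  expect_identical(sum(m), 125L)
  # a second disconnected block is not reached
  v2 <- v
  v2[1, 1, 1] <- 100
  m2 <- grow_region(v2, s, region_grow_params(50, 150))
  expect_false(m2[1, 1, 1])
  expect_identical(sum(m2), 125L)
  expect_error(
    expect_warning(grow_region(v, seed_point_set(matrix(c(1, 1, 1), 1),
                                                 "component-rank"),
                               region_grow_params(50, 150)), "dropped"),
    "outside")
})

test_that("skull stripping removes the shell but not a disconnected tube", {
  n <- 48
  a <- array(0, rep(n, 3))
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  rad <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  shell <- rad >= 20 & rad <= 22
  a[shell] <- 1000
  a[22:26, 22:26, 10:38] <- 600 # interior tube, geometrically separate
  v <- volume(a)
  st <- strip_skull(v)
  expect_true(all(st$volume[shell] == 0))
  tube <- array(FALSE, rep(n, 3)); tube[22:26, 22:26, 10:38] <- TRUE
  expect_true(all(st$volume[tube] == 600))
  # the global max lived on the shell, so the stripped max is lower
  expect_lt(max(st$volume), max(v))
  expect_error(strip_skull(volume(array(0, c(8, 8, 8)))),
               "no skull contact")
})

test_that("foreground binarization is strictly greater-than", {
  v <- volume(array(c(0, 10, 20), c(3, 1, 1)))
  expect_equal(as.vector(binarize_foreground(v, 10)), c(FALSE, FALSE, TRUE))
  expect_false(any(binarize_foreground(v, max(v))))
  expect_true(all(binarize_foreground(v, min(v) - 1)))
})

test_that("vessel seeding picks the largest components deterministically", {
  d <- c(40, 40, 12)
  a <- array(0, d)
  sizes <- c(100, 90, 80, 70, 60, 50, 40)
  for (i in seq_along(sizes)) { # disjoint bars of decreasing length
    a[(5 * i - 4):(5 * i - 1), seq_len(ceiling(sizes[i] / 4)), 5] <- 100
    a[(5 * i - 4):(5 * i - 1), seq_len(ceiling(sizes[i] / 4)), 5] <-
      100 + i # distinct intensities
  }
  mask <- a > 0
  v <- volume(a)
  seeds <- select_vessel_seeds(mask, v)
  expect_identical(nrow(seeds$points), 5L)
  lab <- attr(seeds, "labels")
  picked <- sort(unique(lab[seeds$points]))
  sizes_all <- tabulate(lab[lab > 0])
  expect_setequal(sizes_all[picked], sort(sizes_all, decreasing = TRUE)[1:5])
  # fewer than five components
  m3 <- array(FALSE, c(10, 10, 10))
  m3[1, 1, 1] <- TRUE; m3[5, 5, 5] <- TRUE; m3[9, 9, 9] <- TRUE
  s3 <- select_vessel_seeds(m3, volume(array(1, c(10, 10, 10))))
  expect_identical(nrow(s3$points), 3L)
  # ties are broken deterministically across repeated runs
  m2 <- array(FALSE, c(10, 10, 10))
  m2[2:3, 2, 2] <- TRUE; m2[7:8, 7, 7] <- TRUE
  v2 <- volume(array(1, c(10, 10, 10)))
  s_a <- select_vessel_seeds(m2, v2)
  s_b <- select_vessel_seeds(m2, v2)
  expect_identical(s_a$points, s_b$points)
  expect_error(select_vessel_seeds(array(FALSE, c(4, 4, 4)), v2), "empty")
})

test_that("the Gaussian vessel model uses the n-1 sample deviation", {
  v <- volume(array(c(90, 110, 0, 0), c(4, 1, 1)))
  m <- array(FALSE, c(4, 1, 1)); m[1:2, 1, 1] <- TRUE
  fit <- estimate_vessel_model(v, m)
  expect_equal(fit$mu, 100)
  expect_equal(fit$sigma, sqrt(200), tolerance = 1e-9) # 14.142...
  expect_identical(fit$n, 2L)
  set.seed(42)
  big <- volume(array(stats::rnorm(1e4, 300, 20), c(100, 100, 1)))
  fit2 <- estimate_vessel_model(big, array(TRUE, c(100, 100, 1)))
  expect_lt(abs(fit2$mu - 300), 1)
  expect_lt(abs(fit2$sigma - 20), 1)
  m1 <- array(FALSE, c(4, 1, 1)); m1[1, 1, 1] <- TRUE
  expect_error(estimate_vessel_model(v, m1), "2 voxels")
})

test_that("automatic vessel segmentation recovers an in-band tube", {
  set.seed(9)
  d <- c(48, 48, 48)
  a <- array(pmax(stats::rnorm(prod(d), 50, 5), 0), d)
  tube <- array(FALSE, d); tube[20:28, 20:28, 5:43] <- TRUE
  a[tube] <- stats::rnorm(sum(tube), 300, 20)
  v <- volume(a)
  mask <- segment_vessels(v)
  model <- attr(mask, "model")
  in_band <- tube & a >= model$mu - model$sigma & a <= model$mu + model$sigma
  expect_gt(sum(mask & in_band) / sum(in_band), 0.9)
  # all segmented voxels lie inside [mu - sigma, mu + sigma]
  expect_true(all(a[mask] >= model$mu - model$sigma &
                    a[mask] <= model$mu + model$sigma))
  # constant-intensity tube floors sigma with a warning but still segments
  a2 <- array(0, d); a2[tube] <- 300
  expect_warning(m2 <- segment_vessels(volume(a2), background_value = 10),
                 "floored")
  expect_identical(unname(which(m2)), unname(which(tube)))
  expect_error(segment_vessels(volume(array(1, c(4, 4, 4))),
                               background_value = 2), "empty foreground")
})

test_that("surface extraction produces watertight, accurately sized meshes", {
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  mesh <- extract_mesh(m1, smooth_iters = 0)
  V <- nrow(mesh$vertices); F <- nrow(mesh$faces)
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2)) # watertight: every edge in 2 faces
  E <- length(unique(key))
  expect_identical(V - E + F, 2L) # Euler characteristic of a sphere
  # digitized ball measures close to the analytic sphere area
  ball <- ball_mask(24, 8)
  area <- mesh_area(extract_mesh(ball))
  expect_lt(abs(area - 4 * pi * 64) / (4 * pi * 64), 0.15)
  expect_error(extract_mesh(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("VOI dilation uses the exact Euclidean ball", {
  one <- array(FALSE, c(25, 25, 25)); one[13, 13, 13] <- TRUE
  voi <- dilate_voi(one, 10)
  expect_identical(sum(voi$mask), as.integer(cpp_ball_count(10)))
  expect_identical(dilate_voi(one, 0)$mask, one)
  # composition bound: r then s is contained in r + s
  r2 <- dilate_voi(dilate_voi(one, 3)$mask, 4)$mask
  r6 <- dilate_voi(one, 7)$mask
  expect_true(all(!r2 | r6))
  expect_true(all(!one | dilate_voi(one, 5)$mask)) # VOI contains its source
  expect_error(dilate_voi(one, -1), "radius")
})

test_that("coverage fraction counts lesion voxels inside the VOI", {
  voi <- array(FALSE, c(10, 10, 10)); voi[1:5, , ] <- TRUE
  an <- array(FALSE, c(10, 10, 10)); an[4:5, 1, 1] <- TRUE
  expect_equal(coverage_fraction(voi, an), 1.0)
  an2 <- array(FALSE, c(10, 10, 10)); an2[8:9, 1, 1] <- TRUE
  expect_equal(coverage_fraction(voi, an2), 0.0)
  an3 <- array(FALSE, c(10, 10, 10)); an3[3:7, 1:2, 1] <- TRUE # 3 of 10 in
  expect_equal(coverage_fraction(voi, an3), 0.6)
  an4 <- array(FALSE, c(10, 10, 10)); an4[3:5, 1, 1] <- TRUE
  an4[6, 2:8, 1] <- TRUE # 3 of 10 inside
  expect_equal(coverage_fraction(voi, an4), 0.3)
  expect_error(coverage_fraction(voi, array(FALSE, c(10, 10, 10))), "empty")
  expect_error(coverage_fraction(voi, an[1:5, , ]), "grids")
})
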