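make_pair <- function(seed = 1, n = 10) {
  set.seed(seed)
  img <- volume(array(stats::runif(n^3, 0, 100), rep(n, 3)))
  lab <- array(0L, rep(n, 3))
  lab[3:4, 3:4, 3:4] <- 1L
  lab[n - 1, n - 1, n - 1] <- 2L
  list(image = img, labels = label_volume(lab))
}

test_that("transverse flip reflects the slice axis and is an involution", {
  p <- make_pair()
  f <- flip_transverse(p$image)
  n <- dim(p$image)[3]
  for (z in c(1, 4, n)) # (x, y, z) -> (x, y, Z + 1 - z)
    expect_equal(f[, , z], unclass(p$image)[, , n + 1 - z],
                 ignore_attr = TRUE)
  expect_identical(as.vector(flip_transverse(f)), as.vector(p$image))
  half <- array(stats::runif(2 * 2 * 5), c(2, 2, 5))
  symv <- volume(array(c(half, half[, , 5:1]), c(2, 2, 10)))
  expect_identical(as.vector(flip_transverse(symv)), as.vector(symv))
})

test_that("discrete Gaussian smoothing is normalized and well-behaved", {
  const <- volume(array(3.5, c(8, 8, 8)))
  expect_lt(max(abs(discrete_gaussian(const) - 3.5)), 1e-6)
  imp <- array(0, c(33, 33, 33)); imp[17, 17, 17] <- 1
  sm <- discrete_gaussian(volume(imp), variance = 4, max_kernel_width = 32)
  expect_lt(abs(sum(sm) - 1), 1e-6) # impulse response sums to one
  v <- rand_volume(c(6, 6, 6), seed = 8)
  expect_identical(as.vector(discrete_gaussian(v, variance = 0)),
                   as.vector(v))
  expect_error(discrete_gaussian(v, variance = -1), "variance")
})

test_that("augmentation emits the full 2^3 factorial with unique tags", {
  p <- make_pair()
  av <- augment_variants(p)
  expect_identical(length(av$items), 8L)
  expect_identical(length(unique(av$provenance)), 8L)
  expect_true("identity" %in% av$provenance)
  id <- av$items[[which(av$provenance == "identity")]]
  expect_identical(as.vector(id$image), as.vector(p$image))
  # labels only ever undergo the flip
  for (j in seq_along(av$items)) {
    lab <- av$items[[j]]$labels
    src <- if (grepl("flip", av$provenance[j]))
      flip_transverse(p$labels) else p$labels
    expect_identical(as.vector(lab), as.vector(src))
  }
  # aneurysm component count is preserved by every variant
  n_comp <- function(lv) {
    an <- array(as.vector(lv) == 2L, dim(lv))
    max(cpp_label_components(as.vector(an), dim(lv), 26L))
  }
  expect_true(all(vapply(av$items, function(it) n_comp(it$labels), 0L) ==
                    n_comp(p$labels)))
})

test_that("augmenting n pairs yields exactly 8n items", {
  pairs <- lapply(1:3, make_pair, n = 6)
  out <- augment_set(pairs)
  expect_identical(length(out$items), 24L)
  expect_identical(length(augment_set(list())$items), 0L)
})

test_that("the sphere radius rule reconciles the two stated constraints", {
  expect_identical(annotation_radius(128), 4L) # max(4, ceil(3.84))
  expect_identical(annotation_radius(32), 4L)
  expect_identical(annotation_radius(200), 6L)
  expect_gt(annotation_radius(128), 3L)
})

test_that("annotations become fixed-radius spheres at component centroids", {
  d <- c(128, 128, 128)
  lab <- array(0L, d)
  lab[64, 64, 64] <- 2L
  lv <- label_volume(lab)
  sph <- annotation_to_sphere(lv, axis_length = 128)
  expect_identical(attr(sph, "radius"), 4L)
  expect_identical(unname(attr(sph, "centers")[1, ]), c(64L, 64L, 64L))
  expect_identical(sum(sph == 2L), as.integer(cpp_ball_count(4)))
  # two disjoint annotations become two spheres of the same radius
  lab2 <- array(0L, c(64, 64, 64))
  lab2[16, 16, 16] <- 2L; lab2[48, 48, 48] <- 2L
  sph2 <- annotation_to_sphere(label_volume(lab2), axis_length = 128)
  comp <- cpp_label_components(as.vector(sph2 == 2L), dim(sph2), 26L)
  expect_identical(max(comp), 2L)
  # a corner annotation is clipped, center unchanged
  lab3 <- array(0L, c(32, 32, 32)); lab3[1, 1, 1] <- 2L
  sph3 <- annotation_to_sphere(label_volume(lab3), axis_length = 128)
  expect_identical(unname(attr(sph3, "centers")[1, ]), c(1L, 1L, 1L))
  expect_lt(sum(sph3 == 2L), cpp_ball_count(4))
  expect_true(sph3[1, 1, 1] == 2L)
  expect_error(annotation_to_sphere(label_volume(array(0L, c(8, 8, 8)))),
               "aneurysm")
})

test_that("block preparation yields exact cubes without new labels", {
  p <- make_pair(n = 20)
  b <- prepare_block(p, size = 16)
  expect_identical(dim(b$image), rep(16L, 3))
  expect_identical(dim(b$labels), rep(16L, 3))
  expect_true(all(unique(as.vector(b$labels)) %in%
                    unique(as.vector(p$labels))))
  expect_error(prepare_block(p, size = 4), ">= 8")
  # the identity variant of augmentation leaves a prepared block unchanged
  av <- augment_variants(b)
  id <- av$items[[which(av$provenance == "identity")]]
  expect_identical(as.vector(id$image), as.vector(b$image))
  expect_identical(as.vector(id$labels), as.vector(b$labels))
})
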