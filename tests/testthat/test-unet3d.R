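tiny_cfg <- function() network_config(input_size = 8L, depth = 2L,
                                      base_filters = 2L,
                                      deep_supervision_levels = 0L)

test_that("network configuration enforces divisibility and head limits", {
  expect_error(network_config(input_size = 30, depth = 3), "divisible")
  expect_error(network_config(input_size = 32, depth = 3,
                              deep_supervision_levels = 2), "deep_supervision")
  cfg <- network_config(input_size = 32, depth = 3, base_filters = 4)
  expect_identical(cfg$deep_supervision_levels, 1L)
})

test_that("initialization is deterministic and the forward shape contract holds", {
  cfg <- network_config(input_size = 32, depth = 3, base_filters = 4)
  m1 <- build_network(cfg, seed = 7)
  m2 <- build_network(cfg, seed = 7)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_network(cfg, seed = 8)
  expect_false(identical(m1$weights, m3$weights))
  fw <- mracad:::unet_forward(m1, array(0, rep(32, 3)))
  expect_identical(dim(fw$logits), c(32L, 32L, 32L, 2L))
  expect_identical(dim(fw$probs), rep(32L, 3))
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  # evaluation is deterministic given weights and input
  set.seed(1)
  x <- array(stats::runif(32^3), rep(32, 3))
  expect_identical(mracad:::unet_forward(m1, x)$probs,
                   mracad:::unet_forward(m1, x)$probs)
  # one auxiliary supervision head exists per configured level
  expect_identical(sum(grepl("^seg[0-9]+_w$", names(m1$weights))),
                   1L + cfg$deep_supervision_levels)
})

test_that("analytic gradients match finite differences", {
  m <- build_network(tiny_cfg(), seed = 42)
  set.seed(7)
  x <- array(stats::runif(8^3), rep(8, 3))
  y <- array(0L, rep(8, 3)); y[3:5, 3:5, 3:5] <- 1L
  fw <- mracad:::unet_forward(m, x, keep_cache = TRUE)
  ls <- mracad:::unet_loss(fw$logits, y)
  G <- mracad:::unet_backward(m, fw$cache, ls$grad)
  lossfun <- function(W) {
    mm <- m; mm$weights <- W
    mracad:::unet_loss(mracad:::unet_forward(mm, x)$logits, y)$loss
  }
  eps <- 1e-6
  set.seed(3)
  for (k in c("in_w", "ctx1_w1", "ctx2_w2", "down2_w", "up1_w", "loc1_w1",
              "loc1_w2", "seg1_w", "seg1_b")) {
    for (i in sample(length(m$weights[[k]]), min(3, length(m$weights[[k]])))) {
      Wp <- m$weights; Wp[[k]][i] <- Wp[[k]][i] + eps
      Wm <- m$weights; Wm[[k]][i] <- Wm[[k]][i] - eps
      num <- (lossfun(Wp) - lossfun(Wm)) / (2 * eps)
      expect_lt(abs(num - G[[k]][i]) / max(1e-6, abs(num) + abs(G[[k]][i])),
                1e-4)
    }
  }
})

test_that("training degrades gracefully on degenerate inputs", {
  m <- build_network(tiny_cfg(), seed = 1)
  expect_error(train_network(m, list()), "empty")
  img <- volume(array(stats::runif(8^3), rep(8, 3)))
  all_bg <- label_volume(array(0L, rep(8, 3)))
  expect_error(train_network(m, list(list(image = img, labels = all_bg))),
               "degenerate")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("a tiny block is learnable and early stopping respects patience", {
  set.seed(21)
  img <- array(stats::runif(8^3, 0, 0.2), rep(8, 3))
  lab <- array(0L, rep(8, 3))
  lab[3:6, 3:6, 3:6] <- 1L
  img[lab == 1L] <- img[lab == 1L] + 0.8
  pair <- list(image = volume(img),
               labels = label_volume(2L * lab)) # foreground = aneurysm label
  m <- build_network(tiny_cfg(), seed = 2)
  tc <- train_config(learning_rate = 5e-3, max_epochs = 60L,
                     early_stop_patience = 60L, rng_seed = 1)
  mt <- train_network(m, list(pair), tc)
  expect_lt(min(mt$history$train_loss),
            0.5 * mt$history$train_loss[1]) # loss halves on the toy task
  # plateaued training stops before max_epochs under a small patience
  tc3 <- train_config(learning_rate = 1e-12, max_epochs = 50L,
                      early_stop_patience = 5L, rng_seed = 1)
  mp <- train_network(m, list(pair), tc3)
  expect_lt(nrow(mp$history), 50L)
})

test_that("prediction masks likelihoods outside the VOI", {
  cfg <- network_config(input_size = 16, depth = 2, base_filters = 2,
                        deep_supervision_levels = 0)
  m <- build_network(cfg, seed = 3)
  v <- rand_volume(rep(16, 3), seed = 5)
  p_free <- predict_likelihood(m, v)
  expect_true(all(p_free >= 0 & p_free <= 1))
  none <- dilate_voi(array(FALSE, rep(16, 3)), 0)
  p0 <- predict_likelihood(m, v, none)
  expect_true(all(p0 == 0))
  half <- array(FALSE, rep(16, 3)); half[1:8, , ] <- TRUE
  ph <- predict_likelihood(m, v, half)
  expect_true(all(ph[9:16, , ] == 0))
  expect_identical(as.vector(ph[1:8, , ]), as.vector(p_free[1:8, , ]))
  expect_error(predict_likelihood(m, rand_volume(rep(8, 3))), "input size")
})

test_that("model checkpoints round-trip through disk", {
  m <- build_network(tiny_cfg(), seed = 9)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  r <- load_model(f)
  expect_identical(r$weights, m$weights)
  expect_identical(r$config, m$config)
  saveRDS(1:3, f)
  expect_error(load_model(f), "checkpoint")
})
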