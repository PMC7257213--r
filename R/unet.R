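#' Detection network configuration
#'
#' Topology of the improved 3D U-Net used for per-voxel aneurysm detection:
#' an encoder of residual context blocks, a context aggregation (decoder)
#' pathway with skip connections, and deep supervision heads whose upsampled
#' segmentation maps are summed into the output. The full-scale topology uses
#' 128-voxel blocks with 16 base filters; a 32-voxel / 4-filter scale runs on
#' CPU in minutes and is used throughout the test suite.
#'
#' @param input_size voxels per axis of the cubic input block; must be
#'   divisible by `2^depth`.
#' @param depth number of encoder levels (>= 2); `depth - 1` downsamplings.
#' @param base_filters filters at the first level; doubled per level.
#' @param deep_supervision_levels number of auxiliary supervision heads;
#'   at most `depth - 2`.
#' @param n_classes output classes (2: vessel-background vs aneurysm).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 128L, depth = 4L, base_filters = 16L,
                           deep_supervision_levels = NULL, n_classes = 2L) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  if (is.null(deep_supervision_levels))
    deep_supervision_levels <- max(0L, min(2L, depth - 2L))
  deep_supervision_levels <- as.integer(deep_supervision_levels)
  if (depth < 2L) stop("`depth` must be >= 2", call. = FALSE)
  if (input_size %% 2L^depth != 0L)
    stop("`input_size` must be divisible by 2^depth", call. = FALSE)
  if (deep_supervision_levels > depth - 2L || deep_supervision_levels < 0L)
    stop("`deep_supervision_levels` must be in [0, depth - 2]", call. = FALSE)
  if (n_classes != 2L) stop("only the 2-class problem is supported",
                            call. = FALSE)
  structure(list(input_size = input_size, depth = depth,
                 base_filters = base_filters,
                 deep_supervision_levels = deep_supervision_levels,
                 n_classes = as.integer(n_classes)),
            class = "network_config")
}

# glorot-uniform initializer for a conv kernel (k,k,k,Cin,Cout)
glorot_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin; fan_out <- k^3 * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(k^3 * cin * cout, -lim, lim), dim = c(k, k, k, cin, cout))
}

#' Build an initialized detection network
#'
#' Allocates all convolution kernels with glorot-uniform initialization under
#' the given seed. The same seed always produces identical weights.
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed for the initializer.
#' @return An object of class `model_state`: list of `weights`, `config`,
#'   `history` (per-epoch losses, filled by [train_network()]) and
#'   `best_epoch`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  F <- config$base_filters * 2L^(seq_len(config$depth) - 1L)
  W <- list()
  W$in_w <- glorot_conv(3, 1, F[1]); W$in_b <- numeric(F[1])
  for (l in seq_len(config$depth)) {
    W[[paste0("ctx", l, "_w1")]] <- glorot_conv(3, F[l], F[l])
    W[[paste0("ctx", l, "_b1")]] <- numeric(F[l])
    W[[paste0("ctx", l, "_w2")]] <- glorot_conv(3, F[l], F[l])
    W[[paste0("ctx", l, "_b2")]] <- numeric(F[l])
    if (l > 1) {
      W[[paste0("down", l, "_w")]] <- glorot_conv(3, F[l - 1], F[l])
      W[[paste0("down", l, "_b")]] <- numeric(F[l])
    }
  }
  for (l in seq_len(config$depth - 1L)) { # decoder levels, top (1) .. deep
    W[[paste0("up", l, "_w")]] <- glorot_conv(3, F[l + 1], F[l])
    W[[paste0("up", l, "_b")]] <- numeric(F[l])
    W[[paste0("loc", l, "_w1")]] <- glorot_conv(3, 2 * F[l], F[l])
    W[[paste0("loc", l, "_b1")]] <- numeric(F[l])
    W[[paste0("loc", l, "_w2")]] <- glorot_conv(1, F[l], F[l])
    W[[paste0("loc", l, "_b2")]] <- numeric(F[l])
  }
  for (l in seq_len(1L + config$deep_supervision_levels)) {
    W[[paste0("seg", l, "_w")]] <- glorot_conv(1, F[l], config$n_classes)
    W[[paste0("seg", l, "_b")]] <- numeric(config$n_classes)
  }
  structure(list(weights = W, config = config, history = NULL,
                 best_epoch = NA_integer_), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  np <- sum(vapply(x$weights, length, 0))
  cat(sprintf(paste0("<model_state> input %d^3, depth %d, base filters %d, ",
                     "%d aux supervision head(s), %s parameters\n"),
              x$config$input_size, x$config$depth, x$config$base_filters,
              x$config$deep_supervision_levels, format(np, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s); best epoch %d\n", nrow(x$history),
                x$best_epoch))
  invisible(x)
}

# keep/restore the global RNG state so model code is seed-hygienic
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# ---- tensor primitives (forward + backward) -------------------------------

LRELU_ALPHA <- 0.01
IN_EPS <- 1e-5

lrelu_fwd <- function(x) {
  pos <- x > 0
  list(y = ifelse(pos, x, LRELU_ALPHA * x), pos = pos)
}
lrelu_bwd <- function(gy, cache) gy * ifelse(cache$pos, 1, LRELU_ALPHA)

# instance norm without affine params; x dim (X,Y,Z,C)
inorm_fwd <- function(x) {
  d <- dim(x); n <- prod(d[1:3])
  m <- matrix(x, nrow = n)
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  sd <- sqrt(colMeans(ctr^2) + IN_EPS)
  y <- sweep(ctr, 2, sd, "/")
  list(y = array(y, dim = d), sd = sd)
}
inorm_bwd <- function(gy, cache) {
  d <- dim(gy); n <- prod(d[1:3])
  g <- matrix(gy, nrow = n)
  y <- matrix(cache$y, nrow = n)
  gm <- colMeans(g)
  gym <- colMeans(g * y)
  gx <- sweep(g, 2, gm) - sweep(y, 2, gym, "*")
  gx <- sweep(gx, 2, cache$sd, "/")
  array(gx, dim = d)
}

conv_fwd <- function(x, w, b, stride = 1L) {
  cpp_conv3d_fwd(x, dim(x), w, b, dim(w)[1], as.integer(stride))
}
conv_bwd <- function(x, w, gy, stride = 1L) {
  cpp_conv3d_bwd(x, dim(x), w, gy, dim(w)[1], as.integer(stride),
                 dim(w)[5])
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# IN -> lrelu -> conv composite used throughout; returns out + cache
nlc_fwd <- function(x, w, b, stride = 1L) {
  i <- inorm_fwd(x)
  a <- lrelu_fwd(i$y)
  y <- conv_fwd(a$y, w, b, stride)
  list(y = y, i = i, a = a, x = a$y)
}
nlc_bwd <- function(g, cache, w, stride = 1L) {
  cb <- conv_bwd(cache$x, w, g, stride)
  ga <- lrelu_bwd(cb$gin, cache$a)
  gx <- inorm_bwd(ga, cache$i)
  list(gx = gx, gw = cb$gw, gb = cb$gb)
}

# ---- full forward / backward ----------------------------------------------

# forward pass; input is a 3D array scaled to the block size.
# returns list(logits, probs, cache) -- cache omitted unless keep_cache.
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  W <- model$weights
  D <- cfg$depth
  dim(x) <- c(dim(x), 1L)
  C <- list() # cache
  # encoder
  e <- vector("list", D)
  y0 <- conv_fwd(x, W$in_w, W$in_b, 1L)
  C$x <- x
  cur <- y0
  for (l in seq_len(D)) {
    if (l > 1) {
      dn <- nlc_fwd(e[[l - 1]], W[[paste0("down", l, "_w")]],
                    W[[paste0("down", l, "_b")]], 2L)
      C[[paste0("down", l)]] <- dn
      cur <- dn$y
    }
    c1 <- nlc_fwd(cur, W[[paste0("ctx", l, "_w1")]],
                  W[[paste0("ctx", l, "_b1")]], 1L)
    c2 <- nlc_fwd(c1$y, W[[paste0("ctx", l, "_w2")]],
                  W[[paste0("ctx", l, "_b2")]], 1L)
    e[[l]] <- cur + c2$y # residual context block
    C[[paste0("ctx", l)]] <- list(c1 = c1, c2 = c2)
  }
  # decoder
  d <- vector("list", D - 1L)
  seg <- list()
  cur <- e[[D]]
  for (l in rev(seq_len(D - 1L))) {
    u <- cpp_upsample2_fwd(cur, dim(cur))
    uc <- nlc_fwd(u, W[[paste0("up", l, "_w")]], W[[paste0("up", l, "_b")]],
                  1L)
    cat_ <- concat4(uc$y, e[[l]])
    l1 <- nlc_fwd(cat_, W[[paste0("loc", l, "_w1")]],
                  W[[paste0("loc", l, "_b1")]], 1L)
    l2 <- nlc_fwd(l1$y, W[[paste0("loc", l, "_w2")]],
                  W[[paste0("loc", l, "_b2")]], 1L)
    d[[l]] <- l2$y
    C[[paste0("dec", l)]] <- list(udim = dim(cur), uc = uc, l1 = l1, l2 = l2,
                                  ncu = dim(uc$y)[4])
    cur <- l2$y
  }
  # deep supervision: aux heads summed into the primary output
  logits <- conv_fwd(d[[1]], W$seg1_w, W$seg1_b, 1L)
  for (j in seq_len(cfg$deep_supervision_levels)) {
    s <- conv_fwd(d[[j + 1]], W[[paste0("seg", j + 1, "_w")]],
                  W[[paste0("seg", j + 1, "_b")]], 1L)
    up <- s
    for (r in seq_len(j)) up <- cpp_upsample2_fwd(up, dim(up))
    logits <- logits + 0.5^j * up
    seg[[j]] <- dim(s)
  }
  zf <- logits[, , , 2] - logits[, , , 1]
  probs <- 1 / (1 + exp(-zf))
  C$e <- e; C$d <- d; C$segdims <- seg
  list(logits = logits, probs = probs, cache = if (keep_cache) C else NULL)
}

# loss and gradient wrt logits; target is a 0/1 3D array (foreground)
unet_loss <- function(logits, target) {
  d <- dim(logits)
  n <- prod(d[1:3])
  zb <- logits[, , , 1]; zf <- logits[, , , 2]
  pf <- 1 / (1 + exp(zb - zf))
  pb <- 1 - pf
  y <- as.numeric(target)
  eps <- 1e-12
  ce <- -mean(y * log(pf + eps) + (1 - y) * log(pb + eps))
  s <- 1e-5
  A <- sum(pf * y); S <- sum(pf) + sum(y) + s
  dice <- 1 - (2 * A + s) / S
  # gradients
  g_ce <- (as.numeric(pf) - y) / n
  dLd_pf <- ((2 * A + s) - 2 * y * S) / S^2
  g_dice <- dLd_pf * as.numeric(pf) * as.numeric(pb)
  gzf <- g_ce + g_dice
  g <- array(0, dim = d)
  g[, , , 2] <- gzf
  g[, , , 1] <- -gzf
  list(loss = ce + dice, ce = ce, dice = dice, grad = g,
       dice_score = (2 * A + s) / S)
}

# full backward pass; returns gradient list matching model$weights
unet_backward <- function(model, C, glogits) {
  cfg <- model$config
  W <- model$weights
  D <- cfg$depth
  G <- lapply(model$weights, function(w) array(0, dim = dim(w) %||% length(w)))
  gd <- vector("list", D - 1L) # grads wrt decoder outputs
  # seg heads
  sb <- conv_bwd(C$d[[1]], W$seg1_w, glogits, 1L)
  G$seg1_w <- sb$gw; G$seg1_b <- sb$gb
  gd[[1]] <- sb$gin
  for (j in seq_len(cfg$deep_supervision_levels)) {
    g <- glogits * 0.5^j
    for (r in seq_len(j)) {
      g <- cpp_upsample2_bwd(g, dim(g))
    }
    sbj <- conv_bwd(C$d[[j + 1]], W[[paste0("seg", j + 1, "_w")]], g, 1L)
    G[[paste0("seg", j + 1, "_w")]] <- sbj$gw
    G[[paste0("seg", j + 1, "_b")]] <- sbj$gb
    gd[[j + 1]] <- sbj$gin
  }
  # decoder, top to deep
  ge <- vector("list", D) # grads wrt encoder outputs
  gcur <- gd[[1]]
  for (l in seq_len(D - 1L)) {
    dc <- C[[paste0("dec", l)]]
    b2 <- nlc_bwd(gcur, dc$l2, W[[paste0("loc", l, "_w2")]], 1L)
    G[[paste0("loc", l, "_w2")]] <- G[[paste0("loc", l, "_w2")]] + b2$gw
    G[[paste0("loc", l, "_b2")]] <- G[[paste0("loc", l, "_b2")]] + b2$gb
    b1 <- nlc_bwd(b2$gx, dc$l1, W[[paste0("loc", l, "_w1")]], 1L)
    G[[paste0("loc", l, "_w1")]] <- G[[paste0("loc", l, "_w1")]] + b1$gw
    G[[paste0("loc", l, "_b1")]] <- G[[paste0("loc", l, "_b1")]] + b1$gb
    ncu <- dc$ncu
    gu <- b1$gx[, , , seq_len(ncu), drop = FALSE]
    gskip <- b1$gx[, , , ncu + seq_len(dim(b1$gx)[4] - ncu), drop = FALSE]
    ge[[l]] <- (ge[[l]] %||% 0) + gskip
    bu <- nlc_bwd(gu, dc$uc, W[[paste0("up", l, "_w")]], 1L)
    G[[paste0("up", l, "_w")]] <- G[[paste0("up", l, "_w")]] + bu$gw
    G[[paste0("up", l, "_b")]] <- G[[paste0("up", l, "_b")]] + bu$gb
    gup <- cpp_upsample2_bwd(bu$gx, dim(bu$gx))
    if (l + 1L <= D - 1L) {
      gd[[l + 1L]] <- (gd[[l + 1L]] %||% 0) + gup
      gcur <- gd[[l + 1L]]
    } else {
      ge[[D]] <- (ge[[D]] %||% 0) + gup
    }
  }
  # encoder, deep to top
  for (l in rev(seq_len(D))) {
    gout <- ge[[l]]
    ctx <- C[[paste0("ctx", l)]]
    # residual: out = cur + c2(c1(cur))
    b2 <- nlc_bwd(gout, ctx$c2, W[[paste0("ctx", l, "_w2")]], 1L)
    G[[paste0("ctx", l, "_w2")]] <- G[[paste0("ctx", l, "_w2")]] + b2$gw
    G[[paste0("ctx", l, "_b2")]] <- G[[paste0("ctx", l, "_b2")]] + b2$gb
    b1 <- nlc_bwd(b2$gx, ctx$c1, W[[paste0("ctx", l, "_w1")]], 1L)
    G[[paste0("ctx", l, "_w1")]] <- G[[paste0("ctx", l, "_w1")]] + b1$gw
    G[[paste0("ctx", l, "_b1")]] <- G[[paste0("ctx", l, "_b1")]] + b1$gb
    gcur <- gout + b1$gx
    if (l > 1) {
      dn <- C[[paste0("down", l)]]
      bd <- nlc_bwd(gcur, dn, W[[paste0("down", l, "_w")]], 2L)
      G[[paste0("down", l, "_w")]] <- G[[paste0("down", l, "_w")]] + bd$gw
      G[[paste0("down", l, "_b")]] <- G[[paste0("down", l, "_b")]] + bd$gb
      ge[[l - 1]] <- (ge[[l - 1]] %||% 0) + bd$gx
    } else {
      cb <- conv_bwd(C$x, W$in_w, gcur, 1L)
      G$in_w <- G$in_w + cb$gw
      G$in_b <- G$in_b + cb$gb
    }
  }
  G
}

#' Training configuration
#'
#' @param batch_size fixed at 1 block per gradient step.
#' @param learning_rate Adam step size (default 5e-4).
#' @param max_epochs training epoch cap.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param val_fraction fraction of blocks held out for validation (when at
#'   least 10 blocks are available; otherwise the training loss is monitored).
#' @param rng_seed seed for shuffling and the validation split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 1L, learning_rate = 5e-4,
                         max_epochs = 200L, early_stop_patience = 10L,
                         val_fraction = 0.1, rng_seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (as.integer(batch_size) < 1L) stop("`batch_size` must be >= 1",
                                        call. = FALSE)
  if (as.integer(batch_size) != 1L)
    stop("only batch_size = 1 is implemented", call. = FALSE)
  structure(list(batch_size = 1L, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 rng_seed = as.integer(rng_seed)), class = "train_config")
}

# extract (input array, target array) from an item pair at network scale
block_to_training_pair <- function(item, config) {
  s <- config$input_size
  img <- item$image
  if (!all(dim(img) == s)) {
    b <- prepare_block(item, size = s,
                       background_threshold = stats::median(as.numeric(img)))
    img <- b$image; lab <- b$labels
  } else lab <- item$labels
  x <- array(as.numeric(img), dim = dim(img))
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng) # unit-range input
  y <- array(as.integer(as.vector(lab) == label_legend(lab)[["aneurysm"]]),
             dim = dim(lab))
  list(x = x, y = y)
}

#' Train the detection network
#'
#' Adam optimization (batch size 1) of the deep-supervision loss: the sum of
#' voxelwise cross-entropy and soft-Dice on the aneurysm class, computed on
#' the summed multi-scale output. Stops at `max_epochs` or after
#' `early_stop_patience` epochs without improvement of the monitored loss,
#' and returns the best-epoch weights.
#'
#' @param model a [build_network()] result.
#' @param data an `augmented_set` (or plain list) of `image`/`labels` pairs;
#'   at least one block must contain both classes.
#' @param tconf a [train_config()].
#' @param verbose print per-epoch losses.
#' @return The trained `model_state`, with `history` (data.frame of epoch,
#'   train_loss, val_loss) and `best_epoch` filled in.
#' @export
train_network <- function(model, data, tconf = train_config(),
                          verbose = FALSE) {
  items <- if (inherits(data, "augmented_set")) data$items else data
  if (length(items) == 0) stop("empty training set", call. = FALSE)
  cfg <- model$config
  pairs <- lapply(items, block_to_training_pair, config = cfg)
  has_fg <- vapply(pairs, function(p) any(p$y == 1L), TRUE)
  has_bg <- vapply(pairs, function(p) any(p$y == 0L), TRUE)
  if (!any(has_fg) || !any(has_bg))
    stop("degenerate labels: both classes must be present in the data",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tconf$rng_seed)
  n <- length(pairs)
  if (n >= 10 && tconf$val_fraction > 0) {
    nval <- max(1L, floor(tconf$val_fraction * n))
    val_idx <- sample.int(n, nval)
  } else val_idx <- integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  W <- model$weights
  mom <- lapply(W, function(w) w * 0)
  vel <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0
  hist <- NULL
  best <- Inf; best_w <- W; best_epoch <- NA_integer_; wait <- 0
  for (epoch in seq_len(tconf$max_epochs)) {
    tl <- 0
    for (i in sample(tr_idx)) {
      fw <- unet_forward(list(weights = W, config = cfg), pairs[[i]]$x,
                         keep_cache = TRUE)
      ls <- unet_loss(fw$logits, pairs[[i]]$y)
      G <- unet_backward(list(weights = W, config = cfg), fw$cache, ls$grad)
      t <- t + 1
      for (k in names(W)) {
        mom[[k]] <- b1 * mom[[k]] + (1 - b1) * G[[k]]
        vel[[k]] <- b2 * vel[[k]] + (1 - b2) * G[[k]]^2
        mhat <- mom[[k]] / (1 - b1^t)
        vhat <- vel[[k]] / (1 - b2^t)
        W[[k]] <- W[[k]] - tconf$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      tl <- tl + ls$loss
    }
    tl <- tl / length(tr_idx)
    vl <- if (length(val_idx)) {
      mean(vapply(val_idx, function(i) {
        fw <- unet_forward(list(weights = W, config = cfg), pairs[[i]]$x)
        unet_loss(fw$logits, pairs[[i]]$y)$loss
      }, 0))
    } else tl
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tl,
                                 vl))
    if (vl < best - 1e-6) {
      best <- vl; best_w <- W; best_epoch <- epoch; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= tconf$early_stop_patience) break
    }
  }
  model$weights <- best_w
  model$history <- hist
  model$best_epoch <- best_epoch
  model
}

#' Per-voxel aneurysm likelihood
#'
#' Runs the forward pass on a block-shaped volume and returns the softmax
#' aneurysm-class probability per voxel, forced to zero outside the VOI.
#'
#' @param model a trained `model_state`.
#' @param v a [volume()] with shape `config$input_size^3` (the caller
#'   resamples; see [prepare_block()]).
#' @param voi a [dilate_voi()] result or logical mask on the same grid, or
#'   `NULL` for no masking.
#' @return A [volume()] of probabilities in `[0, 1]` (class attribute
#'   `likelihood`).
#' @export
predict_likelihood <- function(model, v, voi = NULL) {
  cfg <- model$config
  if (!all(dim(v) == cfg$input_size))
    stop("volume shape does not match the network input size", call. = FALSE)
  x <- array(as.numeric(v), dim = dim(v))
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  fw <- unet_forward(model, x)
  p <- fw$probs
  if (!is.null(voi)) {
    m <- if (inherits(voi, "voi")) voi$mask else voi
    if (!identical(dim(m), dim(p)))
      stop("VOI grid does not match the prediction grid", call. = FALSE)
    p[!m] <- 0
  }
  out <- vol_like(p, v)
  class(out) <- c("likelihood", class(out))
  out
}

#' Save / load a trained model
#'
#' The checkpoint is a single serialized file embedding the weights, the
#' [network_config()] and the training history.
#'
#' @param model a `model_state`.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "model_state")) stop("not a model checkpoint", call. = FALSE)
  m
}
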