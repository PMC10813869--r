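#' Training configuration
#'
#' Hyperparameters of the alternating adversarial training loop. Defaults
#' follow common practice for least-squares GANs (Adam with
#' `lr = 2e-4`, `beta = (0.5, 0.999)`, one discriminator update per
#' generator update); the source study reports only that Adam was used.
#' `learning_rate = 0` is permitted as a degenerate configuration for
#' testing (parameters then stay fixed).
#'
#' @param learning_rate Adam step size (>= 0).
#' @param beta1,beta2 Adam moment decays in `[0, 1)`.
#' @param steps Total generator updates (>= 1).
#' @param batch_size Patch pairs per update.
#' @param d_updates_per_g Discriminator updates per generator update (>= 1).
#' @param weights A [loss_weights()].
#' @param patch_stride RL stride for sampling aligned patch starts
#'   (default: the patch side, i.e. non-overlapping starts).
#' @param seed Master seed for batching; all training randomness derives
#'   from it.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         steps = 100L, batch_size = 1L, d_updates_per_g = 1L,
                         weights = loss_weights(), patch_stride = NULL,
                         seed = 1L) {
  if (learning_rate < 0) stop("train_config: learning_rate must be >= 0", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("train_config: betas must lie in [0, 1)", call. = FALSE)
  }
  if (steps < 1) stop("train_config: steps must be >= 1", call. = FALSE)
  if (d_updates_per_g < 1) stop("train_config: d_updates_per_g must be >= 1", call. = FALSE)
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, as.list(weights))
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 steps = as.integer(steps), batch_size = as.integer(batch_size),
                 d_updates_per_g = as.integer(d_updates_per_g),
                 weights = weights,
                 patch_stride = if (is.null(patch_stride)) NULL else as.integer(patch_stride),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ------------------------------------------------------------- Adam -----

adam_init <- function(params) {
  lapply(params, function(lay) list(
    mw = array(0, dim(lay$w)), vw = array(0, dim(lay$w)),
    mb = numeric(length(lay$b)), vb = numeric(length(lay$b))))
}

adam_step <- function(params, grads, state, t, lr, b1, b2, eps = 1e-8) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (nm in names(params)) {
    st <- state[[nm]]
    g <- grads[[nm]]
    st$mw <- b1 * st$mw + (1 - b1) * g$w
    st$vw <- b2 * st$vw + (1 - b2) * g$w^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w - lr * (st$mw / c1) / (sqrt(st$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

add_grads <- function(a, b, scale = 1) {
  if (is.null(a)) return(lapply(b, function(l) list(w = l$w * scale, b = l$b * scale)))
  for (nm in names(b)) {
    a[[nm]]$w <- a[[nm]]$w + b[[nm]]$w * scale
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b * scale
  }
  a
}

# ------------------------------------------------- cross-validation -----

#' Plan k-fold cross-validation over impacted samples
#'
#' Partitions the impacted sample ids into `k` maximally even groups in a
#' seed-deterministic shuffle (74 ids at `k = 15` give fourteen groups of 5
#' and one of 4). Fold `i` tests group `i` and trains on all remaining
#' impacted samples plus every control sample: controls are never held
#' out, they only augment training.
#'
#' @param impacted_ids Vector of impacted-sample ids.
#' @param control_ids Vector of control-sample ids (possibly empty).
#' @param k Number of folds (default 15), `1 <= k <= length(impacted_ids)`.
#' @param seed Shuffle seed.
#' @return A `fold_plan`: list of folds, each `list(train_ids, test_ids)`,
#'   with attribute `n_folds`.
#' @examples
#' fp <- make_cv_folds(1:74, 75:123, k = 15, seed = 1)
#' table(lengths(lapply(fp, `[[`, "test_ids")))
#' @export
make_cv_folds <- function(impacted_ids, control_ids = character(), k = 15L,
                          seed = 1L) {
  k <- as.integer(k)
  n <- length(impacted_ids)
  if (k < 1) stop("make_cv_folds: k must be >= 1", call. = FALSE)
  if (k > n) stop("make_cv_folds: k exceeds the number of impacted samples", call. = FALSE)
  shuffled <- with_seed(seed, sample(impacted_ids))
  base <- n %/% k
  rem <- n %% k
  sizes <- c(rep(base + 1L, rem), rep(base, k - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) {
    test <- shuffled[starts[i]:ends[i]]
    list(train_ids = c(setdiff(shuffled, test), control_ids),
         test_ids = test)
  })
  structure(folds, class = "fold_plan", n_folds = k)
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "test_ids"))
  cat(sprintf("<fold_plan> %d folds, test group sizes: %s\n",
              attr(x, "n_folds"), paste(sizes, collapse = " ")))
  invisible(x)
}

# ------------------------------------------------------- training -------

# Normalize a dataset entry into list(pan = matrix, vol = array).
as_training_pair <- function(s) {
  if (inherits(s, "phantom_sample")) {
    list(pan = pan_data(normalize_intensity(s$panoramic)),
         vol = vol_data(normalize_intensity(s$volume)))
  } else if (is.list(s) && !is.null(s$pan) && !is.null(s$vol)) {
    pan <- if (inherits(s$pan, "panoramic")) s$pan else panoramic(s$pan)
    vol <- if (inherits(s$vol, "volume3d")) s$vol else volume3d(s$vol)
    list(pan = pan_data(normalize_intensity(pan)),
         vol = vol_data(normalize_intensity(vol)))
  } else {
    stop("train: dataset entries must be phantom_sample or list(pan, vol)", call. = FALSE)
  }
}

# Extract the aligned (2D, 3D) patch pair starting at 0-based RL index st.
aligned_patch_pair <- function(pair, st, p) {
  n <- nrow(pair$pan)
  w <- min(p, n - st)
  xp <- matrix(0, p, p)
  xp[seq_len(w), ] <- pair$pan[st + seq_len(w), , drop = FALSE]
  yp <- array(0, c(p, p, p))
  yp[seq_len(w), , ] <- pair$vol[st + seq_len(w), , , drop = FALSE]
  list(x = xp, y = yp)
}

check_finite_loss <- function(value, component, step) {
  if (!is.finite(value)) {
    stop(sprintf("train: non-finite %s loss at step %d", component, step),
         call. = FALSE)
  }
  value
}

#' Train the 2D-to-3D generator adversarially
#'
#' Alternates `d_updates_per_g` least-squares discriminator updates with
#' one generator update per step. Each update samples aligned 2D/3D patch
#' pairs (same RL start) from the dataset; inputs are intensity-normalized
#' to `[-1, 1]`. All randomness derives from `train_cfg$seed`, so repeat
#' runs are bit-identical on a single-threaded BLAS. Training aborts with a
#' diagnostic naming the offending loss component and step if any loss
#' becomes non-finite.
#'
#' @param dataset Non-empty list of `phantom_sample` objects or
#'   `list(pan, vol)` pairs. The dataset is not modified.
#' @param gen_cfg,disc_cfg [generator_config()] for generator and
#'   discriminator (usually the same object).
#' @param train_cfg A [train_config()].
#' @return List with `generator`, `discriminator` (trained networks), and
#'   `history` (data.frame: one row per generator step with every loss
#'   component).
#' @export
train <- function(dataset, gen_cfg, disc_cfg = gen_cfg, train_cfg = train_config()) {
  if (length(dataset) == 0) stop("train: dataset is empty", call. = FALSE)
  stopifnot(inherits(gen_cfg, "generator_config"),
            inherits(disc_cfg, "generator_config"),
            inherits(train_cfg, "train_config"))
  if (disc_cfg$patch_side != gen_cfg$patch_side) {
    stop("train: generator and discriminator patch sides differ", call. = FALSE)
  }
  p <- gen_cfg$patch_side
  pairs <- lapply(dataset, as_training_pair)
  for (pr in pairs) {
    if (ncol(pr$pan) != p || dim(pr$vol)[2] != p) {
      stop(sprintf("train: sample height must equal patch side %d", p), call. = FALSE)
    }
  }
  stride <- train_cfg$patch_stride %||% p
  starts_per <- lapply(pairs, function(pr) patch_starts(nrow(pr$pan), stride))

  gen <- build_generator(gen_cfg)
  disc <- build_discriminator(disc_cfg)
  w <- train_cfg$weights
  adv_on <- w$lambda1 > 0

  hist_cols <- c("step", "loss_d", "loss_g_adv", "loss_voxel",
                 "loss_projection", "loss_g_total")
  history <- matrix(NA_real_, train_cfg$steps, length(hist_cols),
                    dimnames = list(NULL, hist_cols))

  g_state <- adam_init(gen$params)
  d_state <- adam_init(disc$params)
  d_t <- 0L

  with_seed(train_cfg$seed, {
    for (step in seq_len(train_cfg$steps)) {
      draw_batch <- function() {
        idx <- sample.int(length(pairs), train_cfg$batch_size, replace = TRUE)
        lapply(idx, function(i) {
          st <- starts_per[[i]][sample.int(length(starts_per[[i]]), 1L)]
          aligned_patch_pair(pairs[[i]], st, p)
        })
      }

      # With lambda1 = 0 the adversarial term is absent from the generator
      # objective, so discriminator updates cannot influence the result;
      # training reduces to supervised regression and skips them.
      loss_d_val <- NA_real_
      for (du in if (adv_on) seq_len(train_cfg$d_updates_per_g) else integer()) {
        batch <- draw_batch()
        d_grads <- NULL
        loss_d_val <- 0
        for (b in batch) {
          fake <- generator_forward(gen, b$x)
          fr <- discriminator_forward(disc, b$y, keep_cache = TRUE)
          ff <- discriminator_forward(disc, fake, keep_cache = TRUE)
          loss_d_val <- loss_d_val +
            loss_discriminator(fr$s, ff$s) / length(batch)
          nel <- length(fr$s)
          gsr <- 2 * (fr$s - 1) / (nel * length(batch))
          gsf <- 2 * ff$s / (nel * length(batch))
          d_grads <- add_grads(d_grads,
                               discriminator_backward(disc, fr$cache, gsr)$grads)
          d_grads <- add_grads(d_grads,
                               discriminator_backward(disc, ff$cache, gsf)$grads)
        }
        check_finite_loss(loss_d_val, "discriminator", step)
        d_t <- d_t + 1L
        upd <- adam_step(disc$params, d_grads, d_state, d_t,
                         train_cfg$learning_rate, train_cfg$beta1, train_cfg$beta2)
        disc$params <- upd$params
        d_state <- upd$state
      }

      batch <- draw_batch()
      g_grads <- NULL
      comp <- c(adv = 0, voxel = 0, projection = 0, total = 0)
      for (b in batch) {
        fw <- generator_forward(gen, b$x, keep_cache = TRUE)
        gx_hat <- fw$y
        nvox <- length(gx_hat)
        gout <- w$lambda2 * 2 * (gx_hat - b$y) / nvox
        gout <- gout + w$lambda3 * projection_loss_grad(b$y, gx_hat)
        adv <- 0
        if (adv_on) {
          df <- discriminator_forward(disc, gx_hat, keep_cache = TRUE)
          adv <- loss_generator_adv(df$s)
          gs <- 2 * (df$s - 1) / length(df$s)
          gout <- gout + w$lambda1 *
            discriminator_backward(disc, df$cache, gs, need_gx = TRUE)$gx
        }
        vox <- loss_voxel(b$y, gx_hat)
        proj <- loss_projection(b$y, gx_hat)
        comp <- comp + c(adv, vox, proj,
                         w$lambda1 * adv + w$lambda2 * vox + w$lambda3 * proj) /
          length(batch)
        g_grads <- add_grads(g_grads,
                             generator_backward(gen, fw$cache, gout),
                             scale = 1)
      }
      if (length(batch) > 1) {
        g_grads <- lapply(g_grads, function(l) list(w = l$w / length(batch),
                                                    b = l$b / length(batch)))
      }
      check_finite_loss(comp[["adv"]], "generator adversarial", step)
      check_finite_loss(comp[["voxel"]], "voxel", step)
      check_finite_loss(comp[["projection"]], "projection", step)
      upd <- adam_step(gen$params, g_grads, g_state, step,
                       train_cfg$learning_rate, train_cfg$beta1, train_cfg$beta2)
      gen$params <- upd$params
      g_state <- upd$state

      history[step, ] <- c(step, loss_d_val, comp[["adv"]], comp[["voxel"]],
                           comp[["projection"]], comp[["total"]])
    }
  })

  gen$forward <- local({ g <- gen; function(x) generator_forward(g, x) })
  disc$forward <- local({ d <- disc; function(v) discriminator_forward(d, v) })
  list(generator = gen, discriminator = disc,
       history = as.data.frame(history))
}

# Gradient of loss_projection w.r.t. the generated patch gx.
projection_loss_grad <- function(y, gx) {
  d <- dim(gx)
  g <- array(0, d)
  for (ax in 1:3) {
    diff <- mean_project(gx, ax) - mean_project(y, ax)
    scale <- (2 / 3) / (length(diff) * d[ax])
    g <- g + scale * broadcast_over_axis(diff, ax, d)
  }
  g
}

# Expand a projected 2D matrix back over the projected axis of a 3D shape.
broadcast_over_axis <- function(m, axis, d) {
  switch(axis,
    aperm(array(m, c(d[2], d[3], d[1])), c(3L, 1L, 2L)),   # m is (ap, is)
    aperm(array(m, c(d[1], d[3], d[2])), c(1L, 3L, 2L)),   # m is (rl, is)
    array(m, d))                                           # m is (rl, ap)
}

#' Reconstruct a full-width volume from a panoramic
#'
#' Slides the generator over the panoramic at the same RL starts as
#' [extract_patches()] (every multiple of `stride` below the width, with
#' zero-padded overhang), maps each 2D patch to a 3D patch, and reassembles
#' with overlap averaging, excluding padded columns. With a perfect
#' generator this inverts [extract_patches()] exactly for any stride.
#'
#' @param pan A [panoramic()] (or matrix) whose height equals the
#'   generator's patch side. Expected on the `[-1, 1]` intensity scale.
#' @param generator A `pan2vol_generator`, or any function mapping a
#'   `P x P` matrix to a `P x P x P` array.
#' @param patch_side Patch side `P`; defaults to the generator's configured
#'   side.
#' @param stride RL start spacing (default `P`).
#' @param spacing_mm Voxel spacing of the output volume.
#' @return A [volume3d()] of shape `(N, P, P)` where `N` is the panoramic
#'   width.
#' @export
reconstruct_volume <- function(pan, generator, patch_side = NULL, stride = NULL,
                               spacing_mm = c(0.3, 0.3, 0.3)) {
  x <- if (inherits(pan, "panoramic")) pan_data(pan) else unclass(pan)
  if (length(dim(x)) != 2) stop("reconstruct_volume: pan must be 2D", call. = FALSE)
  fwd <- if (inherits(generator, "pan2vol_generator")) {
    if (is.null(patch_side)) patch_side <- generator$cfg$patch_side
    function(xp) generator_forward(generator, xp)
  } else if (is.function(generator)) {
    if (is.null(patch_side)) stop("reconstruct_volume: patch_side required with a function generator", call. = FALSE)
    generator
  } else {
    stop("reconstruct_volume: generator must be a pan2vol_generator or a function", call. = FALSE)
  }
  p <- as.integer(patch_side)
  if (ncol(x) != p) {
    stop(sprintf("reconstruct_volume: panoramic height %d must equal patch side %d",
                 ncol(x), p), call. = FALSE)
  }
  if (is.null(stride)) stride <- p
  stride <- as.integer(stride)
  if (stride < 1 || stride > p) stop("reconstruct_volume: need 1 <= stride <= patch_side", call. = FALSE)
  n <- nrow(x)
  starts <- patch_starts(n, stride)
  patches <- vector("list", length(starts))
  valid <- integer(length(starts))
  for (i in seq_along(starts)) {
    st <- starts[i]
    w <- min(p, n - st)
    xp <- matrix(0, p, p)
    xp[seq_len(w), ] <- x[st + seq_len(w), , drop = FALSE]
    yp <- fwd(xp)
    if (!identical(dim(yp), c(p, p, p))) {
      stop("reconstruct_volume: generator returned a patch of the wrong shape", call. = FALSE)
    }
    patches[[i]] <- yp
    valid[i] <- w
  }
  ps <- structure(list(patches = patches, starts = starts, valid_width = valid,
                       source_width = n, patch_side = p, stride = stride,
                       spacing_mm = spacing_mm),
                  class = "patch_set")
  reassemble_patches(ps)
}
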