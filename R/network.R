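#' Network size configuration
#'
#' Shared configuration for the 2D-to-3D generator and the 3D
#' discriminator. `patch_side` is the cubic patch side `P` (a power of two,
#' >= 16); `n_levels` is the number of 2x downsampling stages, constrained
#' so the coarsest grid keeps side >= 2. `base_channels` sets the width of
#' the first stage; deeper stages double it. Initialization is
#' deterministic given `seed`.
#'
#' @param patch_side Patch side `P` (power of two, >= 16).
#' @param base_channels Channels of the first stage (default 8; small
#'   enough to train on one CPU at `P = 32`).
#' @param n_levels Downsampling stages (default 2).
#' @param seed Integer seed for weight initialization.
#' @return A `generator_config` list.
#' @export
generator_config <- function(patch_side = 32L, base_channels = 8L,
                             n_levels = 2L, seed = 1L) {
  p <- as.integer(patch_side)
  if (p < 16 || bitwAnd(p, p - 1L) != 0L) {
    stop("generator_config: patch_side must be a power of two >= 16", call. = FALSE)
  }
  if (base_channels < 1) stop("generator_config: base_channels must be positive", call. = FALSE)
  if (n_levels < 1 || p / 2^n_levels < 2) {
    stop("generator_config: need patch_side / 2^n_levels >= 2", call. = FALSE)
  }
  structure(list(patch_side = p, base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels), seed = as.integer(seed)),
            class = "generator_config")
}

LRELU_SLOPE <- 0.2

init_conv <- function(cin, cout, k, nd, scale = 1) {
  fan_in <- cin * k^nd
  sd <- scale * sqrt(2 / fan_in)
  list(w = matrix(rnorm(fan_in * cout, sd = sd), fan_in, cout),
       b = numeric(cout))
}

lrelu <- function(x) pmax(x, 0) + LRELU_SLOPE * pmin(x, 0)
lrelu_grad <- function(g, y) g * ((y > 0) + LRELU_SLOPE * (y <= 0))

# decoder channel width at resolution P / 2^j
dec_channels <- function(base, j) if (j >= 1) base * 2^(j - 1) else base

#' Lift a 2D feature map to 3D by depth replication
#'
#' The 2D-to-3D connection of the generator: a feature map indexed
#' `(rl, is, channel)` is replicated `depth` times along a new AP axis,
#' giving `(rl, ap, is, channel)`. An all-ones map lifts to an all-ones
#' block.
#'
#' @param x Numeric 3D array `(rl, is, channels)` (a stack of 2D feature
#'   maps), or a matrix (single channel).
#' @param depth Number of AP replicates.
#' @return Numeric 4D array `(rl, depth, is, channels)`.
#' @export
lift_to_3d <- function(x, depth) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  aperm(array(x, c(d[1], d[2], d[3], depth)), c(1L, 4L, 2L, 3L))
}

lift_to_3d_grad <- function(g) {
  # gradient of depth replication: sum over the AP axis
  colSums(aperm(g, c(2L, 1L, 3L, 4L)))
}

upsample3 <- function(x) {
  d <- dim(x)
  i1 <- rep(seq_len(d[1]), each = 2L)
  i2 <- rep(seq_len(d[2]), each = 2L)
  i3 <- rep(seq_len(d[3]), each = 2L)
  x[i1, i2, i3, , drop = FALSE]
}

upsample3_grad <- function(g) {
  d <- dim(g)
  g <- g[seq(1L, d[1], 2L), , , , drop = FALSE] + g[seq(2L, d[1], 2L), , , , drop = FALSE]
  g <- g[, seq(1L, d[2], 2L), , , drop = FALSE] + g[, seq(2L, d[2], 2L), , , drop = FALSE]
  g[, , seq(1L, d[3], 2L), , drop = FALSE] + g[, , seq(2L, d[3], 2L), , drop = FALSE]
}

#' Build the 2D-to-3D generator
#'
#' Encoder-decoder generator mapping a `P x P` panoramic patch to a
#' `P x P x P` volume patch with values in `[-1, 1]`. A 2D convolutional
#' encoder downsamples `n_levels` times; each encoder feature map is lifted
#' to 3D by depth replication; a 3D convolutional decoder upsamples back to
#' full resolution, adding the lifted encoder features as skip links at
#' matching resolutions; a final 3 x 3 x 3 convolution with tanh bounds the
#' output. Weight initialization is deterministic given `cfg$seed` and does
#' not disturb the caller's RNG state.
#'
#' @param cfg A [generator_config()].
#' @return A `pan2vol_generator`: list with `cfg`, `params` (named list of
#'   weight matrices and bias vectors), and `forward(x)` returning the
#'   generated `P x P x P` array for a `P x P` input.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  C <- cfg$base_channels
  L <- cfg$n_levels
  params <- with_seed(cfg$seed, {
    pr <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      pr[[paste0("enc", l)]] <- init_conv(cin, C * 2^(l - 1), 3, 2)
      cin <- C * 2^(l - 1)
    }
    pr$bott <- init_conv(cin, cin, 3, 2)
    pr$dec0 <- init_conv(cin, cin, 3, 3)
    for (m in L:1) {
      cin_m <- if (m == L) C * 2^(L - 1) else dec_channels(C, m)
      pr[[paste0("dec", m)]] <- init_conv(cin_m, dec_channels(C, m - 1), 3, 3)
    }
    pr$out <- init_conv(dec_channels(C, 0), 1L, 3, 3, scale = 0.3)
    pr
  })
  gen <- structure(list(cfg = cfg, params = params, kind = "generator"),
                   class = "pan2vol_generator")
  gen$forward <- function(x) generator_forward(gen, x)
  gen
}

#' Generator forward pass
#'
#' @param gen A `pan2vol_generator` from [build_generator()].
#' @param x Numeric `P x P` matrix (panoramic patch).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return The generated `P x P x P` array, or (with `keep_cache`) a list
#'   `(y, cache)`.
#' @export
generator_forward <- function(gen, x, keep_cache = FALSE) {
  cfg <- gen$cfg
  pr <- gen$params
  P <- cfg$patch_side
  L <- cfg$n_levels
  x <- unclass(x)
  if (!identical(dim(x), c(P, P))) {
    stop(sprintf("generator_forward: input must be %d x %d", P, P), call. = FALSE)
  }
  stop_if_not_finite(x, "generator input")
  h2 <- array(as.numeric(x), c(P, P, 1L))
  enc_in <- vector("list", L)
  e <- vector("list", L)
  for (l in seq_len(L)) {
    enc_in[[l]] <- h2
    lay <- pr[[paste0("enc", l)]]
    h2 <- lrelu(conv2_fw(h2, dim(h2), lay$w, lay$b, 3L, 2L))
    e[[l]] <- h2
  }
  hb <- lrelu(conv2_fw(h2, dim(h2), pr$bott$w, pr$bott$b, 3L, 1L))
  h <- lift_to_3d(hb, dim(hb)[1])
  dec0_in <- h
  h <- lrelu(conv3_fw(h, dim(h), pr$dec0$w, pr$dec0$b, 3L, 1L))
  dec0_out <- if (keep_cache) h else NULL
  stages <- vector("list", L)
  for (m in L:1) {
    up <- upsample3(h)
    lay <- pr[[paste0("dec", m)]]
    hc <- lrelu(conv3_fw(up, dim(up), lay$w, lay$b, 3L, 1L))
    h <- if (m - 1 >= 1) hc + lift_to_3d(e[[m - 1]], dim(hc)[2]) else hc
    stages[[m]] <- if (keep_cache) list(up = up, hc = hc) else NULL
  }
  out_in <- h
  z <- conv3_fw(h, dim(h), pr$out$w, pr$out$b, 3L, 1L)
  y <- tanh(z)
  dim(y) <- c(P, P, P)
  if (!keep_cache) return(y)
  list(y = y,
       cache = list(enc_in = enc_in, e = e, bott_in = e[[L]], hb = hb,
                    dec0_in = dec0_in, dec0_out = dec0_out,
                    stages = stages, out_in = out_in, y = y))
}

# Backpropagate dLoss/dy through the generator; returns grads shaped like
# gen$params.
generator_backward <- function(gen, cache, gy) {
  cfg <- gen$cfg
  pr <- gen$params
  P <- cfg$patch_side
  L <- cfg$n_levels
  grads <- list()
  y <- cache$y
  g <- gy * (1 - y^2)
  dim(g) <- c(P, P, P, 1L)
  bw <- conv3_bw(cache$out_in, dim(cache$out_in), pr$out$w, g, 3L, 1L, TRUE)
  grads$out <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  g_e <- vector("list", L)
  for (m in 1:L) {
    st <- cache$stages[[m]]
    if (m - 1 >= 1) g_e[[m - 1]] <- lift_to_3d_grad(g)
    gc <- lrelu_grad(g, st$hc)
    lay <- pr[[paste0("dec", m)]]
    bw <- conv3_bw(st$up, dim(st$up), lay$w, gc, 3L, 1L, TRUE)
    grads[[paste0("dec", m)]] <- list(w = bw$gw, b = bw$gb)
    g <- upsample3_grad(bw$gx)
  }
  # g is now the gradient at the dec0 output (post-lrelu)
  g <- lrelu_grad(g, cache$dec0_out)
  bw <- conv3_bw(cache$dec0_in, dim(cache$dec0_in), pr$dec0$w, g, 3L, 1L, TRUE)
  grads$dec0 <- list(w = bw$gw, b = bw$gb)
  g_hb <- lift_to_3d_grad(bw$gx)
  g_hb <- lrelu_grad(g_hb, cache$hb)
  bw <- conv2_bw(cache$bott_in, dim(cache$bott_in), pr$bott$w, g_hb, 3L, 1L, TRUE)
  grads$bott <- list(w = bw$gw, b = bw$gb)
  g_e[[L]] <- if (is.null(g_e[[L]])) bw$gx else g_e[[L]] + bw$gx
  for (l in L:1) {
    gl <- lrelu_grad(g_e[[l]], cache$e[[l]])
    lay <- pr[[paste0("enc", l)]]
    bw <- conv2_bw(cache$enc_in[[l]], dim(cache$enc_in[[l]]), lay$w, gl,
                   3L, 2L, l > 1)
    grads[[paste0("enc", l)]] <- list(w = bw$gw, b = bw$gb)
    if (l > 1) g_e[[l - 1]] <- g_e[[l - 1]] + bw$gx
  }
  grads
}

#' Build the 3D patch discriminator
#'
#' Maps a `P x P x P` volume patch to a coarse 3D grid of unbounded
#' least-squares critic scores via `n_levels` strided 3D convolutions and a
#' final linear 3 x 3 x 3 convolution. The score grid has side
#' `P / 2^n_levels`, strictly smaller than the input on every axis.
#'
#' @param cfg A [generator_config()].
#' @return A `pan2vol_discriminator`: list with `cfg`, `params`, and
#'   `forward(v)` returning the score grid for a `P^3` array.
#' @export
build_discriminator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  C <- cfg$base_channels
  L <- cfg$n_levels
  params <- with_seed(derive_seed(cfg$seed, 7919L), {
    pr <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      pr[[paste0("d", l)]] <- init_conv(cin, C * 2^(l - 1), 3, 3)
      cin <- C * 2^(l - 1)
    }
    pr$score <- init_conv(cin, 1L, 3, 3, scale = 1 / sqrt(2))
    pr
  })
  disc <- structure(list(cfg = cfg, params = params, kind = "discriminator"),
                    class = "pan2vol_discriminator")
  disc$forward <- function(v) discriminator_forward(disc, v)
  disc
}

#' Discriminator forward pass
#'
#' @param disc A `pan2vol_discriminator`.
#' @param v Numeric `P x P x P` array (volume patch).
#' @param keep_cache Keep activations for backpropagation.
#' @return 3D score array of side `P / 2^n_levels`, or (with `keep_cache`)
#'   a list `(s, cache)`.
#' @export
discriminator_forward <- function(disc, v, keep_cache = FALSE) {
  cfg <- disc$cfg
  pr <- disc$params
  P <- cfg$patch_side
  L <- cfg$n_levels
  v <- if (inherits(v, "volume3d")) vol_data(v) else unclass(v)
  if (!identical(dim(v), c(P, P, P))) {
    stop(sprintf("discriminator_forward: input must be %d^3", P), call. = FALSE)
  }
  stop_if_not_finite(v, "discriminator input")
  h <- array(as.numeric(v), c(P, P, P, 1L))
  ins <- vector("list", L)
  outs <- vector("list", L)
  for (l in seq_len(L)) {
    ins[[l]] <- h
    lay <- pr[[paste0("d", l)]]
    h <- lrelu(conv3_fw(h, dim(h), lay$w, lay$b, 3L, 2L))
    outs[[l]] <- h
  }
  score_in <- h
  s <- conv3_fw(h, dim(h), pr$score$w, pr$score$b, 3L, 1L)
  dim(s) <- dim(s)[1:3]
  if (!keep_cache) return(s)
  list(s = s, cache = list(ins = ins, outs = outs, score_in = score_in))
}

# Backpropagate dLoss/dscore; returns list(grads, gx) where gx (gradient
# w.r.t. the input volume patch) is computed only when need_gx.
discriminator_backward <- function(disc, cache, gs, need_gx = FALSE) {
  pr <- disc$params
  L <- disc$cfg$n_levels
  grads <- list()
  g <- gs
  dim(g) <- c(dim(cache$score_in)[1:3], 1L)
  bw <- conv3_bw(cache$score_in, dim(cache$score_in), pr$score$w, g, 3L, 1L, TRUE)
  grads$score <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  for (l in L:1) {
    g <- lrelu_grad(g, cache$outs[[l]])
    lay <- pr[[paste0("d", l)]]
    bw <- conv3_bw(cache$ins[[l]], dim(cache$ins[[l]]), lay$w, g, 3L, 2L,
                   need_gx || l > 1)
    grads[[paste0("d", l)]] <- list(w = bw$gw, b = bw$gb)
    g <- bw$gx
  }
  gx <- if (need_gx) { dim(g) <- dim(g)[1:3]; g } else NULL
  list(grads = grads, gx = gx)
}

#' Count trainable parameters
#'
#' @param net A `pan2vol_generator` or `pan2vol_discriminator`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(net$params, function(l) length(l$w) + length(l$b), numeric(1)))
}

#' Save / load a network checkpoint
#'
#' Checkpoints are single RDS files with format tag
#' `"pan2vol-checkpoint-v1"` holding the network kind, its config, its
#' parameters, and an optional training seed.
#'
#' @param net A generator or discriminator.
#' @param path Output `.rds` path.
#' @param train_seed Optional seed of the training run that produced the
#'   parameters.
#' @return `path` (for `save_checkpoint`); the rebuilt network (for
#'   `load_checkpoint`).
#' @export
save_checkpoint <- function(net, path, train_seed = NULL) {
  obj <- list(format = "pan2vol-checkpoint-v1", kind = net$kind,
              cfg = net$cfg, params = net$params, train_seed = train_seed)
  atomic_write(path, function(tmp) saveRDS(obj, tmp))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pan2vol-checkpoint-v1")) {
    stop("load_checkpoint: unrecognized checkpoint format", call. = FALSE)
  }
  net <- if (obj$kind == "generator") build_generator(obj$cfg) else build_discriminator(obj$cfg)
  net$params <- obj$params
  attr(net, "train_seed") <- obj$train_seed
  net
}

#' @export
print.pan2vol_generator <- function(x, ...) {
  cat(sprintf("<pan2vol_generator> P=%d, base_channels=%d, n_levels=%d, %d parameters\n",
              x$cfg$patch_side, x$cfg$base_channels, x$cfg$n_levels, n_params(x)))
  invisible(x)
}

#' @export
print.pan2vol_discriminator <- function(x, ...) {
  cat(sprintf("<pan2vol_discriminator> P=%d, base_channels=%d, n_levels=%d, %d parameters\n",
              x$cfg$patch_side, x$cfg$base_channels, x$cfg$n_levels, n_params(x)))
  invisible(x)
}
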