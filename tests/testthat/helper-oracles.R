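# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, separate formulas) so they exercise
# a different code path than the implementation they check.

rand_vol <- function(n, p, seed, spacing = c(0.3, 0.3, 0.3)) {
  set.seed(seed)
  volume3d(array(rnorm(n * p * p), c(n, p, p)), spacing_mm = spacing)
}

# Per-window SSIM with the luminance/contrast/structure terms computed
# separately (C3 = C2 / 2), averaged over all valid windows.
ssim_oracle <- function(a, b, w = 7, L = 2, K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  C3 <- C2 / 2
  d <- dim(a)
  vals <- c()
  for (i in 1:(d[1] - w + 1)) {
    for (j in 1:(d[2] - w + 1)) {
      for (k in 1:(d[3] - w + 1)) {
        wa <- as.vector(a[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)])
        wb <- as.vector(b[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)])
        ux <- mean(wa); uy <- mean(wb)
        sx <- sd(wa); sy <- sd(wb)
        sxy <- sum((wa - ux) * (wb - uy)) / (length(wa) - 1)
        l <- (2 * ux * uy + C1) / (ux^2 + uy^2 + C1)
        cc <- (2 * sx * sy + C2) / (sx^2 + sy^2 + C2)
        s <- (sxy + C3) / (sx * sy + C3)
        vals <- c(vals, l * cc * s)
      }
    }
  }
  mean(vals)
}

# Elementwise loop versions of the four losses.
loss_d_oracle <- function(real, fake) {
  s1 <- 0
  for (v in as.vector(real)) s1 <- s1 + (v - 1)^2
  s2 <- 0
  for (v in as.vector(fake)) s2 <- s2 + v^2
  s1 / length(real) + s2 / length(fake)
}

loss_g_oracle <- function(fake) {
  s <- 0
  for (v in as.vector(fake)) s <- s + (v - 1)^2
  s / length(fake)
}

loss_r_oracle <- function(y, gx) {
  s <- 0
  yv <- as.vector(y); gv <- as.vector(gx)
  for (i in seq_along(yv)) s <- s + (yv[i] - gv[i])^2
  s / length(yv)
}

loss_p_oracle <- function(y, gx) {
  proj <- function(x, keep) apply(x, keep, mean)
  planes <- list(c(1, 2), c(1, 3), c(2, 3))
  tot <- 0
  for (keep in planes) {
    py <- proj(y, keep); pg <- proj(gx, keep)
    tot <- tot + mean((py - pg)^2)
  }
  tot / 3
}

# Rank-map histogram matching oracle for equal-sized inputs with all
# distinct values: each source value takes the template value of the same
# rank.
histmatch_oracle <- function(src, tpl) {
  out <- sort(as.vector(tpl))[rank(as.vector(src))]
  dim(out) <- dim(src)
  out
}

tiny_run_config <- function(seed = 1L, side = 32L, width = 64L,
                            base_channels = 4L, steps = 5L) {
  cfg <- default_run_config()
  cfg$seed <- as.integer(seed)
  cfg$phantom$side_p <- as.integer(side)
  cfg$phantom$width_n <- as.integer(width)
  cfg$network$patch_side <- as.integer(side)
  cfg$network$base_channels <- as.integer(base_channels)
  cfg$training$steps <- as.integer(steps)
  validate_run_config(cfg)
}
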