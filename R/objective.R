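#' Generator loss weights
#'
#' Weights of the combined generator objective
#' `lambda1 * L_adv + lambda2 * L_voxel + lambda3 * L_projection`.
#' Defaults (0.1, 10, 10) follow the usual emphasis of reconstruction GANs
#' of this family, where the voxel and projection regularizers dominate the
#' adversarial term; the source study does not report its values.
#'
#' @param lambda1,lambda2,lambda3 Non-negative reals (adversarial, voxel,
#'   projection); not all zero.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 0.1, lambda2 = 10, lambda3 = 10) {
  w <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(w)) || any(w < 0) || all(w == 0)) {
    stop("loss_weights: weights must be non-negative and not all zero", call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

check_scores <- function(x, what) {
  if (length(x) == 0) stop(sprintf("%s: empty score grid", what), call. = FALSE)
  stop_if_not_finite(x, what)
  x
}

#' Least-squares discriminator loss
#'
#' `mean((real - 1)^2) + mean(fake^2)`: the discriminator is pushed to
#' score real volume patches as 1 and generated ones as 0. The expectation
#' is realized as the empirical mean over all score-grid elements (and
#' batch, when scores are stacked).
#'
#' @param real_scores,fake_scores Numeric score grids from the
#'   discriminator (any shape).
#' @return Scalar loss.
#' @export
loss_discriminator <- function(real_scores, fake_scores) {
  real_scores <- check_scores(real_scores, "loss_discriminator real scores")
  fake_scores <- check_scores(fake_scores, "loss_discriminator fake scores")
  mean((real_scores - 1)^2) + mean(fake_scores^2)
}

#' Least-squares adversarial loss for the generator
#'
#' `mean((fake - 1)^2)`: the generator is pushed to make the discriminator
#' score its outputs as 1.
#'
#' @param fake_scores Numeric score grid for generated patches.
#' @return Scalar loss.
#' @export
loss_generator_adv <- function(fake_scores) {
  fake_scores <- check_scores(fake_scores, "loss_generator_adv scores")
  mean((fake_scores - 1)^2)
}

#' Voxel-wise reconstruction loss
#'
#' Mean squared voxel difference between the ground-truth patch `y` and
#' the generated patch `gx`. The squared-norm notation is realized as a
#' mean so the loss is patch-size invariant.
#'
#' @param y,gx Arrays of identical shape.
#' @return Scalar loss.
#' @export
loss_voxel <- function(y, gx) {
  y <- if (inherits(y, "volume3d")) vol_data(y) else unclass(y)
  gx <- if (inherits(gx, "volume3d")) vol_data(gx) else unclass(gx)
  if (!identical(dim(y), dim(gx))) stop("loss_voxel: shape mismatch", call. = FALSE)
  mean((y - gx)^2)
}

#' Tri-plane projection loss
#'
#' One third of the sum over the axial, coronal, and sagittal planes of
#' the mean squared difference between the mean projections of `y` and
#' `gx`. Penalizes disagreement of the generated patch's silhouettes in
#' all three orthogonal views.
#'
#' @param y,gx 3D arrays (or [volume3d()]) of identical shape.
#' @return Scalar loss.
#' @export
loss_projection <- function(y, gx) {
  y <- if (inherits(y, "volume3d")) vol_data(y) else unclass(y)
  gx <- if (inherits(gx, "volume3d")) vol_data(gx) else unclass(gx)
  if (!identical(dim(y), dim(gx))) stop("loss_projection: shape mismatch", call. = FALSE)
  terms <- vapply(1:3, function(ax) {
    mean((mean_project(y, ax) - mean_project(gx, ax))^2)
  }, numeric(1))
  sum(terms) / 3
}

#' Combined generator objective
#'
#' `lambda1 * L_adv + lambda2 * L_voxel + lambda3 * L_projection`, with the
#' three components returned alongside the total for logging.
#'
#' @param fake_scores Discriminator scores of the generated patch (may be
#'   `NULL` when `lambda1 == 0`).
#' @param y,gx Ground-truth and generated patches, identical shape.
#' @param w A [loss_weights()].
#' @return List with `total`, `adv`, `voxel`, `projection`.
#' @export
total_generator_loss <- function(fake_scores, y, gx, w = loss_weights()) {
  if (w$lambda1 > 0 && is.null(fake_scores)) {
    stop("total_generator_loss: fake_scores required when lambda1 > 0", call. = FALSE)
  }
  adv <- if (!is.null(fake_scores)) loss_generator_adv(fake_scores) else 0
  vox <- loss_voxel(y, gx)
  proj <- loss_projection(y, gx)
  list(total = w$lambda1 * adv + w$lambda2 * vox + w$lambda3 * proj,
       adv = adv, voxel = vox, projection = proj)
}
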