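# Evaluation: 3D SSIM, canine position classifiers, confusion-table
# accuracy arithmetic, and report assembly.

# Sliding-window sum along the first axis (valid positions only).
slide_sum1 <- function(x, w) {
  d <- dim(x)
  n <- d[1]
  m <- matrix(x, n, prod(d[-1]))
  cs <- rbind(0, apply(m, 2, cumsum))
  s <- cs[(w + 1):(n + 1), , drop = FALSE] - cs[1:(n - w + 1), , drop = FALSE]
  array(s, c(n - w + 1, d[-1]))
}

# Box-window sum over all axes (valid windows); axes cycled back in place.
box_sum_valid <- function(x, w) {
  nd <- length(dim(x))
  for (i in seq_len(nd)) {
    x <- slide_sum1(x, w)
    x <- aperm(x, c(seq_len(nd)[-1], 1L))
  }
  x
}

pad_zeros <- function(x, r) {
  d <- dim(x)
  out <- array(0, d + 2L * r)
  idx <- lapply(d, function(n) r + seq_len(n))
  do.call(`[<-`, c(list(out), idx, list(value = x)))
}

# Binary dilation by a cubic structuring element of radius r.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  s <- box_sum_valid(pad_zeros(mask + 0, r), 2L * r + 1L)
  s > 0
}

#' Structural similarity of two volumes
#'
#' Mean over all valid sliding cubic windows of the standard
#' luminance-contrast-structure product with stabilizers
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, where `L` is the declared dynamic
#' range (2 for data in `[-1, 1]`). Local statistics use a uniform window
#' (side 7 by default) with unbiased variance/covariance. Constant windows
#' are handled by the stabilizers: zero-variance windows reduce to the
#' luminance term alone. The value lies in `[-1, 1]`; identical inputs give
#' exactly 1.
#'
#' @param a,b [volume3d()] objects or numeric arrays of identical shape
#'   (2D matrices are also accepted).
#' @param window Window side (default 7), at most the smallest extent.
#' @param data_range Dynamic range `L` of the data (default 2).
#' @param K1,K2 Stabilizer constants (defaults 0.01, 0.03).
#' @return Scalar SSIM.
#' @examples
#' v <- array(rnorm(16^3), c(16, 16, 16))
#' ssim(v, v)  # 1
#' @export
ssim <- function(a, b, window = 7L, data_range = 2, K1 = 0.01, K2 = 0.03) {
  a <- if (inherits(a, "volume3d")) vol_data(a) else if (inherits(a, "panoramic")) pan_data(a) else unclass(a)
  b <- if (inherits(b, "volume3d")) vol_data(b) else if (inherits(b, "panoramic")) pan_data(b) else unclass(b)
  if (is.null(dim(a))) dim(a) <- length(a)
  if (is.null(dim(b))) dim(b) <- length(b)
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch", call. = FALSE)
  w <- as.integer(window)
  if (w < 2 || w > min(dim(a))) {
    stop("ssim: window must lie in [2, min extent]", call. = FALSE)
  }
  stop_if_not_finite(a, "ssim input a")
  stop_if_not_finite(b, "ssim input b")
  n_el <- w^length(dim(a))
  cov_norm <- n_el / (n_el - 1)
  ux <- box_sum_valid(a, w) / n_el
  uy <- box_sum_valid(b, w) / n_el
  uxx <- box_sum_valid(a * a, w) / n_el
  uyy <- box_sum_valid(b * b, w) / n_el
  uxy <- box_sum_valid(a * b, w) / n_el
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  cxy <- cov_norm * (uxy - ux * uy)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  num <- (2 * ux * uy + C1) * (2 * cxy + C2)
  den <- (ux * ux + uy * uy + C1) * (vx + vy + C2)
  mean(num / den)
}

# Intensity-weighted centroid coordinate of a volume inside an ROI along
# one axis (1-based continuous coordinate).
roi_centroid <- function(vol, roi, axis) {
  x <- if (inherits(vol, "volume3d")) vol_data(vol) else unclass(vol)
  roi <- as.logical(roi)
  dim(roi) <- dim(x)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  idx <- which(roi, arr.ind = TRUE)
  wts <- x[roi] - min(x[roi])
  if (sum(wts) <= 0) wts <- rep(1, length(wts))
  sum(wts * idx[, axis]) / sum(wts)
}

#' Classify the buccolingual position of a crown
#'
#' Computes the intensity-weighted centroid of `vol` (shifted by its ROI
#' minimum) inside `crown_roi` and converts its AP coordinate to a depth
#' fraction `f` of the volume's AP extent. Equal thirds of the flattened
#' depth define the classes: `f` in `[0, 1/3)` is buccal, `[1/3, 2/3)`
#' middle, `[2/3, 1]` lingual (half-open boundaries, so `f = 1/3` is
#' middle).
#'
#' @param vol A [volume3d()] or 3D array.
#' @param crown_roi Logical 3D array marking the crown region of interest;
#'   must be nonempty.
#' @return `"buccal"`, `"middle"`, or `"lingual"`.
#' @export
classify_buccolingual <- function(vol, crown_roi) {
  d <- dim(if (inherits(vol, "volume3d")) vol_data(vol) else vol)
  ctr <- roi_centroid(vol, crown_roi, 2L)
  f <- (ctr - 0.5) / d[2]
  if (f < 1 / 3) "buccal" else if (f < 2 / 3) "middle" else "lingual"
}

#' Classify the mesiodistal position of a crown
#'
#' The crown is mesial when its intensity-weighted RL centroid lies at
#' least as close to the volume's RL midline as the reference slot (the RL
#' position the canine would occupy if normally erupted); otherwise distal.
#' An exact tie is mesial. There is no middle class in this direction.
#'
#' @param vol A [volume3d()] or 3D array.
#' @param crown_roi Logical 3D array marking the crown; nonempty.
#' @param reference_slot_rl RL coordinate (1-based) of the normal canine
#'   slot.
#' @return `"mesial"` or `"distal"`.
#' @export
classify_mesiodistal <- function(vol, crown_roi, reference_slot_rl) {
  d <- dim(if (inherits(vol, "volume3d")) vol_data(vol) else vol)
  ctr <- roi_centroid(vol, crown_roi, 1L)
  mid <- (d[1] + 1) / 2
  if (abs(ctr - mid) <= abs(reference_slot_rl - mid)) "mesial" else "distal"
}

#' Per-class identification confusion table
#'
#' Ground-truth class totals and correct-identification counts, the raw
#' material of the position-accuracy tables.
#'
#' @param class_names Ordered class labels.
#' @param totals Per-class ground-truth counts (non-negative integers).
#' @param correct Per-class correct counts, `0 <= correct <= totals`.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(class_names, totals, correct) {
  totals <- as.integer(totals)
  correct <- as.integer(correct)
  if (length(class_names) != length(totals) || length(totals) != length(correct)) {
    stop("confusion_table: lengths differ", call. = FALSE)
  }
  if (any(totals < 0) || any(correct < 0) || any(correct > totals)) {
    stop("confusion_table: need 0 <= correct <= totals", call. = FALSE)
  }
  structure(list(class_names = as.character(class_names),
                 totals = totals, correct = correct),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  acc <- accuracy_from_table(x)
  df <- data.frame(`Ground Truth Position` = toupper(x$class_names),
                   `Number of Samples` = x$totals,
                   Correct = x$correct,
                   Incorrect = x$totals - x$correct,
                   `Percentage Correct` = ifelse(is.na(acc$per_class_pct), "",
                                                 paste0(acc$per_class_pct, "%")),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("Accuracy %.2f\n", acc$overall))
  invisible(x)
}

#' Accuracy summary of a confusion table
#'
#' Per-class percentage correct, rounded half-up to the nearest integer
#' (so 3/26 gives 12 and 1/9 gives 11), and overall accuracy
#' `sum(correct) / sum(totals)` reported to two decimals. A class with zero
#' total has no defined percentage and is reported as `NA`.
#'
#' @param t A [confusion_table()].
#' @return List with `per_class_pct` (named integer vector, `NA` where
#'   undefined) and `overall` (numeric).
#' @examples
#' t <- confusion_table(c("buccal", "middle", "lingual"),
#'                      totals = c(36, 12, 26), correct = c(23, 4, 3))
#' accuracy_from_table(t)
#' @export
accuracy_from_table <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  pct <- ifelse(t$totals > 0,
                floor(100 * t$correct / t$totals + 0.5),
                NA_integer_)
  list(per_class_pct = stats::setNames(as.integer(pct), t$class_names),
       overall = round(sum(t$correct) / sum(t$totals), 2))
}

BL_CLASSES <- c("buccal", "middle", "lingual")
MD_CLASSES <- c("mesial", "distal")

#' Evaluate reconstructions against ground truth
#'
#' For every (truth, prediction) pair, computes the SSIM; for impacted
#' pairs, classifies the buccolingual and mesiodistal crown position on
#' the predicted volume inside the ground-truth crown ROI (dilated by
#' `roi_dilate` voxels) and compares with the true labels. Evaluation
#' measures reconstruction fidelity at a known crown site, not detection.
#'
#' @param pairs Non-empty list; each element a list with `truth` and `pred`
#'   ([volume3d()] or arrays), and for impacted samples `crown_roi`
#'   (logical array), `labels` (list with `bl`, `md`), and `slot_rl`.
#'   `phantom_sample` objects pair with predictions via
#'   `list(truth = s$volume, pred = ..., crown_roi = s$crown_mask,
#'   labels = s$labels, slot_rl = s$slot_rl)`.
#' @param window,data_range,K1,K2 SSIM parameters, logged in the report.
#' @param roi_dilate Crown-ROI dilation radius in voxels (default 2).
#' @return An `eval_report`: SSIM summary (mean, min, max, linearly
#'   interpolated quartiles), per-direction confusion tables with per-class
#'   percentages and overall accuracies, and the metric parameters.
#' @export
evaluate_reconstructions <- function(pairs, window = 7L, data_range = 2,
                                     K1 = 0.01, K2 = 0.03, roi_dilate = 2L) {
  if (length(pairs) == 0) stop("evaluate_reconstructions: empty input", call. = FALSE)
  ssims <- numeric(length(pairs))
  bl_tot <- stats::setNames(integer(3), BL_CLASSES)
  bl_cor <- bl_tot
  md_tot <- stats::setNames(integer(2), MD_CLASSES)
  md_cor <- md_tot
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    ssims[i] <- ssim(pr$truth, pr$pred, window = window,
                     data_range = data_range, K1 = K1, K2 = K2)
    if (!is.null(pr$labels)) {
      roi <- dilate_mask(pr$crown_roi, roi_dilate)
      bl_hat <- classify_buccolingual(pr$pred, roi)
      md_hat <- classify_mesiodistal(pr$pred, roi, pr$slot_rl)
      bl_tot[pr$labels$bl] <- bl_tot[pr$labels$bl] + 1L
      md_tot[pr$labels$md] <- md_tot[pr$labels$md] + 1L
      if (bl_hat == pr$labels$bl) bl_cor[bl_hat] <- bl_cor[bl_hat] + 1L
      if (md_hat == pr$labels$md) md_cor[md_hat] <- md_cor[md_hat] + 1L
    }
  }
  bl_table <- confusion_table(BL_CLASSES, bl_tot, bl_cor)
  md_table <- confusion_table(MD_CLASSES, md_tot, md_cor)
  q <- stats::quantile(ssims, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    ssim_mean = mean(ssims), ssim_min = min(ssims), ssim_max = max(ssims),
    ssim_q25 = q[1], ssim_q50 = q[2], ssim_q75 = q[3],
    ssim_values = ssims,
    bl_table = bl_table, md_table = md_table,
    bl_accuracy = if (sum(bl_tot) > 0) accuracy_from_table(bl_table) else NULL,
    md_accuracy = if (sum(md_tot) > 0) accuracy_from_table(md_table) else NULL,
    n_pairs = length(pairs), n_impacted = sum(bl_tot),
    params = list(ssim_window = window, data_range = data_range,
                  K1 = K1, K2 = K2, roi_dilate = roi_dilate)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d pairs (%d impacted)\n", x$n_pairs, x$n_impacted))
  cat(sprintf("  SSIM mean %.3f, range [%.3f, %.3f], quartiles %.3f / %.3f / %.3f\n",
              x$ssim_mean, x$ssim_min, x$ssim_max,
              x$ssim_q25, x$ssim_q50, x$ssim_q75))
  if (x$n_impacted > 0) {
    cat(sprintf("  buccolingual accuracy %.2f, mesiodistal accuracy %.2f\n",
                x$bl_accuracy$overall, x$md_accuracy$overall))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON, and each confusion table as a CSV mirroring
#' the standard layout (Ground Truth Position, Number of Samples, Correct,
#' Incorrect, Percentage Correct).
#'
#' @param report An `eval_report`.
#' @param path Output JSON path; confusion tables are written next to it
#'   as `<stem>_buccolingual.csv` and `<stem>_mesiodistal.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- report
  class(obj) <- NULL
  obj$bl_table <- unclass(obj$bl_table)
  obj$md_table <- unclass(obj$md_table)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
  stem <- sub("\\.json$", "", path)
  write_confusion_csv(report$bl_table, paste0(stem, "_buccolingual.csv"))
  write_confusion_csv(report$md_table, paste0(stem, "_mesiodistal.csv"))
  invisible(path)
}

write_confusion_csv <- function(t, path) {
  acc <- accuracy_from_table(t)
  df <- data.frame(
    `Ground Truth Position` = toupper(t$class_names),
    `Number of Samples` = t$totals,
    Correct = t$correct,
    Incorrect = t$totals - t$correct,
    `Percentage Correct` = ifelse(is.na(acc$per_class_pct), "",
                                  paste0(acc$per_class_pct, "%")),
    check.names = FALSE)
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
  invisible(path)
}
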