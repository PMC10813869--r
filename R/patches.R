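#' Extract sliding cubic patches along the arch width
#'
#' Slices a flattened volume of width `N` into cubic patches of side `P`
#' (the volume's AP/IS extent) starting at every multiple of `stride`
#' strictly below `N`, i.e. `ceiling(N / stride)` patches. A patch whose RL
#' range extends past the volume is zero-padded, and the padded columns are
#' recorded in a per-patch in-bounds width so that reassembly can exclude
#' them. A 320-wide volume at stride 32 with side 128 therefore yields 10
#' patches.
#'
#' @param vol A [volume3d()].
#' @param patch_side Cube side `P`; must equal the volume's AP/IS extent.
#' @param stride Start spacing `S`, with `1 <= S <= P`.
#' @return A `patch_set`: list with `patches` (list of `P^3` arrays),
#'   `starts` (0-based RL start indices), `valid_width` (in-bounds RL
#'   columns per patch), `source_width`, `patch_side`, `stride`,
#'   `spacing_mm`.
#' @examples
#' v <- volume3d(array(rnorm(40 * 16 * 16), c(40, 16, 16)))
#' ps <- extract_patches(v, patch_side = 16, stride = 8)
#' length(ps$patches)  # ceiling(40 / 8) = 5
#' @export
extract_patches <- function(vol, patch_side, stride) {
  if (!inherits(vol, "volume3d")) vol <- volume3d(vol)
  d <- dim(vol)
  n <- d[1]
  p <- as.integer(patch_side)
  s <- as.integer(stride)
  if (p != d[2]) {
    stop("extract_patches: patch_side must equal the volume's AP/IS extent (cubic patches)",
         call. = FALSE)
  }
  if (s < 1 || p < s) stop("extract_patches: need 1 <= stride <= patch_side", call. = FALSE)
  starts <- seq(0L, n - 1L, by = s)
  x <- vol_data(vol)
  patches <- vector("list", length(starts))
  valid <- integer(length(starts))
  for (i in seq_along(starts)) {
    st <- starts[i]
    w <- min(p, n - st)
    patch <- array(0, c(p, p, p))
    patch[seq_len(w), , ] <- x[st + seq_len(w), , , drop = FALSE]
    patches[[i]] <- patch
    valid[i] <- w
  }
  structure(list(patches = patches, starts = starts, valid_width = valid,
                 source_width = n, patch_side = p, stride = s,
                 spacing_mm = attr(vol, "spacing_mm")),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of side %d, stride %d, source width %d\n",
              length(x$patches), x$patch_side, x$stride, x$source_width))
  invisible(x)
}

#' Reassemble a volume from overlapping patches
#'
#' Inverse of [extract_patches()]: every output voxel is the mean of all
#' in-bounds patch contributions covering it; zero-padded patch columns are
#' excluded. When all contributions to a voxel are bit-identical (as in an
#' extract/reassemble round trip, where overlapping patches copy the same
#' source) the common value is returned verbatim, so the round trip is
#' exact rather than exact-up-to-rounding.
#'
#' @param ps A `patch_set` from [extract_patches()] (or one whose patches
#'   were replaced by generator outputs with the same geometry).
#' @return A [volume3d()] of the original width.
#' @examples
#' v <- volume3d(array(rnorm(40 * 16 * 16), c(40, 16, 16)))
#' w <- reassemble_patches(extract_patches(v, 16, 8))
#' identical(unclass(v), unclass(w))
#' @export
reassemble_patches <- function(ps) {
  if (!inherits(ps, "patch_set")) stop("reassemble_patches: not a patch_set", call. = FALSE)
  if (length(ps$patches) == 0) stop("reassemble_patches: empty patch set", call. = FALSE)
  n <- ps$source_width
  p <- ps$patch_side
  acc <- array(0, c(n, p, p))
  cnt <- array(0, c(n, p, p))
  mn <- array(Inf, c(n, p, p))
  mx <- array(-Inf, c(n, p, p))
  for (i in seq_along(ps$patches)) {
    w <- ps$valid_width[i]
    if (w <= 0) next
    idx <- ps$starts[i] + seq_len(w)
    contrib <- ps$patches[[i]][seq_len(w), , , drop = FALSE]
    acc[idx, , ] <- acc[idx, , , drop = FALSE] + contrib
    cnt[idx, , ] <- cnt[idx, , , drop = FALSE] + 1
    mn[idx, , ] <- pmin(mn[idx, , , drop = FALSE], contrib)
    mx[idx, , ] <- pmax(mx[idx, , , drop = FALSE], contrib)
  }
  if (any(cnt == 0)) stop("reassemble_patches: some voxels receive no contribution", call. = FALSE)
  out <- acc / cnt
  agree <- mn == mx
  out[agree] <- mn[agree]
  volume3d(out, spacing_mm = ps$spacing_mm %||% c(0.3, 0.3, 0.3))
}

# RL start indices (0-based) used by the sliding-patch rule.
patch_starts <- function(n, stride) seq(0L, as.integer(n) - 1L, by = as.integer(stride))
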