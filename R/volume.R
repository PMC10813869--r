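#' Flattened pseudo-3D volume
#'
#' A `volume3d` is a 3D intensity grid holding a flattened (un-bent) dental
#' volume, indexed `(rl, ap, is)`: right-left along the arch (width `N`),
#' anterior-posterior depth (buccal face at `ap = 1`), and
#' inferior-superior height. The AP and IS extents must be equal (the
#' configured patch side `P`); the RL width is free. Voxel spacing is
#' carried in millimetres per axis (0.3 mm isotropic by default, matching
#' typical CBCT-derived data).
#'
#' @param data Numeric 3D array, all values finite, `dim[2] == dim[3]`.
#' @param spacing_mm Positive numeric length-3 vector, mm per voxel along
#'   `(rl, ap, is)`.
#' @return An object of class `volume3d`: the array with a `spacing_mm`
#'   attribute.
#' @examples
#' v <- volume3d(array(0, c(16, 8, 8)))
#' dim(v)
#' @export
volume3d <- function(data, spacing_mm = c(0.3, 0.3, 0.3)) {
  data <- unclass(data)
  if (length(dim(data)) != 3) stop("volume3d: data must be a 3D array", call. = FALSE)
  stop_if_not_finite(data, "volume3d data")
  d <- dim(data)
  if (d[2] != d[3]) {
    stop("volume3d: AP and IS extents must be equal (cubic patch side)", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("volume3d: spacing_mm must be 3 strictly positive reals", call. = FALSE)
  }
  structure(data, spacing_mm = spacing_mm, class = "volume3d")
}

#' Panoramic radiograph image
#'
#' A `panoramic` is a 2D intensity grid indexed `(rl, is)`: the projection
#' of a flattened volume along its depth (AP) axis. When paired with a
#' [volume3d()], its RL extent equals the volume's width `N` and its IS
#' extent equals the volume's height.
#'
#' @param data Numeric matrix, all values finite.
#' @return An object of class `panoramic`.
#' @examples
#' p <- panoramic(matrix(0, 16, 8))
#' dim(p)
#' @export
panoramic <- function(data) {
  data <- unclass(data)
  if (length(dim(data)) != 2) stop("panoramic: data must be a matrix", call. = FALSE)
  stop_if_not_finite(data, "panoramic data")
  structure(data, class = "panoramic")
}

vol_data <- function(v) {
  x <- unclass(v)
  attr(x, "spacing_mm") <- NULL
  x
}

pan_data <- function(p) unclass(p)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing_mm")
  cat(sprintf("<volume3d> %d x %d x %d (rl, ap, is), spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(sp, 3), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.panoramic <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<panoramic> %d x %d (rl, is), range [%.4g, %.4g]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

# Rewrap an array with the class/attributes of a template object.
rewrap_like <- function(template, data) {
  if (inherits(template, "volume3d")) {
    volume3d(data, spacing_mm = attr(template, "spacing_mm"))
  } else if (inherits(template, "panoramic")) {
    panoramic(data)
  } else {
    data
  }
}
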