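#' Normalize intensities to the closed interval [-1, 1]
#'
#' Affinely rescales an image or volume so its minimum maps to -1 and its
#' maximum to +1, the intensity convention the 2D-to-3D generator is
#' trained on. A constant input has no range to stretch and maps to all
#' zeros (the midpoint of the target interval).
#'
#' @param x A [volume3d()], [panoramic()], or plain numeric array/matrix.
#' @return Object of the same type with values in `[-1, 1]`.
#' @examples
#' normalize_intensity(panoramic(matrix(c(0, 50, 100, 25), 2, 2)))
#' @export
normalize_intensity <- function(x) {
  data <- if (inherits(x, "volume3d")) vol_data(x) else if (inherits(x, "panoramic")) pan_data(x) else x
  stop_if_not_finite(data)
  lo <- min(data)
  hi <- max(data)
  out <- if (hi > lo) {
    2 * (data - lo) / (hi - lo) - 1
  } else {
    array(0, dim(data) %||% length(data))
  }
  dim(out) <- dim(data)
  rewrap_like(x, out)
}

#' Histogram matching by rank-based quantile mapping
#'
#' Transforms `source` so that its empirical intensity distribution
#' approximates that of `template`. Each source value is replaced by the
#' template quantile at the source value's (average-tie) rank fraction,
#' using linear interpolation between sorted template values. This is the
#' standard preprocessing step that aligns synthetic panoramic intensity
#' distributions to a representative template before training.
#'
#' @param source,template Objects of the same dimensionality:
#'   [volume3d()], [panoramic()], or numeric arrays.
#' @return Object of the same type and shape as `source`.
#' @examples
#' src <- matrix(runif(16), 4, 4)
#' tpl <- matrix(rnorm(16), 4, 4)
#' out <- histogram_match(src, tpl)
#' @export
histogram_match <- function(source, template) {
  sdat <- if (inherits(source, "volume3d")) vol_data(source) else if (inherits(source, "panoramic")) pan_data(source) else source
  tdat <- if (inherits(template, "volume3d")) vol_data(template) else if (inherits(template, "panoramic")) pan_data(template) else template
  if (length(sdat) == 0 || length(tdat) == 0) {
    stop("histogram_match: empty input", call. = FALSE)
  }
  if (length(dim(sdat) %||% 1) != length(dim(tdat) %||% 1)) {
    stop("histogram_match: source and template dimensionality differ", call. = FALSE)
  }
  stop_if_not_finite(sdat, "source")
  stop_if_not_finite(tdat, "template")
  n_s <- length(sdat)
  # Average ranks handle ties; rank fraction in (0, 1].
  frac <- rank(as.vector(sdat), ties.method = "average") / n_s
  tsort <- sort(as.vector(tdat))
  n_t <- length(tsort)
  # Template empirical quantile at fraction f, linearly interpolated.
  pos <- frac * n_t
  lo <- pmax(1L, floor(pos))
  hi <- pmin(n_t, lo + 1L)
  wt <- pos - lo
  wt[pos <= 1] <- 0
  out <- tsort[lo] * (1 - wt) + tsort[hi] * wt
  dim(out) <- dim(sdat)
  rewrap_like(source, out)
}
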