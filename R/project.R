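#' Orthogonal mean projections of a volume
#'
#' Projects a flattened volume onto the axial, coronal, or sagittal plane
#' by averaging intensities along the perpendicular axis: axial averages
#' over IS (leaving an rl x ap image), coronal over AP (rl x is, the
#' panoramic direction), and sagittal over RL (ap x is). Means rather than
#' sums keep projections on the voxel intensity scale, so the projection
#' loss is commensurable with the voxel loss.
#'
#' @param vol A [volume3d()] or plain 3D array.
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return A numeric matrix (the projected image).
#' @examples
#' v <- volume3d(array(1, c(8, 4, 4)))
#' project(v, "coronal")[1, 1]  # 1
#' @export
project <- function(vol, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  x <- if (inherits(vol, "volume3d")) vol_data(vol) else unclass(vol)
  if (length(dim(x)) != 3) stop("project: input must be a 3D array", call. = FALSE)
  axis <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  mean_project(x, axis)
}

#' @rdname project
#' @return For `project_all`, a `projection_triple`: list with elements
#'   `axial`, `coronal`, `sagittal`.
#' @export
project_all <- function(vol) {
  structure(list(axial = project(vol, "axial"),
                 coronal = project(vol, "coronal"),
                 sagittal = project(vol, "sagittal")),
            class = "projection_triple")
}

# Mean over one axis of a 3D array, returning a matrix of the remaining
# two axes in order.
mean_project <- function(x, axis) {
  d <- dim(x)
  out <- switch(axis,
    colMeans(x, dims = 1L),                     # over rl -> (ap, is)
    {                                           # over ap -> (rl, is)
      y <- aperm(x, c(2L, 1L, 3L))
      colMeans(y, dims = 1L)
    },
    {                                           # over is -> (rl, ap)
      y <- aperm(x, c(3L, 1L, 2L))
      colMeans(y, dims = 1L)
    })
  out
}
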