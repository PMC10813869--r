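# Minimal NIfTI-1 I/O. No NIfTI package is available in the target
# environment, so the package carries its own single-file (.nii / .nii.gz)
# reader and writer: float32 data, spacing in pixdim, little-endian,
# magic "n+1". This covers exactly what the pipeline needs (3D volumes and
# 2D panoramics with voxel spacing); it is not a general NIfTI library.

NIFTI_HDR_SIZE <- 348L

#' Write a volume or panoramic as NIfTI-1
#'
#' Writes a single-file NIfTI-1 image (`.nii`, or gzip-compressed when the
#' path ends in `.nii.gz`) with float32 data and the voxel spacing in the
#' header's `pixdim`. Panoramics are written as 2D images with unit
#' spacing.
#'
#' @param x A [volume3d()], [panoramic()], or numeric array (2D or 3D).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "volume3d")) {
    data <- vol_data(x)
    spacing <- attr(x, "spacing_mm")
  } else {
    data <- if (inherits(x, "panoramic")) pan_data(x) else unclass(x)
    spacing <- rep(1, length(dim(data)))
  }
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("write_nifti: only 2D or 3D images supported", call. = FALSE)
  dims <- dim(data)
  atomic_write(path, function(tmp) {
    con <- if (grepl("\\.gz$", path)) gzfile(tmp, "wb") else file(tmp, "wb")
    on.exit(close(con))
    writeBin(NIFTI_HDR_SIZE, con, size = 4, endian = "little")      # sizeof_hdr
    writeBin(raw(36), con)                                          # unused
    dim16 <- integer(8)
    dim16[1] <- nd
    dim16[2:(1 + nd)] <- dims
    dim16[(2 + nd):8] <- 1L
    writeBin(as.integer(dim16), con, size = 2, endian = "little")   # dim[8]
    writeBin(raw(14), con)                                          # intent_p*, intent_code
    writeBin(16L, con, size = 2, endian = "little")                 # datatype = float32
    writeBin(32L, con, size = 2, endian = "little")                 # bitpix
    writeBin(0L, con, size = 2, endian = "little")                  # slice_start
    pixdim <- numeric(8)
    pixdim[1] <- 1
    pixdim[2:(1 + nd)] <- spacing
    pixdim[(2 + nd):8] <- 1
    writeBin(pixdim, con, size = 4, endian = "little")              # pixdim[8]
    writeBin(352, con, size = 4, endian = "little")                 # vox_offset
    writeBin(c(1, 0), con, size = 4, endian = "little")             # scl_slope, scl_inter
    writeBin(raw(224), con)                                         # rest of header (bytes 120..343)
    writeBin(c("n+1"), con)                                         # magic (writes 4 bytes)
    writeBin(raw(4), con)                                           # extension flag
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  })
  invisible(path)
}

#' Read a NIfTI-1 image written by this package
#'
#' Reads a single-file float32/float64/int16 NIfTI-1 image. 3D images are
#' returned as [volume3d()] with spacing from `pixdim`; 2D images as
#' [panoramic()].
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [volume3d()] or [panoramic()].
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, NIFTI_HDR_SIZE)) {
    stop("read_nifti: not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  }
  readBin(con, "raw", 36)
  dim16 <- readBin(con, "integer", 8, size = 2, endian = "little")
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # bitpix
  readBin(con, "integer", 1, size = 2, endian = "little")  # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl <- readBin(con, "numeric", 2, size = 4, endian = "little")
  readBin(con, "raw", as.integer(vox_offset) - 120L)
  nd <- dim16[1]
  dims <- dim16[2:(1 + nd)]
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "4"  = readBin(con, "integer", n, size = 2, endian = "little"),
    stop("read_nifti: unsupported datatype code ", datatype, call. = FALSE))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) data <- data * scl[1] + scl[2]
  dim(data) <- dims
  if (nd == 3) {
    volume3d(data, spacing_mm = pixdim[2:4])
  } else if (nd == 2) {
    panoramic(data)
  } else {
    stop("read_nifti: only 2D or 3D images supported", call. = FALSE)
  }
}

#' Write / read a panoramic as PNG
#'
#' PNG is lossy for real-valued intensities: values are affinely rescaled
#' to 8-bit grey. Intended for previews and interchange; use NIfTI for
#' lossless round trips. Images are stored with IS as the vertical axis
#' (top = superior).
#'
#' @param p A [panoramic()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_panoramic_png <- function(p, path) {
  x <- pan_data(p)
  lo <- min(x); hi <- max(x)
  g <- if (hi > lo) (x - lo) / (hi - lo) else array(0, dim(x))
  # (rl, is) -> image rows = is reversed so superior is at the top
  img <- t(g)[rev(seq_len(ncol(g))), , drop = FALSE]
  atomic_write(path, function(tmp) png::writePNG(img, tmp, dpi = NULL))
  invisible(path)
}

#' @rdname write_panoramic_png
#' @export
read_panoramic_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  g <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  panoramic(g)
}
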