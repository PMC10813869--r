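#' Specification of a synthetic dental phantom
#'
#' Describes a flattened jaw volume built from discrete tissue intensities
#' (air < trabecular bone < dentine <= enamel): a bone slab spanning the
#' arch width, a row of erupted teeth at the middle depth, and optionally
#' one impacted canine whose crown is planted at a controlled buccolingual
#' depth (`canine_bl`) and displaced mesially or distally along the arch
#' (`canine_md`) relative to its normal slot. The paired panoramic is the
#' depth-axis mean projection of the clean volume. Phantoms stand in for
#' CBCT-derived training pairs, which cannot be redistributed.
#'
#' @param width_n RL voxel count `N` (default 160).
#' @param side_p AP/IS voxel count `P` (default 64; 128 supported).
#' @param tissue_levels Named intensities, strictly ordered
#'   `air < bone < dentine <= enamel`.
#' @param n_teeth Number of normal teeth (>= 4).
#' @param canine_bl `"buccal"`, `"middle"`, `"lingual"`, or `NA` for a
#'   control phantom without an impacted canine.
#' @param canine_md `"mesial"` or `"distal"` (ignored for controls). There
#'   is no middle class in this direction.
#' @param vertical_offset_mm Apical (upward) displacement of the impacted
#'   crown relative to the erupted crown height, in mm.
#' @param noise_sd Additive Gaussian noise sigma on the intensity scale of
#'   `tissue_levels` (applied independently to volume and panoramic).
#' @param seed Integer seed; phantom generation is a pure function of the
#'   spec including this seed.
#' @param spacing_mm Voxel spacing (mm), default 0.3 isotropic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width_n = 160L, side_p = 64L,
                         tissue_levels = c(air = 0, bone = 0.35,
                                           dentine = 0.7, enamel = 1.0),
                         n_teeth = 8L,
                         canine_bl = "buccal", canine_md = "mesial",
                         vertical_offset_mm = 2, noise_sd = 0.05,
                         seed = 1L, spacing_mm = c(0.3, 0.3, 0.3)) {
  spec <- list(width_n = as.integer(width_n), side_p = as.integer(side_p),
               tissue_levels = tissue_levels, n_teeth = as.integer(n_teeth),
               canine_bl = if (is.na(canine_bl)) NA_character_ else match.arg(canine_bl, c("buccal", "middle", "lingual")),
               canine_md = if (is.na(canine_bl)) NA_character_ else match.arg(canine_md, c("mesial", "distal")),
               vertical_offset_mm = vertical_offset_mm,
               noise_sd = noise_sd, seed = as.integer(seed),
               spacing_mm = spacing_mm)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  tl <- spec$tissue_levels
  if (length(tl) != 4 || !all(names(tl) == c("air", "bone", "dentine", "enamel"))) {
    stop("phantom_spec: tissue_levels must be named air, bone, dentine, enamel", call. = FALSE)
  }
  if (!(tl[1] < tl[2] && tl[2] < tl[3] && tl[3] <= tl[4])) {
    stop("phantom_spec: need air < bone < dentine <= enamel", call. = FALSE)
  }
  if (spec$width_n < spec$side_p) stop("phantom_spec: width_n must be >= side_p", call. = FALSE)
  if (spec$noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (spec$n_teeth < 4) stop("phantom_spec: need at least 4 teeth", call. = FALSE)
  invisible(spec)
}

# Paint an ellipsoid of a given intensity into `arr` (modified copy
# returned). Center in continuous 1-based voxel coordinates, semi-axes in
# voxels. Returns list(arr, mask).
paint_ellipsoid <- function(arr, center, semi, value) {
  d <- dim(arr)
  lo <- pmax(1L, floor(center - semi))
  hi <- pmin(d, ceiling(center + semi))
  if (any(lo > hi)) return(list(arr = arr, mask = NULL, box = NULL))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx <- (ix - center[1]) / semi[1]
  dy <- (iy - center[2]) / semi[2]
  dz <- (iz - center[3]) / semi[3]
  inside <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
  sub <- arr[ix, iy, iz, drop = FALSE]
  sub[inside] <- value
  arr[ix, iy, iz] <- sub
  list(arr = arr, mask = inside, box = list(ix = ix, iy = iy, iz = iz))
}

#' Generate one synthetic phantom sample
#'
#' Deterministic given the spec (including its seed). The clean volume is
#' assembled from tissue intensities; Gaussian noise is then added to the
#' volume, and independently to the panoramic rendered from the clean
#' volume. For impacted specs the crown mask and `(canine_bl, canine_md)`
#' labels are returned, plus the RL index of the canine's normal slot for
#' mesiodistal evaluation.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_sample`: list with `volume` ([volume3d()]),
#'   `panoramic` ([panoramic()]), `crown_mask` (logical 3D array),
#'   `labels` (list `bl`, `md`; `NULL` for controls), `slot_rl`
#'   (reference RL index of the normal canine slot), and `spec`.
#' @examples
#' s <- generate_phantom(phantom_spec(width_n = 48, side_p = 32, seed = 7))
#' s$labels$bl
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$width_n
  p <- spec$side_p
  tl <- spec$tissue_levels
  with_seed(spec$seed, {
    vol <- array(tl[["air"]], c(n, p, p))

    # trabecular bone slab: middle band of depth, upper part of height
    ap_bone <- round(c(0.32, 0.68) * p)
    is_bone <- round(c(0.40, 0.92) * p)
    vol[, ap_bone[1]:ap_bone[2], is_bone[1]:is_bone[2]] <- tl[["bone"]]

    # erupted teeth: dentine capsules with enamel crown caps, evenly
    # spaced along RL at the middle depth, crowns pointing down (maxilla)
    margin <- 0.10 * n
    centers_rl <- seq(margin, n - margin, length.out = spec$n_teeth)
    slot_idx <- which.min(abs(centers_rl - 0.25 * n))
    slot_rl <- centers_rl[slot_idx]
    impacted <- !is.na(spec$canine_bl)
    tooth_z <- 0.48 * p
    rx <- 0.045 * p; ry <- 0.055 * p; rz <- 0.18 * p
    for (t in seq_len(spec$n_teeth)) {
      if (impacted && t == slot_idx) next  # canine failed to erupt
      ctr <- c(centers_rl[t], 0.5 * p + 0.5, tooth_z + 0.5)
      vol <- paint_ellipsoid(vol, ctr, c(rx, ry, rz), tl[["dentine"]])$arr
      crown_ctr <- ctr - c(0, 0, 0.12 * p)
      vol <- paint_ellipsoid(vol, crown_ctr, c(0.9 * rx, 0.9 * ry, 0.07 * p),
                             tl[["enamel"]])$arr
    }

    crown_mask <- array(FALSE, c(n, p, p))
    labels <- NULL
    if (impacted) {
      f_band <- switch(spec$canine_bl,
                       buccal = c(0.10, 0.26),
                       middle = c(0.40, 0.60),
                       lingual = c(0.74, 0.90))
      f <- runif(1, f_band[1], f_band[2])
      delta <- runif(1, 0.04, 0.08) * n
      towards_mid <- if (slot_rl <= (n + 1) / 2) 1 else -1
      dir <- if (spec$canine_md == "mesial") towards_mid else -towards_mid
      crown_r <- c(0.05, 0.05, 0.06) * p
      zc <- 0.62 * p + spec$vertical_offset_mm / spec$spacing_mm[3]
      ctr <- c(slot_rl + dir * delta, f * p + 0.5, zc + 0.5)
      if (any(ctr - crown_r < 1) || any(ctr + crown_r > c(n, p, p))) {
        stop("generate_phantom: crown placement would exit the volume", call. = FALSE)
      }
      # root above the crown (clipped at the volume boundary if shallow)
      root_ctr <- ctr + c(0, 0, 0.11 * p)
      root_r <- c(0.03, 0.03, 0.10) * p
      vol <- paint_ellipsoid(vol, root_ctr, root_r, tl[["dentine"]])$arr
      res <- paint_ellipsoid(vol, ctr, crown_r, tl[["enamel"]])
      vol <- res$arr
      crown_mask[res$box$ix, res$box$iy, res$box$iz] <-
        crown_mask[res$box$ix, res$box$iy, res$box$iz] | res$mask
      labels <- list(bl = spec$canine_bl, md = spec$canine_md)
    }

    pan_clean <- render_panoramic(volume3d(vol, spec$spacing_mm))
    if (spec$noise_sd > 0) {
      vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim(vol))
      pan <- pan_data(pan_clean) +
        matrix(rnorm(length(pan_clean), sd = spec$noise_sd), nrow(pan_clean))
    } else {
      pan <- pan_data(pan_clean)
    }
    structure(list(volume = volume3d(vol, spec$spacing_mm),
                   panoramic = panoramic(pan),
                   crown_mask = crown_mask,
                   labels = labels,
                   slot_rl = slot_rl,
                   spec = spec),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  lab <- if (is.null(x$labels)) "control" else paste(x$labels$bl, x$labels$md, sep = "/")
  cat(sprintf("<phantom_sample> %s, volume %s, seed %d\n", lab,
              paste(dim(x$volume), collapse = "x"), x$spec$seed))
  invisible(x)
}

#' Render the panoramic projection of a volume
#'
#' Mean projection along the depth (AP) axis followed by intensity
#' normalization to `[-1, 1]` -- the forward model linking a flattened
#' volume to its synthetic panoramic radiograph.
#'
#' @param vol A [volume3d()].
#' @return A [panoramic()] of shape (rl, is).
#' @export
render_panoramic <- function(vol) {
  if (!inherits(vol, "volume3d")) vol <- volume3d(vol)
  normalize_intensity(panoramic(project(vol, "coronal")))
}

#' Generate a labelled phantom dataset
#'
#' Produces exactly the requested number of samples per position label.
#' Per-sample seeds are derived deterministically from `seed`, so the
#' dataset is a pure function of `(counts, spec_defaults, seed)`.
#'
#' @param counts Named non-negative integer vector; names from
#'   `"buccal_mesial"`, `"buccal_distal"`, `"middle_mesial"`,
#'   `"middle_distal"`, `"lingual_mesial"`, `"lingual_distal"`,
#'   `"control"`. Missing names mean zero.
#' @param spec_defaults A [phantom_spec()] supplying everything except the
#'   position labels and seed.
#' @param seed Master seed.
#' @return List of `phantom_sample` objects (impacted first, in label
#'   order, then controls).
#' @examples
#' ds <- generate_dataset(c(buccal_mesial = 2, control = 1),
#'                        phantom_spec(width_n = 48, side_p = 32), seed = 3)
#' length(ds)
#' @export
generate_dataset <- function(counts, spec_defaults = phantom_spec(), seed = 1L) {
  allowed <- c("buccal_mesial", "buccal_distal", "middle_mesial",
               "middle_distal", "lingual_mesial", "lingual_distal", "control")
  if (is.null(names(counts)) || !all(names(counts) %in% allowed)) {
    stop("generate_dataset: counts must be named with <bl>_<md> labels or 'control'",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("generate_dataset: counts must be >= 0", call. = FALSE)
  full <- stats::setNames(integer(length(allowed)), allowed)
  full[names(counts)] <- as.integer(counts)
  samples <- list()
  i <- 0L
  for (lab in allowed) {
    for (j in seq_len(full[[lab]])) {
      i <- i + 1L
      sp <- unclass(spec_defaults)
      if (lab == "control") {
        sp$canine_bl <- NA_character_
        sp$canine_md <- NA_character_
      } else {
        parts <- strsplit(lab, "_", fixed = TRUE)[[1]]
        sp$canine_bl <- parts[1]
        sp$canine_md <- parts[2]
      }
      sp$seed <- derive_seed(seed, i)
      samples[[i]] <- generate_phantom(structure(sp, class = "phantom_spec"))
    }
  }
  samples
}

#' Example cohort label counts
#'
#' A cohort layout typical of impacted-canine case series: 74 impacted
#' samples with buccal/middle/lingual marginals 36/12/26 and mesial/distal
#' marginals 65/9, plus 49 controls. The joint allocation spreads the 9
#' distal cases over the buccolingual classes as 4/2/3 by largest-remainder
#' apportionment so both marginals are met exactly.
#'
#' @return Named integer vector usable as `counts` in [generate_dataset()].
#' @export
example_cohort_counts <- function() {
  c(buccal_mesial = 32L, buccal_distal = 4L,
    middle_mesial = 10L, middle_distal = 2L,
    lingual_mesial = 23L, lingual_distal = 3L,
    control = 49L)
}
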