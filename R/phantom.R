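#' Synthetic thoracic CT phantom specification
#'
#' Describes a synthetic axial CT scene with voxel-exact ground truth:
#' a soft-tissue torso (elliptic cylinder), two ellipsoidal air-filled lungs
#' containing soft-tissue-density vessels (one main trunk plus two short
#' branches per lung), exterior air touching the image border, a laminated
#' stretcher pad (thin foam plates inside a denser shell) near the bottom of
#' the field spanning the full image width, and additive Gaussian noise.
#' Class HU values are chosen so that the air threshold `[-4000, -400]`
#' separates the scene exactly in the noiseless case: exterior air, lung
#' parenchyma and stretcher foam fall inside the range; soft tissue, vessels
#' and the stretcher shell fall outside.
#'
#' Internal geometry (torso/lung semi-axes, vessel layout, stretcher arc)
#' scales with `size` and is documented in the package vignette.
#'
#' @param size integer `c(nx, ny, nz)` grid size.
#' @param spacing voxel spacing in mm.
#' @param hu_air exterior/lung-cavity air HU.
#' @param hu_lung_parenchyma lung parenchyma HU.
#' @param hu_soft_tissue torso soft-tissue HU.
#' @param hu_vessel intrapulmonary vessel HU.
#' @param hu_stretcher stretcher foam HU (inside the threshold range).
#' @param hu_stretcher_shell stretcher shell HU (outside the range).
#' @param noise_sigma additive Gaussian noise standard deviation in HU.
#' @param n_vessels total number of vessel segments (multiple of 2; split
#'   evenly between the lungs as one trunk + branches per lung).
#' @param stretcher_thickness thickness in voxels of each foam lamina (and
#'   of the gaps between laminae). Laminae thinner than 2 voxels cannot be
#'   consolidated by the radius-2 voting fill and will not be classified as
#'   thin by [remove_stretcher_first_slice].
#' @param stretcher_first_slice_only if `TRUE`, the stretcher appears only
#'   in slice 0 and its foam plates are capped at the ends (isolated thin
#'   components, removable only by the first-slice rule); if `FALSE`
#'   (default) it spans all slices and the full x width, so the
#'   border-spanning rule applies to it.
#' @param seed integer seed driving the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128, 128, 64),
                         spacing = c(1, 1, 2),
                         hu_air = -1000,
                         hu_lung_parenchyma = -850,
                         hu_soft_tissue = 40,
                         hu_vessel = 30,
                         hu_stretcher = -600,
                         hu_stretcher_shell = 100,
                         noise_sigma = 20,
                         n_vessels = 6,
                         stretcher_thickness = 2,
                         stretcher_first_slice_only = FALSE,
                         seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 3 || any(size < 32)) {
    stop("invalid phantom geometry: size must be >= 32 per axis",
      call. = FALSE
    )
  }
  if (!(hu_air < -400 && hu_lung_parenchyma < -400 && hu_stretcher < -400)) {
    stop("invalid phantom geometry: air-like classes must lie below -400 HU",
      call. = FALSE
    )
  }
  if (!(hu_soft_tissue > -400 && hu_vessel > -400 &&
    hu_stretcher_shell > -400)) {
    stop("invalid phantom geometry: tissue-like classes must lie above -400 HU",
      call. = FALSE
    )
  }
  if (noise_sigma < 0) stop("invalid phantom geometry: negative noise", call. = FALSE)
  structure(
    list(
      size = size, spacing = as.numeric(spacing),
      hu_air = hu_air, hu_lung_parenchyma = hu_lung_parenchyma,
      hu_soft_tissue = hu_soft_tissue, hu_vessel = hu_vessel,
      hu_stretcher = hu_stretcher, hu_stretcher_shell = hu_stretcher_shell,
      noise_sigma = noise_sigma, n_vessels = as.integer(n_vessels),
      stretcher_thickness = as.integer(stretcher_thickness),
      stretcher_first_slice_only = isTRUE(stretcher_first_slice_only),
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Builds the scene described by a [phantom_spec] and returns the noisy HU
#' volume together with noiseless voxel-exact ground-truth masks. The same
#' spec (including `seed`) always produces bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_result`: list with `volume`
#'   ([ct_volume]), `truth_lung` (parenchyma + vessels), `truth_lung_air`
#'   (parenchyma only), `truth_vessels`, `truth_stretcher` (foam), and the
#'   generating `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(size = c(48, 48, 32), seed = 7))
#' ph$volume
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$size[1]
  ny <- spec$size[2]
  nz <- spec$size[3]
  origin <- -(spec$size - 1) / 2 * spec$spacing

  cx <- (nx - 1) / 2
  cy <- (ny - 1) / 2
  cz <- (nz - 1) / 2

  # scene proportions (fractions of the grid; defaults give the values in
  # the vignette for the 128 x 128 x 64 grid)
  torso_a <- 0.461 * nx # 59
  torso_b <- 0.3125 * ny # 40
  lung_dx <- 0.25 * nx # 32
  lung_a <- 0.18 * nx # 23
  lung_b <- 0.203 * ny # 26
  lung_c <- 0.391 * nz # 25

  if (cy - torso_b < 2) {
    stop("invalid phantom geometry: torso touches the y border", call. = FALSE)
  }

  x <- seq_len(nx) - 1
  y <- seq_len(ny) - 1
  z <- seq_len(nz) - 1
  X <- array(rep(x, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))

  torso <- ((X - cx) / torso_a)^2 + ((Y - cy) / torso_b)^2 <= 1

  lung_of <- function(sgn) {
    lx <- cx + sgn * lung_dx
    ((X - lx) / lung_a)^2 + ((Y - cy) / lung_b)^2 + ((Z - cz) / lung_c)^2 <= 1
  }
  lungs <- lung_of(-1) | lung_of(1)

  # vessels: hilum-proximal stubs -- a y-oriented trunk through the lung
  # center plus (n_vessels/2 - 1) offset branches per lung. At this grid
  # the erosion kernel is nearly half a lung semi-axis, so only compact
  # mid-lung vessels keep the eroded core surrounding their erosion shadow;
  # this layout leaves the opening stage lossless (verified by the
  # threshold-separability and recovery tests).
  vessels <- array(FALSE, spec$size)
  trunk_r <- 1.6
  branch_r <- 1.6
  trunk_hl <- 0.13 * lung_a
  branch_hl <- 0.087 * lung_a
  per_lung <- max(1L, spec$n_vessels %/% 2L)
  for (sgn in c(-1, 1)) {
    lx <- cx + sgn * lung_dx
    trunk <- (X - lx)^2 + (Z - cz)^2 <= trunk_r^2 & abs(Y - cy) <= trunk_hl
    vessels <- vessels | (trunk & lungs)
    nb <- per_lung - 1L
    if (nb > 0) {
      for (b in seq_len(nb)) {
        bs <- if (b %% 2 == 1) 1 else -1
        seg <- (X - (lx + bs * 0.11 * lung_a))^2 +
          (Z - (cz + bs * 0.05 * lung_c))^2 <= branch_r^2 &
          abs(Y - cy) <= branch_hl
        vessels <- vessels | (seg & lungs)
      }
    }
  }

  # stretcher: concentric laminated arc under the torso
  t <- spec$stretcher_thickness
  n_plates <- 3L
  s0 <- t + 2 # outer shell thickness; thick enough not to fill from outside
  band_w <- 2 * s0 + (2L * n_plates - 1L) * t
  arc_r <- 1.5 * nx
  apex_y <- cy + torso_b + 2
  arc_cy <- apex_y - arc_r
  u <- sqrt((X - cx)^2 + (Y - arc_cy)^2) - arc_r
  in_band <- u >= 0 & u < band_w
  foam2d <- array(FALSE, spec$size)
  for (p in seq_len(n_plates)) {
    lo <- s0 + (p - 1) * 2 * t
    foam2d <- foam2d | (u >= lo & u < lo + t)
  }
  shell2d <- in_band & !foam2d
  if (spec$stretcher_first_slice_only) {
    foam2d <- foam2d & abs(X - cx) <= 0.47 * nx
    keep_z <- Z == 0
  } else {
    keep_z <- TRUE
  }
  outside_torso <- !torso
  foam <- foam2d & keep_z & outside_torso
  shell <- shell2d & keep_z & outside_torso

  hu <- array(spec$hu_air, spec$size)
  hu[torso] <- spec$hu_soft_tissue
  hu[lungs] <- spec$hu_lung_parenchyma
  hu[vessels] <- spec$hu_vessel
  hu[shell] <- spec$hu_stretcher_shell
  hu[foam] <- spec$hu_stretcher

  if (spec$noise_sigma > 0) {
    noise <- with_seed(
      spec$seed,
      stats::rnorm(length(hu), sd = spec$noise_sigma)
    )
    hu <- hu + array(noise, spec$size)
  }
  hu <- round(hu)
  hu[hu < -32768] <- -32768
  hu[hu > 32767] <- 32767

  mk <- function(v) binary_mask(v, spacing = spec$spacing, origin = origin)
  structure(
    list(
      volume = ct_volume(hu, spacing = spec$spacing, origin = origin),
      truth_lung = mk(lungs),
      truth_lung_air = mk(lungs & !vessels),
      truth_vessels = mk(vessels),
      truth_stretcher = mk(foam),
      spec = spec
    ),
    class = "phantom_result"
  )
}

#' @export
print.phantom_result <- function(x, ...) {
  cat(sprintf(
    "<phantom_result> %d x %d x %d, lung %d voxels (%d vessel), stretcher %d\n",
    x$spec$size[1], x$spec$size[2], x$spec$size[3],
    sum(x$truth_lung$voxels), sum(x$truth_vessels$voxels),
    sum(x$truth_stretcher$voxels)
  ))
  invisible(x)
}

#' Write a phantom as a DICOM series
#'
#' Writes one single-frame CT file per slice, with rescale slope 1 and
#' intercept -1024 (stored value = HU + 1024), axial orientation, and slice
#' positions consistent with the phantom's spacing and origin, so that
#' [read_dicom_series] round-trips the volume exactly.
#'
#' @param result a [generate_phantom] result.
#' @param directory output directory (created if missing).
#' @return The vector of file paths written, invisibly.
#' @export
write_phantom_dicom <- function(result, directory) {
  stopifnot(inherits(result, "phantom_result"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  vol <- result$volume
  nz <- vol$size[3]
  series_uid <- "1.2.826.0.1.3680043.9.7156.2.1"
  paths <- character(nz)
  for (k in seq_len(nz)) {
    p <- file.path(directory, sprintf("slice_%03d.dcm", k - 1))
    dicom_write_slice(
      p,
      pixels = vol$voxels[, , k] + 1024,
      slope = 1, intercept = -1024,
      position = c(vol$origin[1:2], vol$origin[3] + (k - 1) * vol$spacing[3]),
      pixel_spacing = vol$spacing[1:2],
      series_uid = series_uid,
      sop_uid = paste0(series_uid, ".", k),
      instance_number = k
    )
    paths[k] <- p
  }
  invisible(paths)
}
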