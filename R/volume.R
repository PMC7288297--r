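#' CT volume in Hounsfield units
#'
#' A `ct_volume` is a 3D scalar voxel grid in Hounsfield units (HU) together
#' with its spatial metadata. The axis convention is fixed: the first array
#' dimension is x (column), the second y (row), the third z (slice). Voxel
#' indices are 0-based in all physical-coordinate formulas: the center of
#' voxel `(i, j, k)` lies at `origin + c(i, j, k) * spacing` (mm).
#'
#' @param voxels 3D numeric array of HU values. Must be finite and within
#'   the signed 16-bit HU range `[-32768, 32767]`.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `origin` and `size` (the grid dimensions `c(nx, ny, nz)`).
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 2)), spacing = c(1, 1, 2.5))
#' v$size
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_voxel_array(voxels)
  check_grid_meta(spacing, origin)
  if (anyNA(voxels) || !all(is.finite(voxels))) {
    stop("voxels must be finite HU values", call. = FALSE)
  }
  rng <- range(voxels)
  if (rng[1] < -32768 || rng[2] > 32767) {
    stop("HU values outside [-32768, 32767]", call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      size = dim(voxels)
    ),
    class = "ct_volume"
  )
}

#' Binary voxel mask
#'
#' A `binary_mask` is a boolean voxel grid sharing the grid geometry
#' (size, spacing, origin) of the [ct_volume] it was derived from. Every
#' mask--volume and mask--mask operation in the package checks that the two
#' grids agree before combining voxels.
#'
#' @param voxels 3D logical array (`TRUE` = foreground).
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("voxels must be a 3D array", call. = FALSE)
  }
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (anyNA(voxels)) stop("mask voxels must be TRUE/FALSE", call. = FALSE)
  check_grid_meta(spacing, origin)
  structure(
    list(
      voxels = voxels,
      spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      size = dim(voxels)
    ),
    class = "binary_mask"
  )
}

as_voxel_array <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("voxels must be a 3D array", call. = FALSE)
  }
  if (!is.numeric(voxels)) stop("voxels must be numeric", call. = FALSE)
  storage.mode(voxels) <- "double"
  voxels
}

check_grid_meta <- function(spacing, origin) {
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3 || !all(is.finite(origin))) {
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Derive an empty or full mask on a volume's grid
#'
#' @param x a `ct_volume` or `binary_mask` supplying the grid geometry.
#' @param fill logical scalar used for every voxel.
#' @return A [binary_mask] on the same grid.
#' @export
mask_like <- function(x, fill = FALSE) {
  stopifnot(inherits(x, c("ct_volume", "binary_mask")))
  binary_mask(array(fill, dim = x$size), spacing = x$spacing, origin = x$origin)
}

#' Test whether two grids coincide
#'
#' Grid geometry (size, spacing, origin) must match to within `tol` mm for
#' masks and volumes to be combined.
#'
#' @param a,b `ct_volume` or `binary_mask` objects.
#' @param tol metadata tolerance in mm.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$size, b$size) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("geometry mismatch", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU [%g, %g]\n",
    x$size[1], x$size[2], x$size[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
    x$size[1], x$size[2], x$size[3], sum(x$voxels),
    100 * mean(x$voxels)
  ))
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A  &  B| / (|A| + |B|)`; 1 means perfect agreement. Two empty masks
#' have Dice 1 by convention.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0) {
    return(1)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}
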