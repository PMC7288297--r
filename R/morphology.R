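#' Structuring elements
#'
#' A structuring element is the neighborhood set `B` of integer voxel
#' offsets used by the binary morphological operators. Offsets are isotropic
#' in index space (anisotropic physical spacing is deliberately not
#' compensated; the radius parameter counts voxels). Both shapes contain the
#' zero offset and are symmetric (`b` in `B` implies `-b` in `B`).
#'
#' `se_ball(r)` contains every offset with Euclidean index-space norm <= r;
#' `se_box(r)` contains every offset with Chebyshev norm <= r (a cube of
#' side `2r + 1`).
#'
#' @param radius non-negative integer radius in voxels.
#' @return An object of class `struct_elem` with fields `shape`, `radius`
#'   and `offsets` (an n x 3 integer matrix).
#' @examples
#' nrow(se_ball(1)$offsets) # the 6-neighborhood plus the center
#' @export
se_ball <- function(radius) {
  new_struct_elem("ball", radius)
}

#' @rdname se_ball
#' @export
se_box <- function(radius) {
  new_struct_elem("box", radius)
}

new_struct_elem <- function(shape, radius) {
  radius <- as.integer(radius)
  if (length(radius) != 1 || is.na(radius) || radius < 0) {
    stop("radius must be a non-negative integer", call. = FALSE)
  }
  g <- -radius:radius
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  if (shape == "ball") {
    off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  }
  structure(list(shape = shape, radius = radius, offsets = off),
    class = "struct_elem"
  )
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf(
    "<struct_elem> %s, radius %d voxels, %d offsets\n",
    x$shape, x$radius, nrow(x$offsets)
  ))
  invisible(x)
}

#' Inclusive Hounsfield-unit range
#'
#' @param lower,upper inclusive HU bounds, `lower <= upper`.
#' @export
hu_range <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    stop("invalid HU range: need finite lower <= upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "hu_range")
}

as_hu_range <- function(x) {
  if (inherits(x, "hu_range")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 2) {
    return(hu_range(x[1], x[2]))
  }
  stop("expected a hu_range or a numeric vector of length 2", call. = FALSE)
}

#' Threshold a CT volume to a binary mask
#'
#' A voxel is foreground iff `lower <= HU <= upper`, both bounds inclusive.
#' Grid geometry is copied from the volume.
#'
#' @param volume a [ct_volume].
#' @param range a [hu_range] or numeric `c(lower, upper)`. The lung pipeline
#'   default is `c(-4000, -400)`, the air range of a thoracic CT.
#' @return A [binary_mask].
#' @export
hu_threshold <- function(volume, range = c(-4000, -400)) {
  stopifnot(inherits(volume, "ct_volume"))
  r <- as_hu_range(range)
  binary_mask(volume$voxels >= r$lower & volume$voxels <= r$upper,
    spacing = volume$spacing, origin = volume$origin
  )
}

#' Binary erosion and dilation
#'
#' Erosion keeps voxel `z` iff every offset of the structuring element
#' translated to `z` lands on foreground; out-of-bounds neighbors count as
#' background, so foreground touching the image border erodes inward.
#' Dilation marks `z` foreground iff any translated offset lands on
#' foreground. Ball erosion/dilation is computed through an exact Euclidean
#' distance transform (a voxel is eroded away iff some background voxel --
#' or the image exterior -- lies within Euclidean distance `r`), which is
#' equivalent to the offset definition; box elements use separable sliding
#' windows.
#'
#' @param mask a [binary_mask].
#' @param se a [se_ball] or [se_box] structuring element.
#' @return A [binary_mask] on the same grid.
#' @export
erode <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_elem"))
  if (se$radius == 0) {
    return(mask)
  }
  vox <- if (se$shape == "box") {
    array(cpp_box_morph(mask$voxels, dim(mask$voxels), se$radius, TRUE),
      dim = dim(mask$voxels)
    )
  } else {
    # squared distance to background, with a one-voxel background pad so the
    # exterior participates as background
    d <- dim(mask$voxels)
    pad <- array(TRUE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !mask$voxels
    sq <- array(cpp_sqedt(pad, dim(pad)), dim = dim(pad))
    sq <- sq[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    mask$voxels & sq > se$radius^2
  }
  binary_mask(vox, spacing = mask$spacing, origin = mask$origin)
}

#' @rdname erode
#' @export
dilate <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "struct_elem"))
  if (se$radius == 0) {
    return(mask)
  }
  vox <- if (se$shape == "box") {
    array(cpp_box_morph(mask$voxels, dim(mask$voxels), se$radius, FALSE),
      dim = dim(mask$voxels)
    )
  } else {
    if (!any(mask$voxels)) {
      return(mask)
    }
    sq <- array(cpp_sqedt(mask$voxels, dim(mask$voxels)), dim = dim(mask$voxels))
    sq <= se$radius^2
  }
  binary_mask(vox, spacing = mask$spacing, origin = mask$origin)
}

#' Morphological opening and closing
#'
#' `open_mask` is erosion followed by dilation (anti-extensive: removes
#' structures the element does not fit into); `close_mask` is dilation
#' followed by erosion (extensive: fills gaps narrower than the element).
#' The closing composes its two steps on the background-extended grid (the
#' image padded by the element radius), so that the intermediate dilation
#' is not clipped at the image border and `mask` is always contained in
#' `close_mask(mask, se)`; this matches the safe-border behavior of the
#' field's standard implementations.
#'
#' @inheritParams erode
#' @export
open_mask <- function(mask, se) {
  dilate(erode(mask, se), se)
}

#' @rdname open_mask
#' @export
close_mask <- function(mask, se) {
  r <- se$radius
  if (r == 0) {
    return(mask)
  }
  d <- dim(mask$voxels)
  pad <- array(FALSE, d + 2L * r)
  ix <- r + seq_len(d[1])
  iy <- r + seq_len(d[2])
  iz <- r + seq_len(d[3])
  pad[ix, iy, iz] <- mask$voxels
  pm <- binary_mask(pad,
    spacing = mask$spacing,
    origin = mask$origin - r * mask$spacing
  )
  out <- erode(dilate(pm, se), se)
  binary_mask(out$voxels[ix, iy, iz],
    spacing = mask$spacing,
    origin = mask$origin
  )
}

#' Iterative voting hole filling
#'
#' At each iteration a background voxel flips to foreground iff the number
#' of foreground voxels in its box neighborhood of the given radius
#' (excluding the center; out-of-bounds voxels are excluded from the count)
#' is at least half the neighborhood size plus `majority`. Foreground voxels
#' never flip, so the operation is monotone non-decreasing; iteration stops
#' at convergence or after `max_iterations`. Axes of extent 1 contribute no
#' neighbors, so a single-slice mask is filled with the 2D
#' `(2r+1)^2 - 1`-neighbor rule.
#'
#' @param mask a [binary_mask].
#' @param radius box neighborhood radius in voxels (>= 1).
#' @param max_iterations iteration cap (>= 1). The lung pipeline uses 700.
#' @param majority votes beyond half the neighborhood required to flip.
#' @return A [binary_mask]; attribute `iterations` records how many
#'   iterations were applied before convergence.
#' @export
voting_hole_fill <- function(mask, radius = 2, max_iterations = 700,
                             majority = 1) {
  stopifnot(inherits(mask, "binary_mask"), radius >= 1, max_iterations >= 1,
            majority >= 0)
  res <- cpp_voting_fill(
    mask$voxels, dim(mask$voxels), as.integer(radius),
    as.integer(max_iterations), as.integer(majority)
  )
  out <- binary_mask(array(res$mask, dim = dim(mask$voxels)),
    spacing = mask$spacing, origin = mask$origin
  )
  attr(out, "iterations") <- res$iterations
  out
}

#' Apply a binary mask to a volume
#'
#' Voxels under mask foreground keep their HU value; all others are set to
#' `outside_value`. The default (-4096 HU) lies strictly below the
#' pipeline's lower threshold bound so that re-thresholding a masked volume
#' is stable.
#'
#' @param volume a [ct_volume].
#' @param mask a [binary_mask] on the same grid.
#' @param outside_value HU value written outside the mask.
#' @return A [ct_volume].
#' @export
mask_apply <- function(volume, mask, outside_value = -4096) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(volume, mask)
  vox <- volume$voxels
  vox[!mask$voxels] <- outside_value
  ct_volume(vox, spacing = volume$spacing, origin = volume$origin)
}

#' Boolean mask algebra
#'
#' Element-wise combination of two masks on the same grid. `mask_subtract`
#' is `a AND NOT b` (set difference; never negative).
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return A [binary_mask].
#' @export
mask_and <- function(a, b) {
  mask_binop(a, b, `&`)
}

#' @rdname mask_and
#' @export
mask_or <- function(a, b) {
  mask_binop(a, b, `|`)
}

#' @rdname mask_and
#' @export
mask_xor <- function(a, b) {
  mask_binop(a, b, xor)
}

#' @rdname mask_and
#' @export
mask_subtract <- function(a, b) {
  mask_binop(a, b, function(x, y) x & !y)
}

#' @rdname mask_and
#' @export
mask_complement <- function(a) {
  stopifnot(inherits(a, "binary_mask"))
  binary_mask(!a$voxels, spacing = a$spacing, origin = a$origin)
}

mask_binop <- function(a, b, op) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b)
  binary_mask(op(a$voxels, b$voxels), spacing = a$spacing, origin = a$origin)
}
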