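#' Connected-component labelmap of a binary mask
#'
#' Partitions the mask foreground into connected components under 6- or
#' 26-connectivity. Components are numbered 1..K deterministically by the
#' scan order (x fastest, then y, then z) of their first voxel. Per-component
#' shape statistics (voxel count, inclusive bounding box, per-axis extent)
#' are tabulated; bounding-box indices are 0-based, matching the package's
#' physical-coordinate convention.
#'
#' @param mask a [binary_mask].
#' @param connectivity 6 (face neighbors) or 26 (face, edge and corner
#'   neighbors). The lung pipeline default is 26.
#' @return An object of class `label_map`: a list with `labels` (3D integer
#'   array, 0 = background), `components` (data.frame with columns `label`,
#'   `voxel_count`, `xmin`..`zmax`, `extent_x`, `extent_y`, `extent_z`),
#'   `connectivity` and the grid metadata of the source mask.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  d <- dim(mask$voxels)
  labels <- array(cpp_label(mask$voxels, d, connectivity), dim = d)
  k <- max(labels)
  if (k == 0) {
    comp <- data.frame(
      label = integer(0), voxel_count = integer(0),
      xmin = integer(0), xmax = integer(0), ymin = integer(0),
      ymax = integer(0), zmin = integer(0), zmax = integer(0),
      extent_x = integer(0), extent_y = integer(0), extent_z = integer(0)
    )
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    # 0-based inclusive bounding boxes
    comp <- data.frame(
      label = seq_len(k),
      voxel_count = as.integer(tabulate(lab, nbins = k)),
      xmin = as.integer(tapply(idx[, 1], lab, min) - 1L),
      xmax = as.integer(tapply(idx[, 1], lab, max) - 1L),
      ymin = as.integer(tapply(idx[, 2], lab, min) - 1L),
      ymax = as.integer(tapply(idx[, 2], lab, max) - 1L),
      zmin = as.integer(tapply(idx[, 3], lab, min) - 1L),
      zmax = as.integer(tapply(idx[, 3], lab, max) - 1L)
    )
    comp$extent_x <- comp$xmax - comp$xmin + 1L
    comp$extent_y <- comp$ymax - comp$ymin + 1L
    comp$extent_z <- comp$zmax - comp$zmin + 1L
  }
  rownames(comp) <- NULL
  structure(
    list(
      labels = labels, components = comp, connectivity = connectivity,
      spacing = mask$spacing, origin = mask$origin, size = d
    ),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %d component(s), connectivity %d\n",
    nrow(x$components), x$connectivity
  ))
  if (nrow(x$components) > 0) print(utils::head(x$components, 10))
  invisible(x)
}

labelmap_keep <- function(lm, keep_labels) {
  binary_mask(
    array(lm$labels %in% keep_labels & lm$labels > 0L, dim = lm$size),
    spacing = lm$spacing, origin = lm$origin
  )
}

#' Drop components below a voxel-count cutoff
#'
#' Used by the lung pipeline to discard small groups of voxels that survive
#' thresholding, e.g. due to noise. The default cutoff (1000 voxels) is far
#' below any lung volume and above isolated noise specks.
#'
#' @param lm a [label_components] result.
#' @param min_voxels components with fewer voxels than this are removed.
#' @return A [binary_mask] containing the union of the surviving components.
#' @export
remove_small_components <- function(lm, min_voxels = 1000) {
  stopifnot(inherits(lm, "label_map"))
  keep <- lm$components$label[lm$components$voxel_count >= min_voxels]
  labelmap_keep(lm, keep)
}

#' Drop components spanning the full image width or depth
#'
#' Removes every component whose bounding-box extent along x equals `nx` or
#' whose extent along y equals `ny` (strict equality). In a thoracic CT the
#' air surrounding the patient reaches the image border on every side, so
#' after reconstruction of the mask scale this rule removes the exterior-air
#' group (and anything fused to it, such as the stretcher) while leaving the
#' interior lung components untouched.
#'
#' @param lm a [label_components] result.
#' @param volume_size integer `c(nx, ny, nz)`; defaults to the labelmap's
#'   own grid size.
#' @return A [binary_mask] of the surviving components.
#' @export
remove_border_spanning <- function(lm, volume_size = lm$size) {
  stopifnot(inherits(lm, "label_map"))
  comp <- lm$components
  drop <- comp$extent_x == volume_size[1] | comp$extent_y == volume_size[2]
  labelmap_keep(lm, comp$label[!drop])
}

#' Remove thin stretcher-like structures from the first slice
#'
#' Operates only on slice index 0 (the lowest-z slice in position-sorted
#' order); all other slices pass through unchanged. The first slice is
#' consolidated with a 2D [voting_hole_fill] (box radius `fill_radius`, at
#' most `fill_iterations` iterations): bulky regions gain almost no area,
#' whereas laminated thin structures -- the fine contours a CT stretcher
#' pad leaves in the air mask -- gain the area of their internal gaps. Each
#' connected component of the *filled* slice whose area exceeds the area of
#' the original foreground inside it by more than `thin_ratio` (relative) is
#' classified as stretcher, and its original voxels are removed.
#'
#' @param mask a [binary_mask] with at least one slice.
#' @param fill_radius 2D voting-fill box radius in voxels (pipeline
#'   default 2).
#' @param fill_iterations voting-fill iteration cap (pipeline default 700).
#' @param thin_ratio relative area-gain threshold above which a component
#'   is removed (default 0.5).
#' @param connectivity 2D connectivity for the first-slice components.
#' @return A [binary_mask].
#' @export
remove_stretcher_first_slice <- function(mask, fill_radius = 2,
                                         fill_iterations = 700,
                                         thin_ratio = 0.5,
                                         connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"), mask$size[3] >= 1)
  slice <- mask$voxels[, , 1, drop = FALSE]
  if (!any(slice)) {
    return(mask)
  }
  m2 <- binary_mask(slice, spacing = mask$spacing, origin = mask$origin)
  filled <- voting_hole_fill(m2,
    radius = fill_radius,
    max_iterations = fill_iterations
  )
  lm <- label_components(filled, connectivity = connectivity)
  keep_slice <- slice
  for (l in lm$components$label) {
    inside <- lm$labels == l
    a0 <- sum(slice[inside])
    af <- sum(inside)
    if (a0 > 0 && (af - a0) / a0 > thin_ratio) {
      keep_slice[inside] <- FALSE
    }
  }
  out <- mask$voxels
  out[, , 1] <- keep_slice
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}
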