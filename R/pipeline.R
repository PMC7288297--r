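#' Lung segmentation pipeline configuration
#'
#' Parameters of the staged lung segmentation algorithm, with the classical
#' defaults: air threshold `[-4000, -400]` HU, spherical erosion of radius
#' 10 voxels, first-slice stretcher consolidation with a radius-2 voting
#' fill capped at 700 iterations, and removal of components smaller than
#' 1000 voxels or spanning the full image extent in x or y.
#'
#' @param threshold_range inclusive HU range kept by the initial threshold.
#' @param erosion_radius ball radius (voxels) of the initial erosion, which
#'   severs thin connections and deletes fine structures before component
#'   analysis.
#' @param restore_dilate_radius ball radius of the dilation that restores
#'   the surviving structures to scale before component analysis. The
#'   default (`NA`) uses `erosion_radius + 1`: one extra voxel compensates
#'   the half-voxel digitization loss of the discrete erode/dilate pair, so
#'   the coarse mask ends up slightly larger than the lung -- deliberately,
#'   since the re-threshold refinement trims the overhang back to the air
#'   boundary.
#' @param fill_radius,fill_iterations 2D voting-fill parameters of the
#'   first-slice stretcher stage.
#' @param thin_ratio relative area-gain threshold classifying a first-slice
#'   component as stretcher.
#' @param min_component_voxels small-group cutoff.
#' @param connectivity 6 or 26, for component analysis.
#' @param refine_dilate_radius,refine_erode_radius ball radii of the edge
#'   refinement closing applied after re-thresholding the masked volume.
#'   Kept small (1 voxel) so that vessel-sized structures are not absorbed
#'   into the air mask.
#' @param region_close_radius ball radius of the closing that produces the
#'   lung-region envelope for the vessel split; must exceed the caliber of
#'   the vessels of interest.
#' @param vessel_threshold HU above which a voxel inside the lung envelope
#'   counts as vessel.
#' @param outside_value HU written outside masks by [mask_apply]; strictly
#'   below the lower threshold bound so re-thresholding is stable.
#' @param histogram_bin_width bin width (HU) of the reported histogram.
#' @return An object of class `lung_pipeline_config`.
#' @export
lung_pipeline_config <- function(threshold_range = c(-4000, -400),
                                 erosion_radius = 10,
                                 restore_dilate_radius = NA,
                                 fill_radius = 2,
                                 fill_iterations = 700,
                                 thin_ratio = 0.5,
                                 min_component_voxels = 1000,
                                 connectivity = 26,
                                 refine_dilate_radius = 1,
                                 refine_erode_radius = 1,
                                 region_close_radius = 6,
                                 vessel_threshold = -400,
                                 outside_value = -4096,
                                 histogram_bin_width = 10) {
  cfg <- list(
    threshold_range = as.numeric(unlist(threshold_range))[1:2],
    erosion_radius = as.integer(erosion_radius),
    restore_dilate_radius = if (is.na(restore_dilate_radius)) {
      as.integer(erosion_radius) + 1L
    } else {
      as.integer(restore_dilate_radius)
    },
    fill_radius = as.integer(fill_radius),
    fill_iterations = as.integer(fill_iterations),
    thin_ratio = as.numeric(thin_ratio),
    min_component_voxels = as.integer(min_component_voxels),
    connectivity = as.integer(connectivity),
    refine_dilate_radius = as.integer(refine_dilate_radius),
    refine_erode_radius = as.integer(refine_erode_radius),
    region_close_radius = as.integer(region_close_radius),
    vessel_threshold = as.numeric(vessel_threshold),
    outside_value = as.numeric(outside_value),
    histogram_bin_width = as.numeric(histogram_bin_width)
  )
  if (cfg$erosion_radius < 0 || cfg$restore_dilate_radius < 0 ||
    cfg$fill_radius < 1 ||
    cfg$fill_iterations < 1 || cfg$refine_dilate_radius < 0 ||
    cfg$refine_erode_radius < 0 || cfg$region_close_radius < 0) {
    stop("invalid pipeline configuration", call. = FALSE)
  }
  if (cfg$outside_value >= cfg$threshold_range[1]) {
    stop("outside_value must lie below the lower threshold bound",
      call. = FALSE
    )
  }
  structure(cfg, class = "lung_pipeline_config")
}

#' @export
print.lung_pipeline_config <- function(x, ...) {
  cat("<lung_pipeline_config>\n")
  for (n in names(x)) {
    cat(sprintf("  %-22s %s\n", n, paste(x[[n]], collapse = ", ")))
  }
  invisible(x)
}

stage_stats <- function(name, mask, connectivity, per_component = FALSE) {
  lm <- label_components(mask, connectivity = connectivity)
  out <- list(
    name = name,
    foreground_voxels = sum(mask$voxels),
    n_components = nrow(lm$components)
  )
  if (per_component && nrow(lm$components) > 0) {
    voxvol <- prod(mask$spacing)
    out$per_component <- lapply(seq_len(nrow(lm$components)), function(i) {
      c <- lm$components[i, ]
      list(
        voxel_count = c$voxel_count,
        bbox = c(c$xmin, c$xmax, c$ymin, c$ymax, c$zmin, c$zmax),
        physical_volume_mm3 = c$voxel_count * voxvol
      )
    })
  }
  out
}

#' Segment the lungs from a thoracic CT volume
#'
#' Runs the staged segmentation algorithm:
#' \enumerate{
#'   \item threshold to the air range (`threshold_range`);
#'   \item erode with a ball of `erosion_radius` voxels -- `MASK_01`.
#'     Erosion severs the thin connections between exterior air, stretcher
#'     and lungs and deletes fine structures outright;
#'   \item remove residual thin stretcher contours in the first slice
#'     ([remove_stretcher_first_slice]);
#'   \item dilate by `restore_dilate_radius` (by default one voxel more
#'     than the erosion, restoring the surviving structures to a scale
#'     slightly larger than the lung), then label
#'     components and discard small groups
#'     ([remove_small_components]) and groups spanning the full x or y
#'     image extent ([remove_border_spanning]) -- `MASK_02`;
#'   \item apply `MASK_02` to the volume -- `RES_01`;
#'   \item re-threshold `RES_01` and close with the refine radii to repair
#'     the mask edges -- `MASK_03`, the air-only lung interior;
#'   \item close `MASK_03` with `region_close_radius` to form the lung
#'     envelope; voxels of the envelope outside `MASK_03` that are brighter
#'     than `vessel_threshold` are the vessels; their union with `MASK_03`
#'     is the lung-with-vessels mask;
#'   \item apply `MASK_03` to the volume and histogram the masked HU values.
#' }
#'
#' @param volume an axial [ct_volume] in HU.
#' @param config a [lung_pipeline_config].
#' @return An object of class `segmentation_result`: masks
#'   `mask_lung_with_vessels`, `mask_lung_only`, `mask_vessels_only`, the
#'   `masked_volume`, the HU `histogram` (data.frame), `stage_masks` (named
#'   list of the intermediate masks) and `report` (parameter echo plus
#'   per-stage component statistics).
#' @seealso [generate_phantom] for a synthetic volume to try this on.
#' @export
segment_lungs <- function(volume, config = lung_pipeline_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!inherits(config, "lung_pipeline_config")) {
    stop("config must be a lung_pipeline_config", call. = FALSE)
  }
  conn <- config$connectivity
  stages <- list()

  th <- hu_threshold(volume, config$threshold_range)
  stages$threshold <- stage_stats("threshold", th, conn)

  mask01 <- erode(th, se_ball(config$erosion_radius))
  stages$MASK_01 <- stage_stats("MASK_01", mask01, conn)

  destretched <- remove_stretcher_first_slice(
    mask01,
    fill_radius = config$fill_radius,
    fill_iterations = config$fill_iterations,
    thin_ratio = config$thin_ratio,
    connectivity = conn
  )

  restored <- dilate(destretched, se_ball(config$restore_dilate_radius))
  lm <- label_components(restored, connectivity = conn)
  comp <- lm$components
  keep_small <- comp$voxel_count >= config$min_component_voxels
  keep_border <- !(comp$extent_x == volume$size[1] |
    comp$extent_y == volume$size[2])
  mask02 <- labelmap_keep(lm, comp$label[keep_small & keep_border])
  stages$MASK_02 <- stage_stats("MASK_02", mask02, conn, per_component = TRUE)

  if (!any(mask02$voxels)) {
    cond <- structure(
      class = c("no_lung_candidate", "error", "condition"),
      list(
        message = "no lung candidate found",
        call = NULL,
        report = list(config = unclass(config), stages = unname(stages))
      )
    )
    stop(cond)
  }

  res01 <- mask_apply(volume, mask02, outside_value = config$outside_value)
  mask03 <- refine_mask(res01, config)
  stages$MASK_03 <- stage_stats("MASK_03", mask03, conn)

  region <- close_mask(mask03, se_ball(config$region_close_radius))
  bright <- binary_mask(volume$voxels > config$vessel_threshold,
    spacing = volume$spacing, origin = volume$origin
  )
  vessels <- mask_and(mask_subtract(region, mask03), bright)
  lung_with_vessels <- mask_or(mask03, vessels)
  stages$lung_with_vessels <- stage_stats(
    "lung_with_vessels", lung_with_vessels, conn
  )

  masked <- mask_apply(volume, mask03, outside_value = config$outside_value)
  hist <- hounsfield_histogram(volume, mask03,
    bin_width = config$histogram_bin_width
  )

  structure(
    list(
      mask_lung_with_vessels = lung_with_vessels,
      mask_lung_only = mask03,
      mask_vessels_only = vessels,
      masked_volume = masked,
      histogram = hist,
      stage_masks = list(
        threshold = th, MASK_01 = mask01, MASK_02 = mask02, MASK_03 = mask03
      ),
      report = list(config = unclass(config), stages = unname(stages))
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<segmentation_result> lung+vessels %d voxels",
      " (air %d, vessels %d)\n"
    ),
    sum(x$mask_lung_with_vessels$voxels),
    sum(x$mask_lung_only$voxels),
    sum(x$mask_vessels_only$voxels)
  ))
  invisible(x)
}

#' Refine a coarse masked volume into a tight air mask
#'
#' Re-thresholds a masked volume (`RES_01`) to the air range, then applies
#' a dilation--erosion pair that repairs edge raggedness. The coarse mask
#' produced by the opening stage overhangs the true air boundary slightly;
#' re-thresholding trims the overhang, and the small closing smooths the
#' result without absorbing vessel-caliber structures. The refined
#' foreground is always contained in the dilated envelope of the
#' re-thresholded set.
#'
#' @param res a masked [ct_volume] (outside voxels at the configured
#'   `outside_value`).
#' @param config a [lung_pipeline_config].
#' @return A [binary_mask] (`MASK_03`).
#' @export
refine_mask <- function(res, config = lung_pipeline_config()) {
  stopifnot(inherits(res, "ct_volume"))
  th <- hu_threshold(res, config$threshold_range)
  erode(
    dilate(th, se_ball(config$refine_dilate_radius)),
    se_ball(config$refine_erode_radius)
  )
}

#' Histogram of masked Hounsfield values
#'
#' Counts the masked voxels in fixed-width HU bins covering the observed
#' range. The counts always sum to the mask's foreground size; an empty
#' mask yields an empty (zero-row) histogram.
#'
#' @param volume a [ct_volume].
#' @param mask a [binary_mask] on the same grid.
#' @param bin_width bin width in HU; bin edges are multiples of it.
#' @return A data.frame with columns `bin_start`, `bin_end` (bins are
#'   `[start, end)`) and `count`.
#' @export
hounsfield_histogram <- function(volume, mask, bin_width = 10) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(volume, mask)
  stopifnot(bin_width > 0)
  vals <- volume$voxels[mask$voxels]
  if (length(vals) == 0) {
    return(data.frame(
      bin_start = numeric(0), bin_end = numeric(0),
      count = integer(0)
    ))
  }
  lo <- floor(min(vals) / bin_width)
  bins <- floor(vals / bin_width) - lo + 1
  counts <- tabulate(bins, nbins = max(bins))
  starts <- (lo + seq_along(counts) - 1) * bin_width
  data.frame(
    bin_start = starts, bin_end = starts + bin_width,
    count = as.integer(counts)
  )
}

#' Write a per-slice PNG overlay sequence
#'
#' Renders every axial slice as windowed grayscale with the mask blended in
#' a highlight color, one PNG per slice, zero-padded by slice index. The
#' rendering is deterministic: rerunning on identical input produces
#' byte-identical files. Useful for eyeballing a segmentation slice by
#' slice.
#'
#' @param volume a [ct_volume].
#' @param mask a [binary_mask] on the same grid.
#' @param out_dir output directory (created if missing).
#' @param window_center,window_width HU display window (defaults are a
#'   standard lung window).
#' @param color highlight RGB in `[0, 1]`.
#' @param alpha highlight opacity.
#' @return The vector of file paths written, invisibly.
#' @export
overlay_sequence <- function(volume, mask, out_dir,
                             window_center = -600, window_width = 1500,
                             color = c(1, 0.25, 0.25), alpha = 0.45) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(volume, mask)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nz <- volume$size[3]
  width <- max(3L, nchar(as.character(nz - 1)))
  fmt <- paste0("%0", width, "d.png")
  lo <- window_center - window_width / 2
  paths <- character(nz)
  for (k in seq_len(nz)) {
    gray <- (volume$voxels[, , k] - lo) / window_width
    gray[gray < 0] <- 0
    gray[gray > 1] <- 1
    m <- mask$voxels[, , k]
    img <- array(0, c(volume$size[2], volume$size[1], 3))
    for (ch in 1:3) {
      plane <- gray
      plane[m] <- (1 - alpha) * gray[m] + alpha * color[ch]
      img[, , ch] <- t(plane)
    }
    paths[k] <- file.path(out_dir, sprintf(fmt, k - 1))
    png::writePNG(img, paths[k])
  }
  invisible(paths)
}
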