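#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value` (comments with `#`) whose keys are the
#' argument names of [lung_pipeline_config]; `threshold_range` takes two
#' numbers separated by a comma or whitespace. Unknown keys are an error.
#'
#' @param path configuration file path.
#' @return A [lung_pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- names(formals(lung_pipeline_config))
  args <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("bad config line: ", ln, call. = FALSE)
    key <- kv[2]
    if (!key %in% known) stop("unknown config key: ", key, call. = FALSE)
    vals <- as.numeric(strsplit(trimws(kv[3]), "[,\\s]+")[[1]])
    if (anyNA(vals)) stop("bad config value for ", key, call. = FALSE)
    args[[key]] <- vals
  }
  do.call(lung_pipeline_config, args)
}

ctlungseg_error <- function(class, message) {
  structure(
    class = c(class, "error", "condition"),
    list(message = message, call = NULL)
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

file_md5 <- function(paths) {
  unname(tools::md5sum(paths))
}

#' Run the full segmentation workflow on a CT input
#'
#' Reads a CT volume (a DICOM series directory or an NRRD/MHA file), runs
#' [segment_lungs], reconstructs the lung-with-vessels surface
#' ([extract_isosurface] -> [decimate_mesh] -> [laplacian_smooth]) and
#' writes the full artifact bundle into `out_dir`:
#' `lung_with_vessels.nrrd`, `lung_only.nrrd`, `vessels_only.nrrd`,
#' `masked_volume.mha`, `histogram.csv`, `overlay/NNN.png`, `report.json`,
#' `lung_with_vessels.obj`, `lung_with_vessels.stl` and `manifest.json`.
#' All outputs except the manifest (which carries timestamps) are
#' bit-reproducible for identical input and configuration.
#'
#' @param input path to a DICOM directory or an NRRD/MHA file.
#' @param out_dir output directory (created if missing).
#' @param config a [lung_pipeline_config].
#' @param config_file optional path to a [read_pipeline_config] file;
#'   overrides `config` when given.
#' @param mesh write OBJ/STL surface reconstructions.
#' @param mesh_reduction decimation fraction for the exported mesh.
#' @param smooth_iterations,smooth_relaxation smoothing parameters for the
#'   exported mesh.
#' @param overlay write the per-slice PNG overlay sequence.
#' @return The run manifest (named list), invisibly. The manifest lists
#'   every output file with its md5 checksum.
#' @export
run_segment <- function(input, out_dir,
                        config = lung_pipeline_config(),
                        config_file = NULL,
                        mesh = TRUE, mesh_reduction = 0.5,
                        smooth_iterations = 20, smooth_relaxation = 0.1,
                        overlay = TRUE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  if (!is.null(config_file)) config <- read_pipeline_config(config_file)

  volume <- tryCatch(
    {
      if (dir.exists(input)) {
        read_dicom_series(input)
      } else {
        read_volume(input)
      }
    },
    error = function(e) {
      if (inherits(e, "ctlungseg_input_error")) stop(e)
      stop(ctlungseg_error(
        "ctlungseg_input_error",
        paste0("unreadable input: ", conditionMessage(e))
      ))
    }
  )

  result <- segment_lungs(volume, config)

  out <- tryCatch(
    {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c(
        lung_with_vessels = file.path(out_dir, "lung_with_vessels.nrrd"),
        lung_only = file.path(out_dir, "lung_only.nrrd"),
        vessels_only = file.path(out_dir, "vessels_only.nrrd"),
        masked_volume = file.path(out_dir, "masked_volume.mha"),
        histogram = file.path(out_dir, "histogram.csv"),
        report = file.path(out_dir, "report.json")
      )
      write_volume(result$mask_lung_with_vessels, paths[["lung_with_vessels"]])
      write_volume(result$mask_lung_only, paths[["lung_only"]])
      write_volume(result$mask_vessels_only, paths[["vessels_only"]])
      write_volume(result$masked_volume, paths[["masked_volume"]])
      utils::write.csv(result$histogram, paths[["histogram"]],
        row.names = FALSE
      )
      write_json_file(result$report, paths[["report"]])
      paths <- unname(paths)
      if (overlay) {
        paths <- c(paths, overlay_sequence(
          volume, result$mask_lung_with_vessels,
          file.path(out_dir, "overlay")
        ))
      }
      if (mesh) {
        surf <- extract_isosurface(result$mask_lung_with_vessels)
        surf <- decimate_mesh(surf, target_reduction = mesh_reduction)
        surf <- laplacian_smooth(surf,
          iterations = smooth_iterations,
          relaxation = smooth_relaxation
        )
        obj <- file.path(out_dir, "lung_with_vessels.obj")
        stl <- file.path(out_dir, "lung_with_vessels.stl")
        export_mesh(surf, obj)
        export_mesh(surf, stl)
        paths <- c(paths, obj, stl)
      }
      paths
    },
    error = function(e) {
      stop(ctlungseg_error(
        "ctlungseg_write_error",
        paste0("write failure: ", conditionMessage(e))
      ))
    }
  )

  manifest <- list(
    tool = "ctlungseg",
    tool_version = as.character(utils::packageVersion("ctlungseg")),
    input_path = normalizePath(input),
    config = list(
      pipeline = unclass(config),
      mesh = list(
        enabled = mesh, reduction = mesh_reduction,
        smooth_iterations = smooth_iterations,
        smooth_relaxation = smooth_relaxation
      )
    ),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    outputs = data.frame(
      path = basename_rel(out, out_dir),
      md5 = file_md5(out),
      stringsAsFactors = FALSE
    )
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

basename_rel <- function(paths, root) {
  root <- normalizePath(root)
  vapply(paths, function(p) {
    sub("^/+", "", sub(root, "", normalizePath(p), fixed = TRUE))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate and write a phantom dataset
#'
#' Generates the phantom described by `spec`, writes it as a DICOM series
#' (`dicom/slice_NNN.dcm`) plus the noiseless ground-truth masks as NRRD
#' (`truth_lung.nrrd`, `truth_lung_air.nrrd`, `truth_vessels.nrrd`,
#' `truth_stretcher.nrrd`) and the volume as `volume.nrrd`, and records a
#' manifest with checksums. The seed used is printed.
#'
#' @param out_dir output directory.
#' @param spec a [phantom_spec].
#' @return The run manifest, invisibly.
#' @export
run_phantom <- function(out_dir, spec = phantom_spec()) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  ph <- generate_phantom(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dcm <- write_phantom_dicom(ph, file.path(out_dir, "dicom"))
  paths <- c(
    file.path(out_dir, "volume.nrrd"),
    file.path(out_dir, "truth_lung.nrrd"),
    file.path(out_dir, "truth_lung_air.nrrd"),
    file.path(out_dir, "truth_vessels.nrrd"),
    file.path(out_dir, "truth_stretcher.nrrd")
  )
  write_volume(ph$volume, paths[1])
  write_volume(ph$truth_lung, paths[2])
  write_volume(ph$truth_lung_air, paths[3])
  write_volume(ph$truth_vessels, paths[4])
  write_volume(ph$truth_stretcher, paths[5])
  paths <- c(paths, dcm)
  message("phantom seed: ", spec$seed)
  manifest <- list(
    tool = "ctlungseg",
    tool_version = as.character(utils::packageVersion("ctlungseg")),
    config = list(phantom = unclass(spec)),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    outputs = data.frame(
      path = basename_rel(paths, out_dir),
      md5 = file_md5(paths),
      stringsAsFactors = FALSE
    )
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
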