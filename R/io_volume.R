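#' Read a 3D volume from NRRD or MHA
#'
#' Supports the dialects this package writes plus the common axis-aligned
#' cases: NRRD (raw or gzip encoding, little endian, integer or floating
#' point types) and MetaImage `.mha` with local uncompressed data. Spacing
#' and origin are taken from the header. Axis-aligned direction flips are
#' normalized by flipping the voxel array (with the origin moved
#' accordingly); oblique orientations are rejected.
#'
#' @param path path to a `.nrrd` or `.mha`/`.mhd` file.
#' @return A [ct_volume]. Masks written by [write_volume] come back as 0/1
#'   volumes; use `read_mask()` to reconstruct a [binary_mask].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    read_nrrd(path)
  } else if (ext %in% c("mha", "mhd")) {
    read_mha(path)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$voxels != 0, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to NRRD or MHA
#'
#' All slices are stored in a single container together with spacing and
#' origin, so that segmentations produced independently overlay in their
#' correct spatial positions. Masks are stored as 8-bit 0/1; integer HU
#' volumes within the signed 16-bit range as `int16` (lossless round-trip);
#' anything else as `double`. NRRD data is gzip-encoded; MHA data is raw.
#'
#' @param x a [ct_volume] or [binary_mask].
#' @param path output path.
#' @param format `"nrrd"` or `"mha"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, format = NULL) {
  stopifnot(inherits(x, c("ct_volume", "binary_mask")))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("nrrd", "mha"))
  is_mask <- inherits(x, "binary_mask")
  vox <- x$voxels
  if (is_mask) {
    type <- "uint8"
    data <- as.integer(vox)
  } else if (all(vox == round(vox)) && min(vox) >= -32768 && max(vox) <= 32767) {
    type <- "int16"
    data <- as.integer(vox)
  } else {
    type <- "double"
    data <- as.double(vox)
  }
  if (format == "nrrd") {
    write_nrrd(path, data, type, dim(vox), x$spacing, x$origin)
  } else {
    write_mha(path, data, type, dim(vox), x$spacing, x$origin)
  }
  invisible(path)
}

nrrd_type_table <- list(
  int8 = list(size = 1L, signed = TRUE, what = "integer"),
  uint8 = list(size = 1L, signed = FALSE, what = "integer"),
  int16 = list(size = 2L, signed = TRUE, what = "integer"),
  uint16 = list(size = 2L, signed = FALSE, what = "integer"),
  int32 = list(size = 4L, signed = TRUE, what = "integer"),
  uint32 = list(size = 4L, signed = FALSE, what = "integer"),
  float = list(size = 4L, signed = TRUE, what = "double"),
  double = list(size = 8L, signed = TRUE, what = "double")
)

normalize_nrrd_type <- function(t) {
  t <- tolower(t)
  map <- c(
    "signed char" = "int8", "uchar" = "uint8", "unsigned char" = "uint8",
    "short" = "int16", "signed short" = "int16", "short int" = "int16",
    "ushort" = "uint16", "unsigned short" = "uint16",
    "int" = "int32", "signed int" = "int32",
    "uint" = "uint32", "unsigned int" = "uint32"
  )
  if (t %in% names(map)) map[[t]] else t
}

write_nrrd <- function(path, data, type, size, spacing, origin) {
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(size, collapse = " ")),
    "space dimension: 3",
    sprintf(
      "space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
      spacing[1], spacing[2], spacing[3]
    ),
    sprintf(
      "space origin: (%.9g,%.9g,%.9g)",
      origin[1], origin[2], origin[3]
    ),
    "endian: little",
    "encoding: gzip",
    ""
  )
  tt <- nrrd_type_table[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  payload <- writeBin(data, raw(), size = tt$size, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

# split "(a,b,c) (d,e,f) ..." into a list of numeric vectors
parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) {
    as.numeric(strsplit(gsub("[()]", "", v), "[, ]+")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic)) {
    stop("not a NRRD file: ", path, call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) break
    line <- sub("\r$", "", line)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (!is.null(fields$dimension) && as.integer(fields$dimension) != 3) {
    stop("unsupported dimensionality", call. = FALSE)
  }
  size <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(size) != 3) stop("unsupported dimensionality", call. = FALSE)
  type <- normalize_nrrd_type(fields$type)
  tt <- nrrd_type_table[[type]]
  if (is.null(tt)) stop("unsupported NRRD type: ", fields$type, call. = FALSE)
  encoding <- tolower(fields$encoding %||% "raw")
  endian <- tolower(fields$endian %||% "little")

  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  dirmat <- NULL
  if (!is.null(fields$`space directions`)) {
    dirs <- parse_nrrd_vectors(fields$`space directions`)
    dirmat <- do.call(cbind, dirs)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields$`space origin`)) {
    origin <- parse_nrrd_vectors(fields$`space origin`)[[1]]
  }

  payload <- readBin(con, raw(), n = file.info(path)$size)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  n <- prod(size)
  data <- readBin(payload, tt$what,
    n = n, size = tt$size, signed = tt$signed,
    endian = if (endian == "big") "big" else "little"
  )
  if (length(data) < n) stop("truncated NRRD data", call. = FALSE)
  vox <- array(as.double(data), dim = size)

  if (!is.null(dirmat)) {
    g <- normalize_axis_aligned(vox, dirmat, origin)
    vox <- g$voxels
    spacing <- g$spacing
    origin <- g$origin
  }
  ct_volume(vox, spacing = spacing, origin = origin)
}

# Reduce an axis-aligned direction matrix to positive-diagonal form by
# permuting and flipping the voxel array; oblique matrices are rejected.
normalize_axis_aligned <- function(vox, dirmat, origin) {
  nz <- abs(dirmat) > 1e-9
  if (any(colSums(nz) != 1) || any(rowSums(nz) != 1)) {
    stop("oblique orientation not supported", call. = FALSE)
  }
  axis_of <- apply(nz, 2, which) # world axis addressed by each voxel axis
  perm <- order(axis_of)
  vox <- aperm(vox, perm)
  dirmat <- dirmat[, perm, drop = FALSE]
  size <- dim(vox)
  spacing <- numeric(3)
  for (a in 1:3) {
    d <- dirmat[a, a]
    spacing[a] <- abs(d)
    if (d < 0) {
      idx <- rev(seq_len(size[a]))
      vox <- switch(a,
        vox[idx, , , drop = FALSE],
        vox[, idx, , drop = FALSE],
        vox[, , idx, drop = FALSE]
      )
      origin[a] <- origin[a] + d * (size[a] - 1)
    }
  }
  list(voxels = vox, spacing = spacing, origin = origin)
}

mha_type_table <- c(
  MET_CHAR = "int8", MET_UCHAR = "uint8", MET_SHORT = "int16",
  MET_USHORT = "uint16", MET_INT = "int32", MET_UINT = "uint32",
  MET_FLOAT = "float", MET_DOUBLE = "double"
)

write_mha <- function(path, data, type, size, spacing, origin) {
  met <- names(mha_type_table)[match(type, mha_type_table)]
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste0("Offset = ", paste(sprintf("%.9g", origin), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste0("ElementSpacing = ", paste(sprintf("%.9g", spacing), collapse = " ")),
    paste0("DimSize = ", paste(size, collapse = " ")),
    paste0("ElementType = ", met),
    "ElementDataFile = LOCAL"
  )
  tt <- nrrd_type_table[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(data, con, size = tt$size, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("truncated MHA header", call. = FALSE)
    line <- sub("\r$", "", line)
    kv <- regmatches(line, regexec("^([^=]+)=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
    if (!is.null(fields$ElementDataFile)) break
  }
  if (!identical(fields$ElementDataFile, "LOCAL")) {
    stop("only local MHA data supported", call. = FALSE)
  }
  if (!is.null(fields$CompressedData) &&
    toupper(fields$CompressedData) == "TRUE") {
    stop("compressed MHA not supported", call. = FALSE)
  }
  if (as.integer(fields$NDims) != 3) {
    stop("unsupported dimensionality", call. = FALSE)
  }
  size <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  if (length(size) != 3) stop("unsupported dimensionality", call. = FALSE)
  type <- mha_type_table[[fields$ElementType]]
  if (is.null(type)) {
    stop("unsupported element type: ", fields$ElementType, call. = FALSE)
  }
  tt <- nrrd_type_table[[type]]
  big <- !is.null(fields$BinaryDataByteOrderMSB) &&
    toupper(fields$BinaryDataByteOrderMSB) == "TRUE"
  n <- prod(size)
  data <- readBin(con, tt$what,
    n = n, size = tt$size, signed = tt$signed,
    endian = if (big) "big" else "little"
  )
  if (length(data) < n) stop("truncated MHA data", call. = FALSE)
  spacing <- as.numeric(strsplit(fields$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields$Offset %||% "0 0 0", "\\s+")[[1]])
  vox <- array(as.double(data), dim = size)
  if (!is.null(fields$TransformMatrix)) {
    tm <- matrix(as.numeric(strsplit(fields$TransformMatrix, "\\s+")[[1]]), 3, 3)
    dirmat <- tm %*% diag(spacing)
    g <- normalize_axis_aligned(vox, dirmat, origin)
    vox <- g$voxels
    spacing <- g$spacing
    origin <- g$origin
  }
  ct_volume(vox, spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
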