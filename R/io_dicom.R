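# Minimal DICOM support for single-frame CT slices.
#
# Scope: Part-10 files with the little-endian transfer syntaxes (explicit
# and implicit VR), single-frame MONOCHROME2 images with 16-bit pixel data.
# This covers typical clinical thoracic CT series and the files this
# package writes;
# multiframe/enhanced objects and network services are out of scope.

dcm_uid_ct_storage <- "1.2.840.10008.5.1.4.1.1.2"
dcm_uid_explicit_le <- "1.2.840.10008.1.2.1"
dcm_uid_implicit_le <- "1.2.840.10008.1.2"

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad_even <- function(value, pad = as.raw(0)) {
  if (length(value) %% 2 == 1) c(value, pad) else value
}

# Encode one data element in explicit VR little endian.
dcm_elem <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    value <- dcm_pad_even(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), u32le(length(value)), value)
  } else {
    c(head, u16le(length(value)), value)
  }
}

# Write one single-frame CT slice. `pixels` is an nx x ny integer matrix of
# stored values (x = column index, fastest); HU = slope * stored + intercept.
dicom_write_slice <- function(path, pixels, slope, intercept,
                              position, pixel_spacing,
                              series_uid, sop_uid, instance_number) {
  nx <- nrow(pixels)
  ny <- ncol(pixels)
  stored <- as.integer(pixels)
  if (min(stored) < -32768 || max(stored) > 32767) {
    stop("stored values exceed int16", call. = FALSE)
  }
  pixel_raw <- writeBin(stored, raw(), size = 2, endian = "little")

  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_uid_ct_storage),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    dcm_elem(0x0020, 0x000E, "UI", series_uid),
    dcm_elem(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_elem(0x0020, 0x0032, "DS", paste(sprintf("%.8g", position),
      collapse = "\\"
    )),
    dcm_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_elem(0x0028, 0x0002, "US", u16le(1)),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0010, "US", u16le(ny)), # Rows
    dcm_elem(0x0028, 0x0011, "US", u16le(nx)), # Columns
    dcm_elem(0x0028, 0x0030, "DS", sprintf(
      "%.8g\\%.8g",
      pixel_spacing[2], pixel_spacing[1] # row spacing, then column spacing
    )),
    dcm_elem(0x0028, 0x0100, "US", u16le(16)),
    dcm_elem(0x0028, 0x0101, "US", u16le(16)),
    dcm_elem(0x0028, 0x0102, "US", u16le(15)),
    dcm_elem(0x0028, 0x0103, "US", u16le(1)), # signed
    dcm_elem(0x0028, 0x1052, "DS", sprintf("%.8g", intercept)),
    dcm_elem(0x0028, 0x1053, "DS", sprintf("%.8g", slope)),
    dcm_elem(0x7FE0, 0x0010, "OW", pixel_raw)
  )

  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", dcm_uid_ct_storage),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", dcm_uid_explicit_le),
    dcm_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7156.1")
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", u32le(length(meta))), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(ds, con)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UN", "UT", "UC", "UR")

rd_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}
rd_u32 <- function(bytes, at) {
  as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1L]) +
    65536 * as.integer(bytes[at + 2L]) + 16777216 * as.integer(bytes[at + 3L])
}

# Skip over an undefined-length value (sequence or item); returns the offset
# just past the matching delimiter.
dcm_skip_undefined <- function(bytes, at) {
  repeat {
    if (at + 7 > length(bytes)) stop("truncated sequence", call. = FALSE)
    group <- rd_u16(bytes, at)
    element <- rd_u16(bytes, at + 2L)
    len <- rd_u32(bytes, at + 4L)
    at <- at + 8L
    if (group == 0xFFFE && element == 0xE0DD) {
      return(at)
    } # sequence delimiter
    if (group == 0xFFFE && element == 0xE00D) {
      return(at)
    } # item delimiter
    if (len == 0xFFFFFFFF) {
      at <- dcm_skip_undefined(bytes, at)
    } else {
      at <- at + len
    }
  }
}

# Parse a data-element stream; returns a list keyed by "GGGG,EEEE" with raw
# values. `explicit` selects the VR encoding.
dcm_parse_elements <- function(bytes, at, explicit, stop_group = NULL) {
  out <- list()
  n <- length(bytes)
  while (at + 7L <= n) {
    group <- rd_u16(bytes, at)
    element <- rd_u16(bytes, at + 2L)
    if (!is.null(stop_group) && group != stop_group) break
    vr <- NULL
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
      if (vr %in% dcm_long_vrs) {
        len <- rd_u32(bytes, at + 8L)
        at <- at + 12L
      } else {
        len <- rd_u16(bytes, at + 6L)
        at <- at + 8L
      }
    } else {
      len <- rd_u32(bytes, at + 4L)
      at <- at + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    if (len == 0xFFFFFFFF) {
      at <- dcm_skip_undefined(bytes, at)
      next
    }
    if (len > 0) {
      if (at + len - 1 > n) stop("truncated DICOM element", call. = FALSE)
      out[[key]] <- bytes[at:(at + len - 1L)]
    } else {
      out[[key]] <- raw(0)
    }
    at <- at + len
  }
  attr(out, "end") <- at
  out
}

dcm_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) {
    return(NULL)
  }
  trimws(rawToChar(v[v != as.raw(0)]))
}
dcm_num <- function(el, key) {
  s <- dcm_str(el, key)
  if (is.null(s) || s == "") {
    return(NULL)
  }
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) {
    return(NULL)
  }
  readBin(v, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}

# Parse one DICOM file into the handful of attributes the reader needs.
dicom_read_slice <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140) stop("not a DICOM file", call. = FALSE)
  at <- 1L
  explicit <- TRUE
  if (rawToChar(bytes[129:132]) == "DICM") {
    meta <- dcm_parse_elements(bytes, 133L, explicit = TRUE, stop_group = 2L)
    ts <- dcm_str(meta, "0002,0010") %||% dcm_uid_explicit_le
    at <- attr(meta, "end")
    if (ts == dcm_uid_implicit_le) {
      explicit <- FALSE
    } else if (ts != dcm_uid_explicit_le) {
      stop("unsupported transfer syntax: ", ts, call. = FALSE)
    }
  } else {
    # raw dataset without preamble: guess VR encoding from the first element
    vr_guess <- rawToChar(bytes[5:6])
    explicit <- grepl("^[A-Z]{2}$", vr_guess)
  }
  el <- dcm_parse_elements(bytes, at, explicit = explicit)

  rows <- dcm_us(el, "0028,0010")
  cols <- dcm_us(el, "0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(el[["7FE0,0010"]])) {
    stop("not an image slice", call. = FALSE)
  }
  bits <- dcm_us(el, "0028,0100") %||% 16L
  if (bits != 16L) stop("only 16-bit pixel data supported", call. = FALSE)
  frames <- dcm_str(el, "0028,0008")
  if (!is.null(frames) && as.integer(frames) > 1) {
    stop("multiframe DICOM not supported", call. = FALSE)
  }
  signed <- (dcm_us(el, "0028,0103") %||% 0L) == 1L
  stored <- readBin(el[["7FE0,0010"]], "integer",
    n = rows * cols, size = 2,
    signed = signed, endian = "little"
  )
  if (!signed) stored <- as.integer(stored)
  list(
    pixels = matrix(stored, nrow = cols, ncol = rows), # x fastest
    rows = rows, cols = cols,
    slope = (dcm_num(el, "0028,1053") %||% 1)[1],
    intercept = (dcm_num(el, "0028,1052") %||% 0)[1],
    has_rescale = !is.null(el[["0028,1053"]]) || !is.null(el[["0028,1052"]]),
    position = dcm_num(el, "0020,0032"),
    orientation = dcm_num(el, "0020,0037"),
    pixel_spacing = dcm_num(el, "0028,0030"), # row spacing, column spacing
    series_uid = dcm_str(el, "0020,000E"),
    instance = dcm_str(el, "0020,0013")
  )
}

#' Read a CT series from a directory of DICOM slice files
#'
#' Reads every readable single-frame axial CT slice in `directory`, converts
#' stored values to Hounsfield units with each file's linear rescale
#' (`HU = slope * stored + intercept`), sorts slices by their spatial
#' position along the slice axis (never by filename), and infers the
#' inter-slice spacing from consecutive positions. Files that cannot be
#' parsed, non-axial slices (e.g. localizers) and slices without rescale
#' information are skipped with a warning. If the inter-slice gaps are not
#' uniform, a warning is issued and the median gap is used.
#'
#' @param directory path containing the slice files of one series.
#' @return A [ct_volume].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) {
    stop("no readable slices in ", directory, call. = FALSE)
  }
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(dicom_read_slice(f), error = function(e) NULL)
    if (is.null(s)) {
      warning("skipping unreadable file: ", basename(f), call. = FALSE)
      next
    }
    if (!is.null(s$orientation) &&
      any(abs(s$orientation - c(1, 0, 0, 0, 1, 0)) > 1e-3)) {
      warning("skipping non-axial slice: ", basename(f), call. = FALSE)
      next
    }
    if (!s$has_rescale) {
      warning("skipping slice without rescale tags: ", basename(f),
        call. = FALSE
      )
      next
    }
    slices[[length(slices) + 1]] <- s
  }
  if (length(slices) == 0) {
    stop("no readable slices in ", directory, call. = FALSE)
  }
  uids <- unique(vapply(
    slices, function(s) s$series_uid %||% "", character(1)
  ))
  if (length(uids) > 1) stop("mixed series", call. = FALSE)
  dims <- unique(t(vapply(slices, function(s) c(s$cols, s$rows), integer(2))))
  if (nrow(dims) > 1) stop("mixed series", call. = FALSE)

  z <- vapply(slices, function(s) {
    if (is.null(s$position)) NA_real_ else s$position[3]
  }, numeric(1))
  if (anyNA(z)) stop("slices lack position information", call. = FALSE)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]

  nz <- length(slices)
  dz <- if (nz > 1) diff(z) else 1
  zsp <- stats::median(dz)
  if (nz > 2 && any(abs(dz - zsp) > 1e-3 * max(abs(zsp), 1))) {
    warning("non-uniform inter-slice spacing; using the median (",
      signif(zsp, 6), " mm)",
      call. = FALSE
    )
  }
  if (zsp <= 0) zsp <- 1

  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    vox[, , k] <- s$slope * s$pixels + s$intercept
  }
  origin <- c(slices[[1]]$position[1:2], z[1])
  ct_volume(vox, spacing = c(ps[2], ps[1], zsp), origin = origin)
}
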