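#' Export a triangle mesh to OBJ or STL
#'
#' OBJ is written as ASCII `v`/`f` records with 1-based indices and vertex
#' coordinates in mm; STL is binary with consistent facet normals computed
#' from the winding. Re-importing with [read_mesh] reproduces the face set
#' exactly and vertex positions to well below 1e-4 mm.
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"obj"` or `"stl"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "stl"))
  if (format == "obj") {
    write_obj(mesh, path)
  } else {
    write_stl(mesh, path)
  }
  invisible(path)
}

write_obj <- function(mesh, path) {
  con <- file(path, "wb") # binary mode: LF endings on every platform
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(
    sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
    sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  )
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len

  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "ctlungseg binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  # 12 floats per facet (normal + 3 vertices) followed by a 2-byte attribute
  dat <- t(cbind(n, a, b, cc)) # 12 x m
  fr <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
  blocks <- rbind(
    matrix(fr, nrow = 48),
    matrix(as.raw(0), nrow = 2, ncol = nrow(f))
  )
  writeBin(as.vector(blocks), con)
  invisible(path)
}

#' Read a triangle mesh from OBJ or STL
#'
#' OBJ: `v` and `f` records (polygonal faces are fan-triangulated;
#' `f v/vt/vn` syntax is accepted, only vertex indices are used). Binary
#' STL: facets are read and identical vertex positions merged so the face
#' structure is recovered.
#'
#' @param path path to a `.obj` or `.stl` file.
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    read_obj(path)
  } else if (ext == "stl") {
    read_stl(path)
  } else {
    stop("unsupported mesh format: .", ext, call. = FALSE)
  }
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
    function(p) as.numeric(p[1:3])
  ))
  faces <- do.call(rbind, lapply(
    strsplit(trimws(sub("^f", "", flines)), "\\s+"),
    function(p) {
      idx <- as.integer(vapply(strsplit(p, "/"), `[`, character(1), 1))
      if (length(idx) < 3) stop("bad OBJ face", call. = FALSE)
      # fan-triangulate polygons
      cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
    }
  ))
  triangle_mesh(v, faces)
}

read_stl <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 84) stop("not a binary STL", call. = FALSE)
  m <- readBin(bytes[81:84], "integer", size = 4, endian = "little")
  need <- 84 + m * 50
  if (length(bytes) < need) stop("truncated STL", call. = FALSE)
  body <- matrix(bytes[85:(84 + 50 * m)], nrow = 50)
  fl <- readBin(as.vector(body[1:48, , drop = FALSE]), "numeric",
    n = 12 * m, size = 4, endian = "little"
  )
  tri <- t(matrix(fl, nrow = 12)[4:12, , drop = FALSE])
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- !duplicated(key)
  verts <- pts[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- cbind(idx[1:m], idx[m + (1:m)], idx[2 * m + (1:m)])
  triangle_mesh(verts, faces)
}
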