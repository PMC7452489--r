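# Surface-mesh file input/output: STL (ASCII and binary), OBJ, PLY (ASCII).
# All coordinates are millimetres. STL stores bare triangle soups, so
# reading merges coincident vertices to rebuild shared topology.

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' The format is chosen by file extension. STL files may be ASCII or
#' binary (auto-detected); PLY must be ASCII.
#'
#' @param path file path ending in `.stl`, `.ply` or `.obj`
#' @return a [trimesh()]
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  switch(tolower(tools::file_ext(path)),
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop(sprintf("unknown mesh extension '.%s' (use .stl, .ply or .obj)",
                 tools::file_ext(path)))
  )
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a [trimesh()]
#' @param path output path; extension selects the format
#' @param binary write binary STL instead of ASCII (STL only)
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  switch(tolower(tools::file_ext(path)),
    stl = write_stl(mesh, path, binary = binary),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stop(sprintf("unknown mesh extension '.%s' (use .stl, .ply or .obj)",
                 tools::file_ext(path)))
  )
  invisible(path)
}

is_binary_stl <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary iff the declared triangle count matches the file size
  identical(as.numeric(n), 84 + 50 * as.numeric(ntri)) ||
    (n >= 84 + 50 * ntri && !grepl("^solid", rawToChar(header[1:5])))
}

read_stl <- function(path) {
  if (file.size(path) == 0) stop(sprintf("parse error in %s: empty file", path))
  tri <- if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  soup_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop(sprintf("parse error in %s: expected vertex triples, found %d vertex lines",
                 path, length(vl)))
  }
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(toks, function(x) as.numeric(x[2:4]), numeric(3))
  if (anyNA(coords)) {
    bad <- which(colSums(is.na(coords)) > 0)[1]
    stop(sprintf("parse error in %s: non-numeric vertex at vertex line %d", path, bad))
  }
  t(coords)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", 50 * ntri)
  if (length(rec) < 50 * ntri) stop(sprintf("parse error in %s: truncated binary STL", path))
  rec <- matrix(rec, nrow = 50)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4, n = 12 * ntri,
                  endian = "little")
  vals <- matrix(vals, nrow = 12)       # per triangle: normal, v1, v2, v3
  do.call(rbind, lapply(seq_len(ntri), function(i) {
    matrix(vals[4:12, i], ncol = 3, byrow = TRUE)
  }))
}

# Merge exactly-coincident vertices of a triangle soup (3k x 3 matrix).
soup_to_mesh <- function(tri) {
  key <- apply(tri, 1, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  trimesh(tri[first, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE) {
  fg <- face_geometry(mesh, orient = "winding")
  v1 <- face_corner(mesh, 1); v2 <- face_corner(mesh, 2); v3 <- face_corner(mesh, 3)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(mesh$faces))) {
      writeBin(as.numeric(c(fg$normals[i, ], v1[i, ], v2[i, ], v3[i, ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    out <- character(7 * nrow(mesh$faces) + 2)
    out[1] <- "solid mesh"
    k <- 2
    for (i in seq_len(nrow(mesh$faces))) {
      out[k:(k + 6)] <- c(
        sprintf("  facet normal %.9g %.9g %.9g",
                fg$normals[i, 1], fg$normals[i, 2], fg$normals[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", v1[i, 1], v1[i, 2], v1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", v2[i, 1], v2[i, 2], v2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", v3[i, 1], v3[i, 2], v3[i, 3]),
        "    endloop",
        "  endfacet")
      k <- k + 7
    }
    out[k] <- "endsolid mesh"
    writeLines(out, path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop(sprintf("parse error in %s: empty file", path))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) {
    stop(sprintf("parse error in %s: no vertices or faces", path))
  }
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    # tokens may be "i", "i/j", "i//k" or "i/j/k"; the vertex index leads
    as.integer(sub("/.*$", "", x[2:4]))
  }, integer(3)))
  if (anyNA(v)) stop(sprintf("parse error in %s: non-numeric vertex", path))
  if (anyNA(f)) stop(sprintf("parse error in %s: malformed face line", path))
  trimesh(v, f)
}

write_obj <- function(mesh, path) {
  writeLines(c(
    sprintf("v %.9g %.9g %.9g",
            mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  ), path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop(sprintf("parse error in %s: empty file", path))
  if (!grepl("^ply", lines[1])) stop(sprintf("parse error in %s: missing ply magic", path))
  if (any(grepl("format\\s+binary", lines[1:min(10, length(lines))]))) {
    stop(sprintf("parse error in %s: binary PLY is not supported; export ASCII", path))
  }
  endh <- grep("^end_header", lines)[1]
  if (is.na(endh)) stop(sprintf("parse error in %s: no end_header", path))
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "", grep("element\\s+vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "", grep("element\\s+face", lines, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop(sprintf("parse error in %s: truncated body", path))
  v <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(x) {
    if (as.integer(x[1]) != 3) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L          # PLY indices are 0-based on disk
  }, integer(3)))
  trimesh(v, f)
}

write_ply <- function(mesh, path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header",
    sprintf("%.9g %.9g %.9g",
            mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
    sprintf("3 %d %d %d",
            mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  ), path)
  invisible(path)
}
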