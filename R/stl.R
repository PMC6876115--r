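# STL (standard tessellation language) I/O. Units are millimetres by
# convention of this package; STL itself carries none, so the header/solid
# name records "units=mm".

#' Read an STL file (binary or ASCII)
#'
#' The dialect is auto-detected: a file is taken as binary when its size
#' matches the 84 + 50 n byte layout implied by its triangle-count field;
#' otherwise it is parsed as ASCII. Vertices identical in all three float32
#' coordinates are merged so the result is an indexed mesh with shared
#' topology.
#'
#' @param path file path.
#' @param name mesh label; defaults to the file name.
#' @return a [triangle_mesh].
#' @export
read_stl <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("STL file not found: %s", path))
  size <- file.info(path)$size
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    header <- readBin(con, "raw", 80)
    n_tri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n_tri) && n_tri >= 0 && size == 84 + 50 * as.double(n_tri)) {
      return(read_stl_binary(con, n_tri, name))
    }
    close(con)
    on.exit()
  } else if (size < 15) {
    stop(sprintf("malformed STL '%s': truncated at byte %d (binary needs >= 84 bytes, ASCII needs a 'solid' header)",
                 path, size))
  }
  read_stl_ascii(path, name)
}

read_stl_binary <- function(con, n_tri, name) {
  # each record: normal (3 x float32), 3 vertices (9 x float32), uint16 attr
  raw <- readBin(con, "raw", n = 50 * n_tri)
  if (length(raw) != 50 * n_tri)
    stop(sprintf("malformed binary STL: expected %d triangle records, data ends at byte %d",
                 n_tri, 84 + length(raw)))
  rec <- matrix(raw, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12 * n_tri,
                    size = 4, endian = "little")
  m <- matrix(floats, nrow = 12)
  tris <- t(m[4:12, , drop = FALSE])  # drop the stored normal; recomputed
  soup_to_mesh(tris, name)
}

read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*solid", lines[1]))
    stop(sprintf("malformed ASCII STL '%s': line 1 does not start with 'solid'", path))
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL '%s': vertex count %d is not a multiple of 3 (last vertex at line %d)",
                 path, length(vl), if (length(vl)) vl[length(vl)] else 1L))
  if (length(vl) == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), name))
  txt <- sub("^\\s*vertex\\s+", "", lines[vl])
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))))
  if (length(vals) != 3 * length(vl) || anyNA(vals))
    stop(sprintf("malformed ASCII STL '%s': non-numeric vertex coordinates near line %d",
                 path, vl[which(is.na(matrix(vals, ncol = 3, byrow = TRUE)[, 1]))[1]]))
  coords <- matrix(vals, ncol = 3, byrow = TRUE)
  tris <- matrix(t(coords), ncol = 9, byrow = TRUE)
  soup_to_mesh(tris, name)
}

float32_quantize <- function(x) {
  dims <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4, endian = "little"),
               "numeric", n = length(x), size = 4, endian = "little")
  dim(y) <- dims
  y
}

# triangle soup (m x 9: ax ay az bx by bz cx cy cz) -> indexed mesh
soup_to_mesh <- function(tris, name) {
  pts <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE],
               tris[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "/")
  uid <- !duplicated(key)
  verts <- pts[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  n <- nrow(tris)
  faces <- cbind(idx[seq_len(n)], idx[n + seq_len(n)], idx[2 * n + seq_len(n)])
  triangle_mesh(verts, faces, name = name)
}

#' Write a mesh as STL
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  assert_mesh(mesh)
  # both dialects quantize to float32 so they describe the same triangle soup
  mesh$vertices <- float32_quantize(mesh$vertices)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  nrm <- mesh_face_normals(mesh)
  n <- nrow(mesh$faces)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header <- charToRaw(sprintf("%-80s", "fiducialign STL units=mm"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    block <- t(cbind(nrm, a, b, c))  # 12 floats per triangle, column per face
    fl <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
    recs <- rbind(matrix(fl, nrow = 48), matrix(as.raw(0), 2, n))
    writeBin(as.vector(recs), con)
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * n + 2)
    out[1] <- sprintf("solid %s units=mm", gsub("\\s", "_", mesh$name))
    k <- 2
    for (f in seq_len(n)) {
      out[k] <- sprintf("  facet normal %s %s %s", fmt(nrm[f, 1]), fmt(nrm[f, 2]), fmt(nrm[f, 3]))
      out[k + 1] <- "    outer loop"
      out[k + 2] <- sprintf("      vertex %s %s %s", fmt(a[f, 1]), fmt(a[f, 2]), fmt(a[f, 3]))
      out[k + 3] <- sprintf("      vertex %s %s %s", fmt(b[f, 1]), fmt(b[f, 2]), fmt(b[f, 3]))
      out[k + 4] <- sprintf("      vertex %s %s %s", fmt(c[f, 1]), fmt(c[f, 2]), fmt(c[f, 3]))
      out[k + 5] <- "    endloop"
      out[k + 6] <- "  endfacet"
      k <- k + 7
    }
    out[k] <- sprintf("endsolid %s", gsub("\\s", "_", mesh$name))
    writeLines(out, path)
  }
  invisible(path)
}
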