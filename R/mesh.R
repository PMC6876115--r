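#' Indexed triangle mesh
#'
#' The universal container of the package: an indexed triangle surface with
#' coordinates in millimetres. Faces are integer triples into the vertex
#' matrix; counter-clockwise winding (seen from outside) defines the outward
#' normal.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param name label carried through the pipeline (used in logs and reports).
#' @param clean drop zero-area faces and unreferenced vertices (default TRUE).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, n_vertices]")
  }
  m <- structure(list(vertices = vertices, faces = faces, name = name),
                 class = "triangle_mesh")
  if (clean) m <- mesh_clean(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces> [mm]\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_mesh <- function(x) inherits(x, "triangle_mesh")

assert_mesh <- function(x, arg = "mesh") {
  if (!is_mesh(x)) stop(sprintf("'%s' must be a triangle_mesh", arg))
  if (nrow(x$faces) == 0L) stop(sprintf("'%s' has no faces", arg))
  invisible(x)
}

#' Remove zero-area faces and unreferenced vertices
#'
#' @param mesh a `triangle_mesh`.
#' @param area_eps faces with area below this [mm^2] are dropped.
#' @return cleaned `triangle_mesh`.
#' @export
mesh_clean <- function(mesh, area_eps = 1e-12) {
  f <- mesh$faces
  if (nrow(f) > 0L) {
    keep <- mesh_face_areas(mesh) > area_eps
    f <- f[keep, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(mesh$vertices)) {
    remap <- integer(nrow(mesh$vertices))
    remap[used] <- seq_along(used)
    v <- mesh$vertices[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
  } else {
    v <- mesh$vertices
  }
  structure(list(vertices = v, faces = f, name = mesh$name),
            class = "triangle_mesh")
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Per-face outward normals and areas
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh_face_normals`: m x 3 matrix of unit normals (zero rows for
#'   degenerate faces); `mesh_face_areas`: numeric vector of face areas [mm^2].
#' @export
mesh_face_normals <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname mesh_face_normals
#' @export
mesh_face_areas <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Surface area, signed volume and simple descriptors
#'
#' `mesh_volume` is the signed volume from the divergence theorem; it is the
#' enclosed volume for a watertight, outward-wound surface and negates under
#' normal inversion.
#'
#' @param mesh a `triangle_mesh`.
#' @return scalar [mm^2], [mm^3]; `mesh_centroid` returns the vertex mean;
#'   `mesh_bbox` a 2 x 3 matrix (min row, max row).
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' @rdname mesh_area
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' @rdname mesh_area
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

# undirected edge keys: each face contributes 3 edges (sorted index pairs)
mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(i, j); hi <- pmax(i, j)
  lo + (hi - 1) * as.double(nrow(mesh$vertices))
}

#' Topology checks
#'
#' `mesh_euler_characteristic` returns V - E + F over unique undirected edges
#' (2 for a watertight genus-0 surface). `mesh_is_watertight` is TRUE iff
#' every edge is shared by exactly two faces.
#'
#' @param mesh a `triangle_mesh`.
#' @export
mesh_euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - length(unique(mesh_edge_keys(mesh))) + nrow(mesh$faces)
}

#' @rdname mesh_euler_characteristic
#' @export
mesh_is_watertight <- function(mesh) {
  tab <- table(mesh_edge_keys(mesh))
  all(tab == 2L)
}

#' Area-weighted unit vertex normals
#'
#' @param mesh a `triangle_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh) * mesh_face_areas(mesh)
  idx <- as.vector(mesh$faces)
  acc <- rowsum(rbind(fn, fn, fn), idx)
  n <- matrix(0, nrow(mesh$vertices), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Concatenate meshes (triangle-soup union, no boolean operation)
#'
#' @param ... `triangle_mesh` objects.
#' @param name label for the result.
#' @return a `triangle_mesh` holding all parts; parts stay disjoint components.
#' @export
mesh_concat <- function(..., name = "assembly") {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  off <- 0L
  vs <- list(); fs <- list()
  for (p in parts) {
    assert_mesh(p)
    vs[[length(vs) + 1L]] <- p$vertices
    fs[[length(fs) + 1L]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), name = name,
                clean = FALSE)
}

#' Translate a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param offset length-3 translation [mm].
#' @export
mesh_translate <- function(mesh, offset) {
  stopifnot(length(offset) == 3L)
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}
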