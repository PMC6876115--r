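# Mesh utilities for workflow steps 3 and 5: segmentation into parts and the
# "normal inversion" that turns a scanned impression (negative mould) into
# the positive counterfeit of the dental arch.

#' Invert surface orientation ("normal inversion")
#'
#' Reverses the winding of every face; vertex positions are untouched. An
#' involution; on watertight meshes the signed volume negates.
#'
#' @param mesh a [triangle_mesh].
#' @return a [triangle_mesh] with flipped normals.
#' @export
invert_normals <- function(mesh) {
  assert_mesh(mesh)
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Split a mesh into edge-connected components
#'
#' Faces sharing an undirected edge are connected; the partition is returned
#' ordered by descending face count (the segmentation step of the workflow).
#' Coincident vertices (identical coordinates, e.g. seams left by adaptive
#' refinement) are merged before connectivity is computed unless
#' `merge_coincident = FALSE`.
#'
#' @param mesh a [triangle_mesh].
#' @param merge_coincident treat vertices with identical coordinates as one.
#' @param connectivity `"edge"` (faces must share a full edge; the default)
#'   or `"vertex"` (sharing a single vertex connects; robust to the
#'   T-junction seams adaptive refinement leaves behind).
#' @return list of [triangle_mesh] components.
#' @export
connected_components <- function(mesh, merge_coincident = TRUE,
                                 connectivity = c("edge", "vertex")) {
  connectivity <- match.arg(connectivity)
  assert_mesh(mesh)
  nf <- nrow(mesh$faces)
  fidx <- mesh$faces
  if (merge_coincident) {
    vkey <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                  sep = "/")
    remap <- match(vkey, vkey)
    fidx <- matrix(remap[fidx], ncol = 3L)
  }
  if (connectivity == "edge") {
    i <- c(fidx[, 1], fidx[, 2], fidx[, 3])
    j <- c(fidx[, 2], fidx[, 3], fidx[, 1])
    keys <- pmin(i, j) + pmax(i, j) * as.double(nrow(mesh$vertices) + 1)
  } else {
    keys <- as.double(c(fidx[, 1], fidx[, 2], fidx[, 3]))
  }
  face_of <- rep(seq_len(nf), 3L)
  ord <- order(keys)
  keys <- keys[ord]; face_of <- face_of[ord]
  # consecutive faces within each equal-key run share that edge
  same <- which(diff(keys) == 0)
  g <- igraph::graph_from_edgelist(
    cbind(face_of[same], face_of[same + 1L]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nf - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  ids <- unique(comp)
  parts <- lapply(ids, function(id) {
    triangle_mesh(mesh$vertices, mesh$faces[comp == id, , drop = FALSE],
                  name = mesh$name)
  })
  sizes <- vapply(parts, function(p) nrow(p$faces), integer(1))
  parts <- parts[order(-sizes)]
  for (k in seq_along(parts)) parts[[k]]$name <- sprintf("%s_part%d", mesh$name, k)
  parts
}

#' Region predicates for cropping
#'
#' `region_halfspace(normal, offset)` keeps face centroids with
#' `dot(centroid, normal) >= offset`; `region_box(min, max)` keeps centroids
#' inside an axis-aligned box; `region_near(points, radius)` keeps centroids
#' within `radius` mm of any of the given points (the landmark-radius masks
#' used to restrict ICP to the fiducial or gumline region).
#'
#' @param normal length-3 plane normal; `offset` plane offset [mm].
#' @export
region_halfspace <- function(normal, offset) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L)
  structure(list(type = "halfspace", normal = normal, offset = offset),
            class = "crop_region")
}

#' @rdname region_halfspace
#' @param lo,hi length-3 box corners [mm].
#' @export
region_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(lo <= hi))
  structure(list(type = "box", lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "crop_region")
}

#' @rdname region_halfspace
#' @param points n x 3 matrix of anchor points; `radius` mask radius [mm].
#' @param radius mask radius [mm].
#' @export
region_near <- function(points, radius = 10) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3L, radius > 0)
  structure(list(type = "near", points = points, radius = radius),
            class = "crop_region")
}

region_test <- function(region, pts) {
  switch(region$type,
    halfspace = as.vector(pts %*% region$normal) >= region$offset,
    box = pts[, 1] >= region$lo[1] & pts[, 1] <= region$hi[1] &
          pts[, 2] >= region$lo[2] & pts[, 2] <= region$hi[2] &
          pts[, 3] >= region$lo[3] & pts[, 3] <= region$hi[3],
    near = {
      keep <- rep(FALSE, nrow(pts))
      for (k in seq_len(nrow(region$points))) {
        d2 <- rowSums(sweep(pts, 2, region$points[k, ], "-")^2)
        keep <- keep | d2 <= region$radius^2
      }
      keep
    },
    stop("unknown region type"))
}

#' Crop a mesh by a declarative region
#'
#' Keeps the faces whose centroids satisfy the region predicate. Boundary
#' triangles are kept or dropped whole (no re-meshing); at scan sampling
#' density the ragged boundary is well below registration tolerances.
#'
#' @param mesh a [triangle_mesh].
#' @param region a region from [region_halfspace()], [region_box()] or
#'   [region_near()].
#' @return the cropped [triangle_mesh].
#' @export
crop <- function(mesh, region) {
  assert_mesh(mesh)
  stopifnot(inherits(region, "crop_region"))
  cen <- (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
  keep <- region_test(region, cen)
  if (!any(keep))
    stop(structure(class = c("fiducialign_empty_selection", "error", "condition"),
                   list(message = "crop region selects no faces",
                        call = sys.call())))
  out <- triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                       name = paste0(mesh$name, "_crop"), clean = FALSE)
  mesh_clean(out)
}
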