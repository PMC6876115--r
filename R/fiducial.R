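# Parametric fiducial markers: the sphere and cross registration geometries
# glued to the threaded base of a modified impression tray. The published
# design gives no dimensions, so the defaults below are stand-ins chosen to
# be scannable at 0.1 mm resolution while staying child-safe small; all are
# configurable. The threaded base is modelled as a plain cylindrical boss:
# threads add nothing to registration and break watertightness.

#' Fiducial marker specification
#'
#' @param kind `"sphere"` or `"cross"`.
#' @param sphere_radius sphere radius [mm].
#' @param cross_arm_length full length of each cross arm [mm].
#' @param cross_arm_width arm cross-section width [mm].
#' @param cross_arm_depth arm cross-section depth (extrusion) [mm].
#' @param base_diameter,base_height cylindrical mounting boss [mm].
#' @param mount_offset length-3 offset of the marker relative to the base top
#'   [mm].
#' @return an object of class `fiducial_spec`.
#' @export
fiducial_spec <- function(kind = c("sphere", "cross"),
                          sphere_radius = 10,
                          cross_arm_length = 20,
                          cross_arm_width = 6,
                          cross_arm_depth = 6,
                          base_diameter = 8,
                          base_height = 10,
                          mount_offset = c(0, 0, 15)) {
  kind <- match.arg(kind)
  dims <- c(sphere_radius = sphere_radius, cross_arm_length = cross_arm_length,
            cross_arm_width = cross_arm_width, cross_arm_depth = cross_arm_depth,
            base_diameter = base_diameter, base_height = base_height)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all fiducial dimensions must be strictly positive")
  if (cross_arm_width >= cross_arm_length)
    stop("cross_arm_width must be smaller than cross_arm_length")
  stopifnot(length(mount_offset) == 3L)
  structure(list(kind = kind, sphere_radius = sphere_radius,
                 cross_arm_length = cross_arm_length,
                 cross_arm_width = cross_arm_width,
                 cross_arm_depth = cross_arm_depth,
                 base_diameter = base_diameter, base_height = base_height,
                 mount_offset = as.numeric(mount_offset)),
            class = "fiducial_spec")
}

#' Triangulated sphere marker (subdivided icosahedron)
#'
#' Starts from a regular icosahedron and midpoint-subdivides `refinement`
#' times, projecting new vertices back onto the sphere. The result is
#' watertight and centred at the origin; area and volume converge to the
#' analytic values from below as `refinement` grows.
#'
#' @param radius sphere radius [mm], > 0.
#' @param refinement subdivision level >= 0 (level 3 gives 1280 faces).
#' @return a [triangle_mesh].
#' @export
make_sphere_marker <- function(radius = 10, refinement = 3) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (refinement < 0) stop("refinement must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lvl in seq_len(refinement)) {
    sub <- subdivide_all(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$faces
  }
  triangle_mesh(v * radius, f, name = sprintf("sphere_r%g", radius),
                clean = FALSE)
}

# midpoint 1->4 subdivision of every face, sharing edge midpoints
subdivide_all <- function(v, f) {
  nv <- nrow(v)
  ek <- function(i, j) pmin(i, j) + pmax(i, j) * (nv + 1)
  e1 <- ek(f[, 1], f[, 2]); e2 <- ek(f[, 2], f[, 3]); e3 <- ek(f[, 3], f[, 1])
  keys <- c(e1, e2, e3)
  ukeys <- unique(keys)
  mid_id <- nv + match(keys, ukeys)
  first <- match(ukeys, keys)
  pair_i <- c(f[, 1], f[, 2], f[, 3])[first]
  pair_j <- c(f[, 2], f[, 3], f[, 1])[first]
  mids <- (v[pair_i, , drop = FALSE] + v[pair_j, , drop = FALSE]) / 2
  nf <- nrow(f)
  m1 <- mid_id[seq_len(nf)]
  m2 <- mid_id[nf + seq_len(nf)]
  m3 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m1, m3),
                 cbind(f[, 2], m2, m1),
                 cbind(f[, 3], m3, m2),
                 cbind(m1, m2, m3))
  list(vertices = rbind(v, mids), faces = faces)
}

#' Cross marker: two orthogonal rectangular arms
#'
#' The union of two boxes sharing a centre, built directly as the watertight
#' extrusion of a plus-shaped polygon (no boolean operation needed). Enclosed
#' volume is `w (2L - w) d` for arm length L, width w, depth d.
#'
#' @param spec a [fiducial_spec] with `kind = "cross"`, or arm dimensions.
#' @param arm_length,arm_width,arm_depth used when `spec` is missing [mm].
#' @return a [triangle_mesh] centred at the origin, arms along x and y,
#'   extruded in z.
#' @export
make_cross_marker <- function(spec = NULL, arm_length = 20, arm_width = 6,
                              arm_depth = 6) {
  if (!is.null(spec)) {
    if (spec$kind != "cross") stop("spec$kind must be 'cross'")
    arm_length <- spec$cross_arm_length
    arm_width <- spec$cross_arm_width
    arm_depth <- spec$cross_arm_depth
  }
  if (arm_width >= arm_length) stop("arm_width must be smaller than arm_length")
  if (min(arm_length, arm_width, arm_depth) <= 0)
    stop("cross dimensions must be strictly positive")
  L <- arm_length / 2; w <- arm_width / 2; d <- arm_depth / 2
  xb <- c(-L, -w, w, L)
  # 4 x 4 vertex grid per layer; the four extreme corners are unused
  grid_id <- function(i, j) (j - 1) * 4 + i
  layer <- as.matrix(expand.grid(x = xb, y = xb))
  cells <- rbind(c(2, 2), c(1, 2), c(3, 2), c(2, 1), c(2, 3))  # plus shape
  quads <- t(apply(cells, 1, function(cl) {
    i <- cl[1]; j <- cl[2]
    c(grid_id(i, j), grid_id(i + 1, j), grid_id(i + 1, j + 1), grid_id(i, j + 1))
  }))
  top_tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  verts <- rbind(cbind(layer, d), cbind(layer, -d))  # top layer then bottom
  bot_tris <- top_tris[, c(1, 3, 2)] + 16L
  # boundary edges of the plus polygon, counter-clockwise
  b <- c(grid_id(2, 1), grid_id(3, 1), grid_id(3, 2), grid_id(4, 2),
         grid_id(4, 3), grid_id(3, 3), grid_id(3, 4), grid_id(2, 4),
         grid_id(2, 3), grid_id(1, 3), grid_id(1, 2), grid_id(2, 2))
  nb <- length(b)
  side <- NULL
  for (k in seq_len(nb)) {
    i <- b[k]; j <- b[if (k == nb) 1 else k + 1]
    side <- rbind(side, c(i, i + 16L, j), c(j, i + 16L, j + 16L))
  }
  triangle_mesh(verts, rbind(top_tris, bot_tris, side),
                name = sprintf("cross_%gx%gx%g", arm_length, arm_width, arm_depth))
}

#' Cylinder mesh (mounting boss)
#'
#' @param diameter,height cylinder size [mm].
#' @param segments circle resolution.
#' @param center length-3 centre of the cylinder's top disc [mm]; the body
#'   extends downward by `height`.
#' @return a watertight [triangle_mesh].
#' @export
make_cylinder <- function(diameter = 8, height = 10, segments = 48,
                          center = c(0, 0, 0)) {
  stopifnot(diameter > 0, height > 0, segments >= 3)
  r <- diameter / 2
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- cbind(r * cos(th), r * sin(th))
  vt <- cbind(ring, 0)             # top ring at z = 0
  vb <- cbind(ring, -height)       # bottom ring
  verts <- rbind(vt, vb, c(0, 0, 0), c(0, 0, -height))
  ct <- 2L * segments + 1L; cb <- 2L * segments + 2L
  nxt <- c(seq_len(segments)[-1], 1L)
  faces <- rbind(
    cbind(seq_len(segments), nxt, ct),                       # top fan (+z out)
    cbind(nxt + segments, seq_len(segments) + segments, cb), # bottom fan
    cbind(seq_len(segments), seq_len(segments) + segments, nxt),
    cbind(nxt, seq_len(segments) + segments, nxt + segments))
  m <- triangle_mesh(sweep(verts, 2, as.numeric(center), "+"), faces,
                     name = "base_cylinder")
  m
}

#' Build a marker from a spec
#'
#' @param spec a [fiducial_spec].
#' @return a [triangle_mesh] of the bare marker centred at the origin.
#' @export
make_marker <- function(spec) {
  stopifnot(inherits(spec, "fiducial_spec"))
  if (spec$kind == "sphere") make_sphere_marker(spec$sphere_radius)
  else make_cross_marker(spec)
}

#' Attach a marker to its cylindrical base
#'
#' The marker is rigidly translated by `spec$mount_offset`; the base is a
#' cylinder whose top disc sits at the origin. By default the two parts are
#' concatenated (2 connected components), which is all registration needs;
#' boolean union is out of scope.
#'
#' @param marker a [triangle_mesh].
#' @param spec a [fiducial_spec] (provides `mount_offset`, base dimensions).
#' @return assembly [triangle_mesh] with components `marker` then `base`.
#' @export
attach_to_base <- function(marker, spec) {
  assert_mesh(marker, "marker")
  stopifnot(inherits(spec, "fiducial_spec"))
  placed <- mesh_translate(marker, spec$mount_offset)
  base <- make_cylinder(spec$base_diameter, spec$base_height)
  mesh_concat(placed, base, name = paste0(marker$name, "_on_base"))
}
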