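# Surface-deviation metrics: the RMSE analysis used to score both the
# scannability of the fiducial geometries and the in-face alignments.

#' Distance from a point to a closed triangle
#'
#' Exact Euclidean distance to the nearest point of the triangle (interior,
#' edge or vertex region).
#'
#' @param p length-3 point [mm].
#' @param tri 3 x 3 matrix, one vertex per row.
#' @return distance [mm].
#' @export
point_to_triangle <- function(p, tri) {
  p <- as.numeric(p)
  tri <- as.matrix(tri)
  stopifnot(length(p) == 3L, all(dim(tri) == c(3, 3)))
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(cr^2)) / 2 <= 1e-12)
    stop("degenerate triangle (area ~ 0)")
  cpp_point_triangle_distance(p, tri)
}

#' Deterministic area-weighted surface samples
#'
#' Each face receives `ceil(area / spacing^2)` samples placed by a
#' golden-ratio lattice in barycentric coordinates — deterministic (no RNG),
#' well spread, and independent of the mesh's frame, so deviation metrics
#' are exactly rigid-invariant.
#'
#' @param mesh a [triangle_mesh].
#' @param spacing target sample spacing [mm].
#' @param max_points hard cap on the total sample count.
#' @return n x 3 matrix of surface points.
#' @export
sample_surface_points <- function(mesh, spacing, max_points = 5e5) {
  assert_mesh(mesh)
  areas <- mesh_face_areas(mesh)
  n_f <- pmax(1L, as.integer(ceiling(areas / spacing^2)))
  if (sum(n_f) > max_points) {
    n_f <- pmax(1L, as.integer(floor(n_f * max_points / sum(n_f))))
  }
  face_id <- rep(seq_along(n_f), n_f)
  k <- sequence(n_f)
  g1 <- 0.6180339887498949   # 1/phi
  g2 <- 0.3819660112501051   # 1/phi^2
  u <- (k * g1 + face_id * 0.217) %% 1
  v <- (k * g2 + face_id * 0.413) %% 1
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  a <- mesh$vertices[mesh$faces[face_id, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[face_id, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[face_id, 3], , drop = FALSE]
  a + u * (b - a) + v * (c - a)
}

new_deviation_report <- function(distances, n_excluded, cutoff, direction) {
  stopifnot(all(distances >= 0))
  r <- list(distances = distances,
            rmse = sqrt(mean(distances^2)),
            mean_abs = mean(distances),
            max_abs = max(distances),
            n_points = length(distances),
            n_excluded = n_excluded,
            cutoff = cutoff,
            direction = direction)
  class(r) <- "deviation_report"
  r
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report: rmse %.4f mm, mean %.4f, max %.4f, n = %d%s>\n",
              x$rmse, x$mean_abs, x$max_abs, x$n_points,
              if (x$n_excluded > 0) sprintf(" (+%d beyond cutoff)", x$n_excluded) else ""))
  invisible(x)
}

#' Surface deviation between two meshes (RMSE analysis)
#'
#' Samples the source surface and measures the unsigned distance of each
#' sample to the nearest point of the reference surface. Meshes must already
#' share a frame — registration is the caller's job. Directed
#' source-to-reference by default (scan compared to original); `symmetric`
#' takes the larger RMSE of the two directions.
#'
#' @param source,reference [triangle_mesh] objects in a common frame.
#' @param sample_spacing sampling density [mm].
#' @param cutoff distances beyond this [mm] are excluded from the summaries
#'   (counted in `n_excluded`); `NULL` disables the cutoff.
#' @param direction `"source_to_reference"` or `"symmetric"`.
#' @param mode `"area"` (area-weighted samples, default) or `"vertices"`
#'   (use source vertices verbatim — exact small-case oracle mode).
#' @return a `deviation_report` with fields `distances`, `rmse`, `mean_abs`,
#'   `max_abs`, `n_points`, `n_excluded`, `cutoff`, `direction`.
#' @export
surface_deviation <- function(source, reference, sample_spacing = 0.5,
                              cutoff = NULL,
                              direction = c("source_to_reference", "symmetric"),
                              mode = c("area", "vertices")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  assert_mesh(source, "source")
  assert_mesh(reference, "reference")
  if (direction == "symmetric") {
    fwd <- surface_deviation(source, reference, sample_spacing, cutoff,
                             "source_to_reference", mode)
    rev <- surface_deviation(reference, source, sample_spacing, cutoff,
                             "source_to_reference", mode)
    pick <- if (fwd$rmse >= rev$rmse) fwd else rev
    pick$direction <- "symmetric"
    return(pick)
  }
  pts <- if (mode == "vertices") source$vertices
         else sample_surface_points(source, sample_spacing)
  d <- cpp_nearest_on_mesh(pts, reference$vertices, reference$faces)$distance
  n_excluded <- 0L
  if (!is.null(cutoff)) {
    drop <- d > cutoff
    n_excluded <- sum(drop)
    d <- d[!drop]
    if (length(d) == 0L)
      stop(structure(class = c("fiducialign_empty_report", "error", "condition"),
                     list(message = "all sample points lie beyond the cutoff",
                          call = sys.call())))
  }
  new_deviation_report(d, n_excluded, cutoff, direction)
}

#' Round half-up to a fixed number of decimals
#'
#' Table-style presentation rounding (0.355 -> "0.36"), unlike R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # snap away float error first (0.355 * 100 is 35.499999...), then half-up
  floor(round(x * p, 6) + 0.5) / p
}

#' Presentation rounding of a deviation report
#'
#' @param report a `deviation_report` (or any list with rmse/mean_abs/max_abs).
#' @param digits decimal places (tables use 2).
#' @return list of formatted strings `rmse`, `mean_abs`, `max_abs` plus the
#'   raw report under `$raw`.
#' @export
report_round <- function(report, digits = 2L) {
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  list(rmse = fmt(report$rmse), mean_abs = fmt(report$mean_abs),
       max_abs = fmt(report$max_abs), raw = report)
}
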