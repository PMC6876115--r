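#' Rigid transform (rotation + translation)
#'
#' Maps points by `p' = R p + t`. Rotations must be proper (det +1,
#' orthonormal); scaling and reflection are deliberately unsupported because
#' scanner data and dental models are metric.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector [mm].
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I beyond 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1); reflections are not rigid motions")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: angle %.4f deg, |t| = %.4f mm>\n",
              rotation_angle_deg(x), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose and invert rigid transforms
#'
#' `rt_compose(T1, T2)` applies `T2` first, then `T1` (matrix convention
#' `T1 %*% T2`). `rt_invert(T)` satisfies `rt_compose(rt_invert(T), T) = I`.
#'
#' @param t1,t2,transform `rigid_transform` objects.
#' @export
rt_compose <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.vector(t1$rotation %*% t2$translation) + t1$translation)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a `rigid_transform`.
#' @param x an n x 3 point matrix, a length-3 vector, or a [triangle_mesh].
#' @return object of the same kind as `x`.
#' @export
rt_apply <- function(transform, x) {
  if (is_mesh(x)) {
    x$vertices <- rt_apply(transform, x$vertices)
    return(x)
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    return(as.vector(transform$rotation %*% x) + transform$translation)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rotation helpers
#'
#' `rot_axis_angle` builds a rotation about a unit axis (Rodrigues);
#' `rotation_angle_deg` is the geodesic rotation angle of a transform,
#' in degrees. Both are used to score pose-recovery error.
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rot_axis_angle
#' @param transform a `rigid_transform` (or 3 x 3 rotation matrix).
#' @export
rotation_angle_deg <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation else transform
  cth <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, cth))) * 180 / pi
}

#' Pose difference between two transforms
#'
#' Angle [deg] and translation norm [mm] of `rt_compose(rt_invert(a), b)`,
#' plus the RMS displacement the difference induces on a reference point set
#' (the practical "placement error" of a posed model).
#'
#' @param a,b `rigid_transform` objects.
#' @param points optional n x 3 reference points for the RMS displacement.
#' @return list with `angle_deg`, `translation_mm`, and `rms_mm` (NA without
#'   `points`).
#' @export
rt_difference <- function(a, b, points = NULL) {
  d <- rt_compose(rt_invert(a), b)
  rms <- NA_real_
  if (!is.null(points)) {
    pa <- rt_apply(a, points)
    pb <- rt_apply(b, points)
    rms <- sqrt(mean(rowSums((pa - pb)^2)))
  }
  list(angle_deg = rotation_angle_deg(d),
       translation_mm = sqrt(sum(d$translation^2)),
       rms_mm = rms)
}

#' 4 x 4 homogeneous matrix round-trip (for JSON sidecars)
#'
#' @param transform a `rigid_transform`; `m` a 4 x 4 row-major matrix.
#' @export
rt_to_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname rt_to_matrix
#' @param m 4 x 4 homogeneous matrix.
#' @export
rt_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}
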