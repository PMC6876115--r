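# Rigid registration: landmark-seeded coarse alignment (Kabsch) plus
# point-to-surface ICP refinement, and the six-step transform chain that
# places the dental models in the face-scan frame. The published workflow
# performs the point selection interactively in commercial software; here
# landmarks are explicit inputs, which makes the step reproducible.

#' Ordered landmark set
#'
#' @param points n x 3 matrix of 3D points [mm].
#' @param labels optional character labels (defaults `L1..Ln`).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(points)))
  stopifnot(length(labels) == nrow(points))
  structure(list(points = points, labels = as.character(labels)),
            class = "landmark_set")
}

as_points <- function(x) {
  if (inherits(x, "landmark_set")) x$points else rbind(x)
}

check_pose_configuration <- function(p, what = "landmarks") {
  if (nrow(p) < 3L)
    stop(structure(class = c("fiducialign_degenerate", "error", "condition"),
                   list(message = sprintf("%s: need >= 3 points for pose estimation", what),
                        call = sys.call())))
  cen <- scale(p, scale = FALSE)
  sv <- svd(cen, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9)
    stop(structure(class = c("fiducialign_degenerate", "error", "condition"),
                   list(message = sprintf("%s: points are collinear (2nd singular value %.2e)", what, sv[2]),
                        call = sys.call())))
  invisible(p)
}

#' Least-squares rigid fit of corresponding point sets (Kabsch)
#'
#' Returns the proper rigid transform minimising the sum of squared
#' residuals `sum ||T(src_i) - dst_i||^2`. No scaling; reflections are
#' excluded by a sign correction on the smallest singular direction.
#'
#' @param src,dst corresponding points: [landmark_set] or n x 3 matrices,
#'   equal counts >= 3, non-collinear.
#' @return a [rigid_transform].
#' @export
kabsch <- function(src, dst) {
  ps <- as_points(src); pd <- as_points(dst)
  if (nrow(ps) != nrow(pd)) stop("src and dst must have equal point counts")
  check_pose_configuration(ps, "src")
  check_pose_configuration(pd, "dst")
  cs <- colMeans(ps); cd <- colMeans(pd)
  H <- crossprod(sweep(ps, 2, cs), sweep(pd, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cd - as.vector(R %*% cs))
}

#' Registration result
#'
#' @param transform fitted [rigid_transform] (source frame into target frame).
#' @param final_rms RMS of the correspondences used at convergence [mm].
#' @param iterations iterations executed.
#' @param converged TRUE iff the RMS change fell below tolerance.
#' @param correspondences_used count after distance rejection.
#' @param rms_trace per-iteration RMS values.
#' @export
registration_result <- function(transform, final_rms, iterations, converged,
                                correspondences_used, rms_trace = numeric(0)) {
  stopifnot(inherits(transform, "rigid_transform"), final_rms >= 0)
  structure(list(transform = transform, final_rms = final_rms,
                 iterations = iterations, converged = converged,
                 correspondences_used = correspondences_used,
                 rms_trace = rms_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration: rms %.5f mm, %d iter, converged=%s, %d corr.>\n",
              x$final_rms, x$iterations, x$converged, x$correspondences_used))
  invisible(x)
}

#' Iterative closest point (point-to-surface, point-to-point objective)
#'
#' Source sample points are matched to their nearest points on the target
#' surface; correspondences farther than `reject_distance_mm` are discarded;
#' a Kabsch fit updates the pose. Iterates until the RMS change drops below
#' `tolerance_mm` or `max_iterations` is reached. The RMS objective is
#' monotone non-increasing: an update that would increase it is rejected and
#' iteration stops at the previous pose.
#'
#' @param source,target [triangle_mesh] objects (or `source` an n x 3 point
#'   matrix).
#' @param init initial [rigid_transform] (default identity).
#' @param max_iterations,tolerance_mm,reject_distance_mm ICP controls.
#' @param source_points optional pre-selected source points (overrides the
#'   source mesh vertices), e.g. a fiducial-region subset.
#' @param max_points subsample cap on source points (lowest-index ties kept
#'   for determinism).
#' @return a [registration_result].
#' @export
icp <- function(source, target, init = rt_identity(), max_iterations = 100L,
                tolerance_mm = 1e-6, reject_distance_mm = 1.0,
                source_points = NULL, max_points = 20000L) {
  assert_mesh(target, "target")
  pts <- if (!is.null(source_points)) rbind(source_points)
         else { assert_mesh(source, "source"); source$vertices }
  if (nrow(pts) > max_points) {
    keep <- as.integer(seq(1L, nrow(pts), length.out = max_points))
    pts <- pts[keep, , drop = FALSE]
  }
  transform <- init
  prev_rms <- Inf
  trace <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  n_used <- 0L
  for (it in seq_len(max_iterations)) {
    cur <- rt_apply(transform, pts)
    nn <- cpp_nearest_on_mesh(cur, target$vertices, target$faces)
    use <- nn$distance <= reject_distance_mm
    if (!any(use))
      stop(structure(class = c("fiducialign_registration_failure", "error", "condition"),
                     list(message = sprintf(
                       "no correspondences within reject distance %.3g mm", reject_distance_mm),
                       call = sys.call())))
    rms <- sqrt(mean(nn$distance[use]^2))
    if (rms > prev_rms + 1e-12) break       # monotone-descent guard
    iterations <- it
    trace <- c(trace, rms)
    n_used <- sum(use)
    if (prev_rms - rms < tolerance_mm) {
      converged <- TRUE
      prev_rms <- rms
      break
    }
    prev_rms <- rms
    upd <- kabsch(cur[use, , drop = FALSE], nn$point[use, , drop = FALSE])
    transform <- rt_compose(upd, transform)
  }
  registration_result(transform, prev_rms, iterations, converged, n_used, trace)
}

#' Fiducial-guided alignment of two scans
#'
#' Workflow step 4: coarse Kabsch fit on corresponding landmark picks in the
#' fiducial geometry's surface, then ICP restricted to the fiducial region
#' (source points within `region_radius` mm of the source landmarks).
#'
#' @param scan_a source scan ([triangle_mesh]); `scan_b` target scan.
#' @param scan_b target scan ([triangle_mesh]).
#' @param landmarks_a,landmarks_b corresponding [landmark_set]s (index-wise).
#' @param region_radius fiducial-region mask radius [mm].
#' @param ... passed to [icp()].
#' @return a [registration_result] mapping scan_a into scan_b's frame.
#' @export
align_by_fiducial <- function(scan_a, scan_b, landmarks_a, landmarks_b,
                              region_radius = 15, ...) {
  pa <- as_points(landmarks_a); pb <- as_points(landmarks_b)
  init <- kabsch(pa, pb)
  d2min <- rep(Inf, nrow(scan_a$vertices))
  for (k in seq_len(nrow(pa))) {
    d2 <- rowSums(sweep(scan_a$vertices, 2, pa[k, ], "-")^2)
    d2min <- pmin(d2min, d2)
  }
  sel <- scan_a$vertices[d2min <= region_radius^2, , drop = FALSE]
  if (nrow(sel) < 3L) sel <- scan_a$vertices
  icp(scan_a, scan_b, init = init, source_points = sel, ...)
}

chain_step <- function(step, what, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("fiducialign_chain_error", "error", "condition"),
                   list(message = sprintf("workflow step %d (%s) failed: %s",
                                          step, what, conditionMessage(e)),
                        call = sys.call(-4L), step = step)))
  })
}

#' Chain the six-step workflow into face-frame transforms
#'
#' Places both dental models in the face-scan frame: the tray scan is
#' aligned to the face scan through the fiducial geometries (step 4); the
#' arch impression is cropped from the tray scan and normal-inverted into
#' the positive counterfeit (step 5); the maxilla model is ICP-fitted to
#' that counterfeit along the gumline region; the mandible is posed by a
#' Kabsch fit of occlusion landmark pairs in maximal intercuspation
#' (step 6), optionally refined by a tight-rejection ICP against the posed
#' maxilla.
#'
#' @param face_scan,tray_scan scans ([triangle_mesh]).
#' @param fiducial_landmarks_tray,fiducial_landmarks_face corresponding picks
#'   on the fiducial surfaces, tray frame / face frame.
#' @param impression_region `crop_region` isolating the arch impression in
#'   the tray scan.
#' @param maxilla_model,mandible_model dental models ([triangle_mesh]), each
#'   in its own frame.
#' @param occlusion_landmarks_mand,occlusion_landmarks_max >= 3 corresponding
#'   occlusal contact points, mandible frame / maxilla-model frame.
#' @param icp_tolerance_mm,icp_max_iterations,reject_distance_mm ICP controls
#'   for the fiducial and gumline fits.
#' @param gumline_coarse_reject_mm wide rejection gate for the coarse pass of
#'   the gumline fit (must exceed the model's initial misplacement).
#' @param refine_mandible if TRUE, refine the occlusal Kabsch pose with a
#'   0.5 mm-rejection ICP against the posed maxilla (kept only if it
#'   converges; occluding arches only touch at cusps, so unrestricted ICP
#'   would collapse the interocclusal gap).
#' @return list with [rigid_transform]s `maxilla` and `mandible` (model frame
#'   to face frame), plus `tray_to_face`, `maxilla_fit`, `positive` (the
#'   inverted impression) and per-stage registration results.
#' @export
chain_to_face_frame <- function(face_scan, tray_scan,
                                fiducial_landmarks_tray, fiducial_landmarks_face,
                                impression_region,
                                maxilla_model, mandible_model,
                                occlusion_landmarks_mand, occlusion_landmarks_max,
                                icp_tolerance_mm = 1e-6,
                                icp_max_iterations = 60L,
                                reject_distance_mm = 2.0,
                                gumline_coarse_reject_mm = 8.0,
                                refine_mandible = FALSE) {
  # step 4: tray -> face through the fiducial geometries
  fid <- chain_step(4L, "fiducial alignment", align_by_fiducial(
    tray_scan, face_scan, fiducial_landmarks_tray, fiducial_landmarks_face,
    tolerance_mm = icp_tolerance_mm, max_iterations = icp_max_iterations,
    reject_distance_mm = reject_distance_mm))
  t_tray_face <- fid$transform

  # step 5: impression -> positive counterfeit -> maxilla model fit
  impression <- chain_step(5L, "impression segmentation",
                           crop(tray_scan, impression_region))
  positive <- invert_normals(impression)
  max_fit <- chain_step(5L, "gumline model alignment", {
    init <- rigid_transform(diag(3),
                            mesh_centroid(positive) - mesh_centroid(maxilla_model))
    # coarse pass with a wide rejection gate: the model frame may start
    # several mm off, and a tight gate would keep only a biased subset of
    # correspondences and stall; then refine with the tight gate
    coarse <- icp(maxilla_model, positive, init = init,
                  tolerance_mm = 1e-3, max_iterations = icp_max_iterations,
                  reject_distance_mm = gumline_coarse_reject_mm)
    icp(maxilla_model, positive, init = coarse$transform,
        tolerance_mm = icp_tolerance_mm, max_iterations = icp_max_iterations,
        reject_distance_mm = reject_distance_mm)
  })
  t_maxilla_face <- rt_compose(t_tray_face, max_fit$transform)

  # step 6: mandible by occlusal landmarks in maximal intercuspation
  occl <- chain_step(6L, "occlusal alignment", kabsch(
    occlusion_landmarks_mand, occlusion_landmarks_max))
  occl_result <- NULL
  if (refine_mandible) {
    occl_result <- tryCatch(
      icp(mandible_model, maxilla_model, init = occl,
          tolerance_mm = icp_tolerance_mm, max_iterations = 20L,
          reject_distance_mm = 0.5),
      error = function(e) NULL)
    if (!is.null(occl_result) && occl_result$converged)
      occl <- occl_result$transform
  }
  t_mandible_face <- rt_compose(t_maxilla_face, occl)

  list(maxilla = t_maxilla_face,
       mandible = t_mandible_face,
       tray_to_face = t_tray_face,
       fiducial_result = fid,
       maxilla_fit = max_fit,
       occlusal_fit = occl,
       occlusal_refine = occl_result,
       positive = positive)
}

#' Landmark file I/O
#'
#' Plain text, one `label x y z` per line, millimetres.
#'
#' @param path file path.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad))
    stop(sprintf("malformed landmark line %d: expected 'label x y z'", bad[1]))
  labels <- vapply(parts, `[`, character(1), 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinates in landmark file")
  landmark_set(xyz, labels)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  writeLines(sprintf("%s %.9g %.9g %.9g", landmarks$labels,
                     landmarks$points[, 1], landmarks$points[, 2],
                     landmarks$points[, 3]), path)
  invisible(path)
}
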