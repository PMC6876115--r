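# Virtual structured-light scanner and synthetic face/arch surrogates.
#
# The simulator emulates three artefacts of a hand-held blue-light scanner:
# finite sampling density (~0.1 mm resolution), Gaussian point noise along
# the line of sight (~0.05 mm accuracy), and rounding of sharp edges, which
# is reproduced here as uniform Laplacian smoothing with one interpretable
# knob (smoothing_iters). No speckle/specularity/trajectory physics.

#' Virtual scanner configuration
#'
#' Defaults mirror the scanner class the workflow targets: 0.1 mm sampling,
#' 0.05 mm point accuracy. One integer seed drives one private random stream
#' per scan; global RNG state is left untouched.
#'
#' @param noise_sigma Gaussian noise s.d. [mm] applied along vertex normals.
#' @param sample_spacing target point spacing [mm].
#' @param smoothing_iters uniform Laplacian passes emulating edge radiusing.
#' @param coverage_dirs NULL (full coverage) or an n x 3 matrix of unit view
#'   vectors pointing from the surface toward the scanner; faces back-facing
#'   to every view are dropped.
#' @param seed integer seed for the scan's private random stream.
#' @param isotropic if TRUE, noise is an isotropic 3D Gaussian instead of
#'   along-normal.
#' @param max_vertices refinement budget for the resampled surface.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(noise_sigma = 0.05, sample_spacing = 0.1,
                        smoothing_iters = 0L, coverage_dirs = NULL,
                        seed = 1L, isotropic = FALSE, max_vertices = 2e5) {
  stopifnot(noise_sigma >= 0, sample_spacing > 0, smoothing_iters >= 0)
  if (!is.null(coverage_dirs)) {
    coverage_dirs <- as.matrix(coverage_dirs)
    if (ncol(coverage_dirs) != 3L) stop("coverage_dirs must be n x 3")
    len <- sqrt(rowSums(coverage_dirs^2))
    coverage_dirs <- coverage_dirs / len
  }
  structure(list(noise_sigma = noise_sigma, sample_spacing = sample_spacing,
                 smoothing_iters = as.integer(smoothing_iters),
                 coverage_dirs = coverage_dirs, seed = as.integer(seed),
                 isotropic = isTRUE(isotropic),
                 max_vertices = max_vertices),
            class = "scan_config")
}

# evaluate expr under a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Refine a mesh until edges reach a target spacing
#'
#' Longest-edge bisection: every face whose longest edge exceeds `spacing`
#' is split in two at that edge's midpoint (adjacent faces splitting the
#' same edge share the midpoint). Unlike 1-to-4 midpoint subdivision this
#' refines anisotropic triangles — long thin plate faces — without blowing
#' up the short direction. New vertices lie exactly on the input surface.
#'
#' @param mesh a [triangle_mesh].
#' @param spacing target edge length [mm].
#' @param max_vertices stop refining beyond this budget.
#' @export
subdivide_to_spacing <- function(mesh, spacing, max_vertices = 2e5) {
  v <- mesh$vertices
  f <- mesh$faces
  repeat {
    e2 <- cbind(rowSums((v[f[, 1], , drop = FALSE] - v[f[, 2], , drop = FALSE])^2),
                rowSums((v[f[, 2], , drop = FALSE] - v[f[, 3], , drop = FALSE])^2),
                rowSums((v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])^2))
    m <- pmax(e2[, 1], e2[, 2], e2[, 3])
    # tie-break to the lowest edge index with a relative tolerance, so the
    # choice is invariant to ulp-level perturbations (e.g. translation)
    tol <- m * 1e-9
    longest <- ifelse(e2[, 1] >= m - tol, 1L, ifelse(e2[, 2] >= m - tol, 2L, 3L))
    split <- m > spacing^2
    if (!any(split) || nrow(v) + sum(split) > max_vertices) break
    fs <- f[split, , drop = FALSE]
    ls <- longest[split]
    i <- ifelse(ls == 1L, fs[, 1], ifelse(ls == 2L, fs[, 2], fs[, 3]))
    j <- ifelse(ls == 1L, fs[, 2], ifelse(ls == 2L, fs[, 3], fs[, 1]))
    k <- ifelse(ls == 1L, fs[, 3], ifelse(ls == 2L, fs[, 1], fs[, 2]))
    key <- pmin(i, j) + pmax(i, j) * (nrow(v) + 1)
    uk <- unique(key)
    mid_id <- nrow(v) + match(key, uk)
    first <- match(uk, key)
    mids <- (v[i[first], , drop = FALSE] + v[j[first], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    f <- rbind(f[!split, , drop = FALSE],
               cbind(i, mid_id, k), cbind(mid_id, j, k))
  }
  dimnames(f) <- NULL
  triangle_mesh(v, f, name = mesh$name, clean = FALSE)
}

# merge vertices with bitwise-identical coordinates (refinement seams), so
# per-vertex noise and smoothing treat them as one point
merge_coincident_vertices <- function(mesh) {
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
               sep = "/")
  remap <- match(key, key)
  if (all(remap == seq_along(remap))) return(mesh)
  mesh$faces <- matrix(remap[mesh$faces], ncol = 3L)
  mesh_clean(mesh)
}

#' Uniform Laplacian smoothing
#'
#' `v <- v + lambda (mean(neighbours) - v)` per pass. Each vertex moves into
#' the convex hull of itself and its neighbours, so the bounding box never
#' grows (the "contractive" property the edge-rounding model relies on).
#'
#' @param mesh a [triangle_mesh].
#' @param iters number of passes.
#' @param lambda step size in (0, 1].
#' @export
laplacian_smooth <- function(mesh, iters, lambda = 0.5) {
  if (iters <= 0) return(mesh)
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(lo + (hi - 1) * as.double(nrow(mesh$vertices)))
  lo <- lo[!dup]; hi <- hi[!dup]
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                            dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (k in seq_len(iters)) {
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
  }
  mesh$vertices <- v
  mesh
}

#' Simulate a structured-light scan of a mesh
#'
#' Pipeline: (1) refine the surface to ~`sample_spacing`; (2) displace each
#' sample along its surface normal by `N(0, noise_sigma^2)` drawn from the
#' seed's private stream; (3) apply `smoothing_iters` Laplacian passes
#' (edge radiusing); (4) cull faces back-facing to all `coverage_dirs`.
#' Deterministic: the same `(mesh, config)` yields bitwise-identical output.
#'
#' @param mesh a [triangle_mesh].
#' @param config a [scan_config].
#' @return the scan as a [triangle_mesh].
#' @export
simulate_scan <- function(mesh, config) {
  assert_mesh(mesh)
  stopifnot(inherits(config, "scan_config"))
  m <- subdivide_to_spacing(mesh, config$sample_spacing, config$max_vertices)
  m <- merge_coincident_vertices(m)
  if (config$noise_sigma > 0) {
    nv <- nrow(m$vertices)
    if (config$isotropic) {
      disp <- with_seed(config$seed,
                        matrix(stats::rnorm(3 * nv, 0, config$noise_sigma), nv, 3))
      m$vertices <- m$vertices + disp
    } else {
      nrm <- mesh_vertex_normals(m)
      disp <- with_seed(config$seed, stats::rnorm(nv, 0, config$noise_sigma))
      m$vertices <- m$vertices + disp * nrm
    }
  }
  m <- laplacian_smooth(m, config$smoothing_iters)
  if (!is.null(config$coverage_dirs)) {
    fn <- mesh_face_normals(m)
    vis <- rowSums((fn %*% t(config$coverage_dirs)) > 1e-12) > 0
    if (!any(vis)) {
      stop(structure(class = c("fiducialign_empty_scan", "error", "condition"),
                     list(message = "coverage_dirs eliminated every face of the scan",
                          call = sys.call())))
    }
    m$faces <- m$faces[vis, , drop = FALSE]
    m <- mesh_clean(m)
  }
  m$name <- paste0(mesh$name, "_scan")
  m
}

#' Edge-rounding bias of a marker under a scan configuration
#'
#' RMSE of the simulated scan of a default-dimension marker against the
#' pristine marker, in a common frame. Under smoothing (edge radiusing) the
#' cross, having sharp edges, deviates more than the sphere — the in-silico
#' counterpart of the scannability experiment.
#'
#' @param marker_kind `"sphere"` or `"cross"`.
#' @param config a [scan_config].
#' @return RMSE [mm].
#' @export
edge_rounding_bias <- function(marker_kind = c("sphere", "cross"), config) {
  marker_kind <- match.arg(marker_kind)
  marker <- make_marker(fiducial_spec(kind = marker_kind))
  scan <- simulate_scan(marker, config)
  surface_deviation(scan, marker,
                    sample_spacing = config$sample_spacing)$rmse
}

#' Synthetic face surrogate
#'
#' A smooth half-ellipsoid (~120 x 180 x 90 mm) facing +z with a nose-like
#' Gaussian protrusion and a small seed-specific low-frequency relief, the
#' stand-in for a real facial scan. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_grid grid resolution per parameter direction.
#' @return a [triangle_mesh].
#' @export
make_face_surrogate <- function(seed = 1L, n_grid = 48L) {
  a <- 60; b <- 90; cc <- 45  # semi-axes: width 120, height 180, depth 90
  th <- seq(0, pi, length.out = n_grid + 1L)        # from chin pole to crown
  ph <- seq(-pi / 2, pi / 2, length.out = n_grid + 1L)
  g <- expand.grid(th = th, ph = ph)
  x <- a * sin(g$th) * sin(g$ph)
  y <- b * cos(g$th)
  z <- cc * sin(g$th) * cos(g$ph)
  # nose: gaussian boss on the facial midline
  z <- z + 18 * exp(-((x / 12)^2 + ((y - 5) / 12)^2) / 2) * pmax(z / cc, 0)
  ph_r <- with_seed(seed, stats::runif(4, 0, 2 * pi))
  z <- z + 0.4 * sin(x / 17 + ph_r[1]) * sin(y / 23 + ph_r[2]) +
       0.2 * sin(x / 9 + ph_r[3]) * sin(y / 11 + ph_r[4])
  v <- cbind(x, y, z)
  f <- grid_faces(n_grid + 1L, n_grid + 1L)
  triangle_mesh(v, f, name = sprintf("face_surrogate_seed%d", seed))
}

# triangulation of an (nr x nc) vertex grid stored column-major
grid_faces <- function(nr, nc) {
  i <- rep(seq_len(nr - 1L), nc - 1L)
  j <- rep(seq_len(nc - 1L), each = nr - 1L)
  v00 <- i + (j - 1L) * nr
  v10 <- v00 + 1L
  v01 <- v00 + nr
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Synthetic dental-arch surrogate
#'
#' A parabolic ridge (~50 mm wide horseshoe) carrying `n_teeth` cusp-like
#' bumps, the stand-in for a digitized maxillary arch model. The ridge
#' midline has exactly `n_teeth` local height maxima. Deterministic per seed.
#'
#' @param n_teeth number of cusps, between 6 and 16.
#' @param seed integer seed.
#' @param width arch width [mm].
#' @return a [triangle_mesh].
#' @export
make_arch_surrogate <- function(n_teeth = 14L, seed = 1L, width = 50) {
  if (n_teeth < 6L || n_teeth > 16L)
    stop("n_teeth must be between 6 and 16")
  nt <- 8L * n_teeth          # samples along the arch
  ns <- 9L                    # samples across the ridge (odd: midline row)
  tt <- seq(0, 1, length.out = nt + 1L)
  ss <- seq(-1, 1, length.out = ns)
  u <- 2 * tt - 1
  cx <- (width / 2) * u
  cy <- 40 * (1 - u^2)                     # parabolic horseshoe, opens -y
  # unit normal of the curve in the xy-plane
  dx <- rep(width / 2, length(u))
  dy <- -160 * u / 2                        # d(cy)/du * du/dt scale-free
  nl <- sqrt(dx^2 + dy^2)
  nxv <- -dy / nl
  nyv <- dx / nl
  ridge_w <- 5                              # half-width of ridge crest [mm]
  tk <- (seq_len(n_teeth) - 0.5) / n_teeth
  sig_t <- 0.25 / n_teeth
  jit <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  verts <- NULL
  for (k in seq_len(ns)) {
    s <- ss[k]
    px <- cx + s * ridge_w * nxv
    py <- cy + s * ridge_w * nyv
    pz <- 8 * (1 - s^2)
    for (m in tk) pz <- pz + 4 * exp(-((tt - m) / sig_t)^2 / 2 - (s / 0.5)^2 / 2)
    pz <- pz + 0.05 * sin(10 * pi * tt + jit[1]) * cos(3 * s + jit[2])
    verts <- rbind(verts, cbind(px, py, pz))
  }
  f <- grid_faces(nt + 1L, ns)
  triangle_mesh(verts, f, name = sprintf("arch_%dteeth_seed%d", n_teeth, seed))
}

#' Ground-truth pose wrapper
#'
#' @param transform a [rigid_transform] applied to the object before scanning.
#' @param label free-text label.
#' @export
ground_truth_pose <- function(transform, label = "pose") {
  stopifnot(inherits(transform, "rigid_transform"))
  structure(list(transform = transform, label = label),
            class = "ground_truth_pose")
}

#' Scan a mesh in a known pose
#'
#' Applies the pose, simulates the scan, and echoes the pose so registration
#' can later be scored against ground truth.
#'
#' @param mesh a [triangle_mesh].
#' @param pose a [ground_truth_pose].
#' @param config a [scan_config].
#' @return list with `scan` ([triangle_mesh]) and `pose`.
#' @export
pose_and_scan <- function(mesh, pose, config) {
  stopifnot(inherits(pose, "ground_truth_pose"))
  posed <- rt_apply(pose$transform, mesh)
  list(scan = simulate_scan(posed, config), pose = pose)
}
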