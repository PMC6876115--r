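test_that("rigid transforms satisfy the group axioms", {
  set.seed(21)
  A <- random_rigid(); B <- random_rigid(); C <- random_rigid()
  idm <- rt_to_matrix(rt_compose(A, rt_invert(A)))
  expect_lt(max(abs(idm - diag(4))), 1e-12)
  expect_equal(rt_to_matrix(rt_compose(rt_identity(), A)), rt_to_matrix(A))
  lhs <- rt_to_matrix(rt_compose(rt_compose(A, B), C))
  rhs <- rt_to_matrix(rt_compose(A, rt_compose(B, C)))
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  # compose(T1, T2) applies T2 first
  p <- c(1, 2, 3)
  expect_equal(rt_apply(rt_compose(A, B), p), rt_apply(A, rt_apply(B, p)),
               tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper|reflection")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("kabsch recovers exact poses and rejects degenerate input", {
  set.seed(31)
  src <- matrix(runif(30, -20, 20), 10, 3)
  expect_equal(rt_to_matrix(kabsch(src, src)), diag(4), tolerance = 1e-12)
  truth <- rigid_transform(rot_axis_angle(c(0, 0, 1), 30), c(5, -2, 1))
  fit <- kabsch(src, rt_apply(truth, src))
  expect_lt(max(abs(fit$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - truth$translation)), 1e-9)
  expect_error(kabsch(src[1:2, ], src[1:2, ]),
               class = "fiducialign_degenerate")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), class = "fiducialign_degenerate")
  expect_error(kabsch(src[1:4, ], src[1:5, ]), "equal")
})

test_that("kabsch beats 1000 random rigid transforms on noisy correspondences", {
  set.seed(41)
  src <- matrix(runif(30, -20, 20), 10, 3)
  truth <- random_rigid()
  dst <- rt_apply(truth, src) + matrix(rnorm(30, 0, 0.05), 10, 3)
  fit <- kabsch(src, dst)
  rmsd <- function(tr) sqrt(mean(rowSums((rt_apply(tr, src) - dst)^2)))
  best_random <- min(vapply(1:1000, function(i) rmsd(random_rigid()), numeric(1)))
  expect_lte(rmsd(fit), best_random)
})

test_that("icp on identical meshes converges immediately with monotone trace", {
  cr <- make_cross_marker()
  res <- icp(cr, cr)
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
  expect_lt(res$final_rms, 1e-9)
  expect_true(all(diff(res$rms_trace) <= 1e-12))
})

test_that("icp recovers a perturbed cross-scan pose at paper noise", {
  cr <- make_cross_marker()
  scan <- simulate_scan(cr, scan_config(0.05, 0.5, seed = 7))
  pert <- rigid_transform(rot_axis_angle(c(1, 1, 0), 5), c(2, 0, 0))
  res <- icp(rt_apply(pert, scan), cr, reject_distance_mm = 3)
  expect_true(all(diff(res$rms_trace) <= 1e-12))    # monotone descent
  rec <- rt_difference(rt_invert(pert), res$transform)
  expect_lt(rec$angle_deg, 0.5)
  expect_lt(rec$translation_mm, 0.2)
  expect_lte(res$final_rms, 0.075)                  # 1.5 sigma
})

test_that("icp recovers a sphere-scan centre; rotation is a symmetry mode", {
  # a bare sphere is rotation-invariant about its centre, so only the
  # translation component of the pose is observable
  sp <- make_sphere_marker(10, 2)
  scan <- simulate_scan(sp, scan_config(0.05, 0.8, seed = 7))
  pert <- rigid_transform(rot_axis_angle(c(1, 1, 0), 5), c(2, 0, 0))
  res <- icp(rt_apply(pert, scan), sp, reject_distance_mm = 3)
  centre_err <- sqrt(sum((rt_apply(res$transform, rt_apply(pert, c(0, 0, 0))))^2))
  expect_lt(centre_err, 0.2)
  expect_lte(res$final_rms, 0.075)
})

test_that("align_by_fiducial is exact on identical scans and validates landmarks", {
  asm <- attach_to_base(make_sphere_marker(10, 2), fiducial_spec("sphere"))
  lm <- landmark_set(rbind(c(10, 0, 15), c(0, 10, 15), c(0, 0, 25), c(-10, 0, 15)))
  res <- align_by_fiducial(asm, asm, lm, lm)
  expect_lt(max(abs(rt_to_matrix(res$transform) - diag(4))), 1e-9)
  lm2 <- landmark_set(rbind(c(10, 0, 15), c(0, 10, 15)))
  expect_error(align_by_fiducial(asm, asm, lm2, lm2),
               class = "fiducialign_degenerate")
})

test_that("two noisy scans of the same marker register within 2 sigma", {
  cr <- make_cross_marker()
  for (s in c(11L, 12L, 13L)) {
    a <- simulate_scan(cr, scan_config(0.05, 0.8, seed = s))
    b <- simulate_scan(cr, scan_config(0.05, 0.8, seed = s + 100L))
    res <- icp(a, b, reject_distance_mm = 2)
    expect_lte(res$final_rms, 2 * 0.05)
  }
})

test_that("landmark files round-trip and reject malformed lines", {
  lm <- landmark_set(rbind(c(1.5, -2, 3), c(0, 0, 1), c(4, 4, 4)),
                     c("tip", "edge", "apex"))
  f <- withr::local_tempfile(fileext = ".pts")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(back$points, lm$points, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$labels, lm$labels)
  writeLines(c("a 1 2 3", "b 4 5"), f)
  expect_error(read_landmarks(f), "malformed landmark line 2")
})
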