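test_that("a noiseless scan lies on the input surface and is deterministic", {
  s <- make_sphere_marker(10, 2)
  cfg <- scan_config(noise_sigma = 0, sample_spacing = 1, smoothing_iters = 0,
                     seed = 3)
  scan <- simulate_scan(s, cfg)
  d <- fiducialign:::cpp_nearest_on_mesh(scan$vertices, s$vertices, s$faces)$distance
  expect_lt(max(d), cfg$sample_spacing / 2 + 1e-6)
  expect_gt(nrow(scan$vertices), nrow(s$vertices))  # refined to spacing
  scan2 <- simulate_scan(s, cfg)
  expect_identical(scan$vertices, scan2$vertices)   # bitwise determinism
  cfgn <- scan_config(noise_sigma = 0.05, sample_spacing = 1, seed = 9)
  expect_identical(simulate_scan(s, cfgn)$vertices,
                   simulate_scan(s, cfgn)$vertices)
})

test_that("scan RMSE calibrates to noise_sigma on a plane (n >= 1e4)", {
  plane <- make_plane(100, 1)                       # 101^2 > 1e4 vertices
  cfg <- scan_config(noise_sigma = 0.05, sample_spacing = 2,
                     smoothing_iters = 0, seed = 42)
  scan <- simulate_scan(plane, cfg)
  expect_gte(nrow(scan$vertices), 1e4)
  rmse <- sqrt(mean(scan$vertices[, 3]^2))          # distance to z = 0 plane
  expect_lt(abs(rmse - 0.05), 0.005)
})

test_that("smoothing is contractive and does not touch global RNG state", {
  cr <- make_cross_marker()
  vol_bb <- function(m) prod(mesh_bbox(m)["max", ] - mesh_bbox(m)["min", ])
  vols <- vapply(c(0L, 2L, 5L), function(it) {
    vol_bb(simulate_scan(cr, scan_config(0, 1, it, seed = 1)))
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
  set.seed(123); before <- runif(1)
  invisible(simulate_scan(cr, scan_config(0.05, 1, 2, seed = 77)))
  set.seed(123)
  expect_identical(runif(1), before)                # private stream contract
})

test_that("coverage culling drops back-facing faces and can empty a scan", {
  cube <- fiducialign:::box_mesh(c(0, 0, 0), c(10, 10, 10))
  top <- simulate_scan(cube, scan_config(0, 20, coverage_dirs = rbind(c(0, 0, 1))))
  n <- mesh_face_normals(top)
  expect_true(all(n[, 3] > 0))
  expect_error(
    simulate_scan(make_plane(2, 1),
                  scan_config(0, 10, coverage_dirs = rbind(c(0, 0, -1)))),
    class = "fiducialign_empty_scan")
})

test_that("pose_and_scan is translation-equivariant and echoes its pose", {
  s <- make_sphere_marker(6, 2)
  cfg <- scan_config(noise_sigma = 0, sample_spacing = 1, seed = 5)
  base <- simulate_scan(s, cfg)
  pose <- ground_truth_pose(rigid_transform(diag(3), c(5, 0, 0)), "shift")
  out <- pose_and_scan(s, pose, cfg)
  expect_identical(out$pose, pose)
  expect_equal(out$scan$vertices,
               sweep(base$vertices, 2, c(5, 0, 0), "+"), tolerance = 1e-12)
  ident <- pose_and_scan(s, ground_truth_pose(rt_identity()), cfg)
  expect_identical(ident$scan$vertices, base$vertices)
})

test_that("face and arch surrogates are deterministic with stated geometry", {
  f1 <- make_face_surrogate(seed = 4)
  expect_identical(f1$vertices, make_face_surrogate(seed = 4)$vertices)
  expect_false(identical(f1$vertices, make_face_surrogate(seed = 5)$vertices))
  bb <- mesh_bbox(f1)
  expect_gte(bb["max", 2] - bb["min", 2], 150)      # facial height
  expect_lte(bb["max", 2] - bb["min", 2], 210)

  a <- make_arch_surrogate(n_teeth = 14, seed = 2)
  expect_identical(a$vertices, make_arch_surrogate(14, seed = 2)$vertices)
  expect_error(make_arch_surrogate(n_teeth = 4), "n_teeth")
  # exactly n_teeth interior local maxima along the ridge midline
  nt <- 8L * 14L + 1L
  mid <- a$vertices[(4L * nt + 1L):(5L * nt), 3]    # middle grid row (s = 0)
  is_max <- mid[2:(nt - 1)] > mid[1:(nt - 2)] & mid[2:(nt - 1)] > mid[3:nt]
  expect_equal(sum(is_max), 14L)
})

test_that("edge rounding biases the cross more than the sphere", {
  cfg0 <- scan_config(noise_sigma = 0, sample_spacing = 0.8,
                      smoothing_iters = 0, seed = 1)
  expect_lt(edge_rounding_bias("sphere", cfg0), cfg0$sample_spacing / 2)
  expect_lt(edge_rounding_bias("cross", cfg0), cfg0$sample_spacing / 2)
  seeds <- 1:5
  bias <- function(kind, sigma) vapply(seeds, function(s) {
    edge_rounding_bias(kind, scan_config(sigma, 0.8, 5L, seed = s))
  }, numeric(1))
  expect_gt(mean(bias("cross", 0.05)), mean(bias("sphere", 0.05)))
  # monotone in noise on seed-matched runs (on average)
  expect_gte(mean(bias("sphere", 0.10)), mean(bias("sphere", 0.05)))
})
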