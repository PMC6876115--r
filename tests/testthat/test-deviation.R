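test_that("point_to_triangle handles interior, edge and vertex regions", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(point_to_triangle(c(0, 0, 1), tri), 1.0)      # interior
  expect_equal(point_to_triangle(c(3, 0, 0), tri), 1.0)      # vertex region
  expect_equal(point_to_triangle(c(1, 1, 0), tri), 0.0)      # on hypotenuse
  expect_equal(point_to_triangle(c(-1, -1, 0), tri), sqrt(2))
  expect_error(point_to_triangle(c(0, 0, 0),
                                 rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "degenerate")
})

test_that("point_to_triangle agrees with the barycentric grid-search oracle", {
  set.seed(13)
  for (i in 1:1000) {
    tri <- matrix(runif(9, -5, 5), 3, 3)
    p <- runif(3, -8, 8)
    exact <- tryCatch(point_to_triangle(p, tri), error = function(e) NULL)
    if (is.null(exact)) next
    oracle <- fiducialign:::cpp_point_triangle_grid_oracle(p, tri, 200L)
    diam <- max(dist(tri))
    expect_gte(oracle - exact, -1e-12)       # true minimum never above grid
    expect_lte(oracle - exact, 2 * diam / 200)
  }
})

test_that("surface deviation reproduces analytic constant-offset cases", {
  plane <- make_plane(20, 5)
  expect_lt(surface_deviation(plane, plane, sample_spacing = 5)$rmse, 1e-9)
  shifted <- mesh_translate(plane, c(0, 0, 0.30))
  rep <- surface_deviation(shifted, plane, sample_spacing = 5)
  expect_equal(rep$rmse, 0.30, tolerance = 1e-6)
  expect_equal(rep$max_abs, 0.30, tolerance = 1e-6)
  expect_true(rep$mean_abs <= rep$rmse && rep$rmse <= rep$max_abs)
  expect_equal(rep$rmse, sqrt(mean(rep$distances^2)), tolerance = 1e-12)
})

test_that("deviation equals the brute-force oracle on small meshes", {
  set.seed(17)
  src <- make_sphere_marker(5, 1)                       # 80 faces
  ref <- mesh_translate(make_sphere_marker(5.2, 1), c(0.3, -0.1, 0.2))
  rep <- surface_deviation(src, ref, mode = "vertices")
  brute <- brute_force_distances(src$vertices, ref)
  expect_equal(rep$distances, brute, tolerance = 1e-9)
  expect_equal(rep$rmse, sqrt(mean(brute^2)), tolerance = 1e-9)
})

test_that("deviation is rigid-invariant and stable under sampling refinement", {
  set.seed(19)
  src <- make_sphere_marker(8, 2)
  ref <- mesh_translate(make_sphere_marker(8.1, 2), c(0.2, 0, 0))
  base <- surface_deviation(src, ref, sample_spacing = 1)$rmse
  tr <- random_rigid()
  moved <- surface_deviation(rt_apply(tr, src), rt_apply(tr, ref),
                             sample_spacing = 1)$rmse
  expect_lt(abs(moved - base), 1e-9)
  finer <- surface_deviation(src, ref, sample_spacing = 0.5)$rmse
  expect_lt(abs(finer - base) / base, 0.05)
  # monotone in plane offset
  plane <- make_plane(10, 5)
  r <- vapply(c(0.1, 0.2, 0.4), function(off) {
    surface_deviation(mesh_translate(plane, c(0, 0, off)), plane,
                      sample_spacing = 5)$rmse
  }, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("cutoff excludes far points and empties raise a typed error", {
  plane <- make_plane(10, 5)
  far <- mesh_translate(make_plane(2, 5), c(100, 0, 5))
  both <- mesh_concat(plane, far)
  rep <- surface_deviation(both, plane, sample_spacing = 5, cutoff = 1)
  expect_gt(rep$n_excluded, 0)
  expect_lte(rep$max_abs, 1)
  expect_error(surface_deviation(mesh_translate(plane, c(0, 0, 50)), plane,
                                 sample_spacing = 5, cutoff = 1),
               class = "fiducialign_empty_report")
})

test_that("report rounding is half-up with trailing zeros retained", {
  fake <- list(rmse = 0.244, mean_abs = 0.355, max_abs = 0.400)
  out <- report_round(fake)
  expect_identical(out$rmse, "0.24")
  expect_identical(out$mean_abs, "0.36")
  expect_identical(out$max_abs, "0.40")
  expect_equal(round_half_up(0.125, 2), 0.13)   # R's round() would give 0.12
})
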