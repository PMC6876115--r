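test_that("sphere marker is a centred watertight genus-0 surface", {
  s <- make_sphere_marker(10, 3)
  expect_lt(max(abs(mesh_centroid(s))), 1e-9)
  expect_equal(mesh_euler_characteristic(s), 2)
  expect_true(mesh_is_watertight(s))
  # area within 1% of 4 pi r^2 at refinement 4; converges monotonically
  a3 <- mesh_area(s)
  a4 <- mesh_area(make_sphere_marker(10, 4))
  exact <- 4 * pi * 100
  expect_lt(abs(a4 - exact) / exact, 0.01)
  expect_true(a3 < a4 && a4 < exact)
  v3 <- mesh_volume(s)
  v4 <- mesh_volume(make_sphere_marker(10, 4))
  expect_true(v3 < v4 && v4 < 4 / 3 * pi * 1000)
  expect_gt(nrow(make_sphere_marker(10, 4)$vertices), nrow(s$vertices))
  expect_error(make_sphere_marker(-1), "radius")
})

test_that("cross marker is the watertight union of two boxes", {
  cr <- make_cross_marker(arm_length = 20, arm_width = 6, arm_depth = 6)
  expect_equal(mesh_volume(cr), 2 * (20 * 6 * 6) - 6^3, tolerance = 1e-9)
  bb <- mesh_bbox(cr)
  expect_equal(unname(bb["max", ] - bb["min", ]), c(20, 20, 6))
  expect_true(mesh_is_watertight(cr))      # every edge shared by exactly 2 faces
  expect_error(make_cross_marker(arm_length = 5, arm_width = 6), "arm_width")
  expect_error(fiducial_spec("cross", cross_arm_width = 30), "arm_width")
  expect_error(fiducial_spec("sphere", sphere_radius = 0), "positive")
})

test_that("attach_to_base is a rigid placement by mount_offset", {
  spec <- fiducial_spec("sphere", mount_offset = c(0, 0, 15))
  marker <- make_sphere_marker(spec$sphere_radius, 2)
  asm <- attach_to_base(marker, spec)
  nm <- nrow(marker$vertices)
  # marker sub-component comes first: centroid shifted exactly by the offset
  expect_lt(max(abs(colMeans(asm$vertices[seq_len(nm), ]) - c(0, 0, 15))), 1e-9)
  expect_equal(nrow(asm$vertices),
               nm + nrow(make_cylinder(spec$base_diameter, spec$base_height)$vertices))
  expect_length(connected_components(asm), 2L)
  # pairwise distances within the marker preserved exactly
  idx <- c(1L, 5L, 17L, 42L)
  d0 <- dist(marker$vertices[idx, ])
  d1 <- dist(asm$vertices[idx, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
})
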