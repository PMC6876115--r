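test_that("normal inversion is an involution that negates signed volume", {
  s <- make_sphere_marker(8, 2)
  inv <- invert_normals(s)
  expect_identical(inv$vertices, s$vertices)           # geometry untouched
  expect_equal(mesh_volume(inv), -mesh_volume(s), tolerance = 1e-12)
  expect_identical(invert_normals(inv)$faces, s$faces) # involution
})

test_that("connected components partition disjoint parts by face count", {
  a <- make_sphere_marker(5, 2)
  b <- mesh_translate(make_sphere_marker(3, 1), c(30, 0, 0))
  parts <- connected_components(mesh_concat(a, b))
  expect_length(parts, 2L)
  expect_equal(nrow(parts[[1]]$faces), nrow(a$faces))  # ordered descending
  expect_equal(nrow(parts[[2]]$faces), nrow(b$faces))
  single <- connected_components(a)
  expect_length(single, 1L)
  expect_equal(nrow(single[[1]]$faces), nrow(a$faces))
  expect_equal(sum(vapply(parts, function(p) nrow(p$faces), integer(1))),
               nrow(a$faces) + nrow(b$faces))          # faces conserved
})

test_that("crop follows the face-centroid rule and partitions by complement", {
  cube <- fiducialign:::box_mesh(c(0, 0, 0), c(1, 1, 1))
  whole <- crop(cube, region_halfspace(c(0, 0, 1), -10))
  expect_equal(nrow(whole$faces), nrow(cube$faces))    # contains entire mesh
  top <- crop(cube, region_halfspace(c(0, 0, 1), 0.5))
  cen <- (fiducialign:::face_corner(cube, 1) + fiducialign:::face_corner(cube, 2) +
          fiducialign:::face_corner(cube, 3)) / 3
  expect_equal(nrow(top$faces), sum(cen[, 3] >= 0.5))
  bottom <- crop(cube, region_halfspace(c(0, 0, -1), -0.5 + 1e-12))
  expect_equal(nrow(top$faces) + nrow(bottom$faces), nrow(cube$faces))
  expect_error(crop(cube, region_halfspace(c(0, 0, 1), 99)),
               class = "fiducialign_empty_selection")
  inside <- crop(cube, region_box(c(-1, -1, -1), c(2, 2, 2)))
  expect_equal(nrow(inside$faces), nrow(cube$faces))
})
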