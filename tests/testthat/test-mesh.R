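test_that("triangle_mesh validates and cleans its input", {
  expect_error(triangle_mesh(matrix(1, 2, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(triangle_mesh(rbind(c(0, 0, NA)), matrix(0L, 0, 3)), "finite")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 4))), "out of range")
  # zero-area face dropped, unreferenced vertex removed
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0)),
                     rbind(c(1, 2, 3), c(1, 2, 2)))
  expect_equal(nrow(m$faces), 1L)
  expect_equal(nrow(m$vertices), 3L)
})

test_that("area, volume, euler characteristic and watertightness are coherent", {
  cube <- fiducialign:::box_mesh(c(0, 0, 0), c(2, 3, 4))
  expect_equal(mesh_volume(cube), 24)
  expect_equal(mesh_area(cube), 2 * (6 + 8 + 12))
  expect_equal(mesh_euler_characteristic(cube), 2)
  expect_true(mesh_is_watertight(cube))
  expect_false(mesh_is_watertight(make_quad()))
  expect_equal(mesh_bbox(cube), rbind(min = c(0, 0, 0), max = c(2, 3, 4)),
               ignore_attr = TRUE)
})

test_that("mesh_concat keeps parts intact and offsets indices", {
  a <- make_sphere_marker(5, 1)
  b <- mesh_translate(make_sphere_marker(3, 1), c(20, 0, 0))
  both <- mesh_concat(a, b)
  expect_equal(nrow(both$vertices), nrow(a$vertices) + nrow(b$vertices))
  expect_equal(nrow(both$faces), nrow(a$faces) + nrow(b$faces))
  expect_equal(mesh_volume(both), mesh_volume(a) + mesh_volume(b))
})

test_that("vertex normals of a sphere point radially outward", {
  s <- make_sphere_marker(10, 2)
  n <- mesh_vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  expect_gt(min(rowSums(n * radial)), 0.99)
})
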