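test_that("binary and ASCII STL round-trips preserve the triangle soup", {
  m <- make_quad()
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, fb, "binary")
  write_stl(m, fa, "ascii")
  rb <- read_stl(fb)
  ra <- read_stl(fa)
  soup <- function(x) {
    s <- cbind(x$vertices[x$faces[, 1], ], x$vertices[x$faces[, 2], ],
               x$vertices[x$faces[, 3], ])
    s[order(s[, 1], s[, 2], s[, 3], s[, 4]), ]
  }
  expect_equal(soup(rb), soup(m), ignore_attr = TRUE)
  expect_equal(soup(ra), soup(rb), ignore_attr = TRUE)  # dialect equivalence
})

test_that("STL round-trip is exact at float32 precision on irregular coordinates", {
  set.seed(11)
  v <- matrix(runif(30, -50, 50), 10, 3)
  m <- triangle_mesh(v, cbind(1:8, 2:9, 3:10), name = "irregular")
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, f, "binary")
  r <- read_stl(f)
  expect_equal(sort(fiducialign:::float32_quantize(m$vertices)),
               sort(r$vertices), tolerance = 1e-12)
  expect_lt(max(abs(sort(r$vertices) - sort(v))), 1e-4)
})

test_that("malformed STL inputs raise parse errors that locate the fault", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0, 40)), f)               # truncated binary header
  expect_error(read_stl(f), "truncated|malformed")
  writeLines(c("nonsense header", "vertex 0 0 0"), f)
  expect_error(read_stl(f), "solid")
  writeLines(c("solid broken", "  vertex 0 0 0", "  vertex 1 0 0",
               "endsolid broken"), f)
  expect_error(read_stl(f), "multiple of 3")
  expect_error(read_stl(tempfile()), "not found")
})
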