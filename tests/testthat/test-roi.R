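test_that("axis-aligned square rasterizes to the brute-force pixel set", {
  poly <- roi_polygon("sq", c(0, 10, 10, 0), c(0, 0, 10, 10))
  mask <- rasterize_polygon(poly, c(20, 20))
  expect_equal(sum(mask), 121)   # centers 0..10 inclusive, both axes
  # full brute-force agreement over every pixel center
  for (row in 1:20) for (col in 1:20) {
    expect_identical(mask[row, col],
                     oracle_point_in_polygon(col - 1, row - 1, poly$x, poly$y),
                     label = sprintf("pixel (%d,%d)", row, col))
  }
})

test_that("general polygons agree with the point-in-polygon oracle", {
  set.seed(5)
  for (rep in 1:5) {
    k <- sample(3:7, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 4, 13)
    xs <- 15 + r * cos(ang); ys <- 15 + r * sin(ang)
    poly <- roi_polygon("p", xs, ys)
    mask <- rasterize_polygon(poly, c(30, 30))
    ok <- TRUE
    for (row in 1:30) for (col in 1:30) {
      if (!identical(mask[row, col],
                     oracle_point_in_polygon(col - 1, row - 1, xs, ys)))
        ok <- FALSE
    }
    expect_true(ok, label = sprintf("random polygon %d", rep))
  }
})

test_that("rasterized area approximates the shoelace area", {
  poly <- roi_polygon("tri", c(2, 40, 8), c(3, 12, 38))
  mask <- rasterize_polygon(poly, c(45, 45))
  a_true <- polygon_area(poly, 1)
  perim <- sum(sqrt(diff(c(poly$x, poly$x[1]))^2 + diff(c(poly$y, poly$y[1]))^2))
  expect_lt(abs(sum(mask) - a_true), perim + 4)
})

test_that("degenerate polygons are rejected", {
  expect_error(rasterize_polygon(roi_polygon("bad", c(0, 5, 10), c(0, 5, 10)),
                                 c(20, 20)), "degenerate")
  expect_error(polygon_area(roi_polygon("bad", c(0, 5, 10), c(0, 5, 10))),
               "degenerate")
  expect_error(roi_polygon("short", c(0, 1), c(0, 1)))
})

test_that("polygon_area converts pixel area through the calibration", {
  sq <- roi_polygon("sq", c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(polygon_area(sq, 1), 100)
  expect_equal(polygon_area(sq, 1.096), 100 / 1.096^2, tolerance = 1e-12)
  tri <- roi_polygon("tri", c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri, 1), 6)
})

test_that("apply_roi zeroes outside the mask, is idempotent, matches multiply", {
  set.seed(9)
  img <- matrix(runif(100, 0, 100), 10, 10)
  roi <- matrix(sample(c(TRUE, FALSE), 100, replace = TRUE), 10, 10)
  out <- apply_roi(img, roi)
  expect_equal(out, img * roi)                      # elementwise oracle
  expect_equal(apply_roi(out, roi), out)            # idempotent
  expect_equal(apply_roi(img, matrix(TRUE, 10, 10)), img)
  # 3D: same mask on every plane
  st <- array(runif(300), dim = c(10, 10, 3))
  out3 <- apply_roi(st, roi)
  for (z in 1:3) expect_equal(out3[, , z], st[, , z] * roi)
  expect_error(apply_roi(img, matrix(TRUE, 5, 5)), "shape")
})

test_that("ROI polygons round-trip through the text format", {
  poly <- roi_polygon("NMJ042", c(1.5, 20, 18, 2), c(3, 4, 22, 19))
  dir <- withr::local_tempdir()
  path <- write_roi(poly, dir = dir)
  back <- read_roi(path)
  expect_equal(back$nmj_id, "NMJ042")
  expect_equal(back$x, poly$x)
  expect_equal(back$y, poly$y)
})
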