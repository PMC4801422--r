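# Plant an isolated 3D Gaussian spot into a stack.
add_spot <- function(st, y, x, z, amp = 1000, sxy = 2, sz = 1) {
  d <- dim(st)
  for (dy in -4:4) for (dx in -4:4) for (dz in -2:2) {
    yy <- y + dy; xx <- x + dx; zz <- z + dz
    if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3]) next
    st[yy, xx, zz] <- st[yy, xx, zz] +
      amp * exp(-(dy^2 + dx^2) / (2 * sxy^2) - dz^2 / (2 * sz^2))
  }
  st
}

test_that("grey closing matches the dilate-then-erode oracle and fills pits", {
  expect_equal(grey_close_3d(array(1:24, dim = c(2, 3, 4)), 0),
               array(1:24, dim = c(2, 3, 4)))
  # dark voxel inside a bright plateau is filled
  st <- array(500, dim = c(7, 7, 5)); st[4, 4, 3] <- 100
  cl <- grey_close_3d(st, 1)
  expect_equal(cl[4, 4, 3], 500)
  expect_true(all(cl >= st))
  # random stack equals the literal two-pass morphology
  set.seed(14)
  st2 <- array(runif(5 * 6 * 4, 0, 100), dim = c(5, 6, 4))
  cl2 <- grey_close_3d(st2, 1)
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  off <- off[off$dy^2 + off$dx^2 + off$dz^2 <= 1, ]
  at <- function(a, y, x, z, def) {
    d <- dim(a)
    if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) def
    else a[y, x, z]
  }
  dil <- st2
  for (y in 1:5) for (x in 1:6) for (z in 1:4)
    dil[y, x, z] <- max(mapply(function(a, b, c)
      at(st2, y + a, x + b, z + c, -Inf), off$dy, off$dx, off$dz))
  ero <- dil
  for (y in 1:5) for (x in 1:6) for (z in 1:4)
    ero[y, x, z] <- min(mapply(function(a, b, c)
      at(dil, y + a, x + b, z + c, Inf), off$dy, off$dx, off$dz))
  expect_equal(cl2, ero, tolerance = 1e-12)
})

test_that("isolated spots are counted; plateaus merge; the floor excludes dim peaks", {
  st <- array(0, dim = c(40, 40, 10))
  pts <- rbind(c(10, 10, 5), c(10, 25, 5), c(25, 10, 5), c(25, 25, 5), c(33, 33, 6))
  for (i in seq_len(nrow(pts)))
    st <- add_spot(st, pts[i, 1], pts[i, 2], pts[i, 3])
  fp <- matrix(TRUE, 40, 40)
  ss <- find_maxima_3d(st, spot_params(noise_tolerance = 100, min_intensity = 250), fp)
  expect_equal(ss$count, 5L)
  # every planted spot recovered within a voxel
  for (i in seq_len(nrow(pts)))
    expect_true(any(abs(ss$coordinates[, "y"] - pts[i, 1]) < 1.5 &
                      abs(ss$coordinates[, "x"] - pts[i, 2]) < 1.5))
  # plateau of 4 mutually adjacent maximal voxels -> one spot
  st2 <- array(0, dim = c(10, 10, 3))
  st2[5:6, 5:6, 2] <- 500
  ss2 <- find_maxima_3d(st2, spot_params(noise_tolerance = 0, min_intensity = 250),
                        matrix(TRUE, 10, 10))
  expect_equal(ss2$count, 1L)
  # a 200-peak under a 250 floor is dropped
  st3 <- array(0, dim = c(10, 10, 3)); st3[5, 5, 2] <- 200
  expect_equal(find_maxima_3d(st3, spot_params(0, min_intensity = 250),
                              matrix(TRUE, 10, 10))$count, 0L)
  expect_error(find_maxima_3d(st3, spot_params(), matrix(FALSE, 10, 10)), "footprint")
})

test_that("spots outside the footprint are excluded", {
  st <- array(0, dim = c(30, 30, 6))
  st <- add_spot(st, 8, 8, 3)          # inside footprint
  st <- add_spot(st, 24, 24, 3)        # outside
  fp <- matrix(FALSE, 30, 30); fp[1:15, 1:15] <- TRUE
  ss <- find_maxima_3d(st, spot_params(noise_tolerance = 50, min_intensity = 250), fp)
  expect_equal(ss$count, 1L)
  expect_lt(ss$coordinates[1, "y"], 15)
})

test_that("the prominence test rejects noise shoulders of a stronger peak", {
  st <- array(0, dim = c(30, 30, 6))
  st <- add_spot(st, 15, 15, 3, amp = 1000)
  st[15, 21, 3] <- st[15, 21, 3] + 50    # small secondary bump on the flank
  fp <- matrix(TRUE, 30, 30)
  tol <- find_maxima_3d(st, spot_params(noise_tolerance = 100, min_intensity = 30), fp)
  expect_equal(tol$count, 1L)
  no_tol <- find_maxima_3d(st, spot_params(noise_tolerance = 0, min_intensity = 30), fp)
  expect_gte(no_tol$count, 2L)
})

test_that("count is monotone non-increasing in tolerance and floor", {
  set.seed(55)
  st <- array(0, dim = c(60, 60, 12))
  for (i in 1:12)
    st <- add_spot(st, sample(6:54, 1), sample(6:54, 1), sample(3:10, 1),
                   amp = runif(1, 400, 1000))
  st <- st + array(rnorm(length(st), 50, 20), dim = dim(st))
  st[st < 0] <- 0
  fp <- matrix(TRUE, 60, 60)
  counts_tol <- sapply(c(0, 50, 100, 200, 400), function(tt)
    find_maxima_3d(st, spot_params(noise_tolerance = tt, min_intensity = 100), fp)$count)
  expect_true(all(diff(counts_tol) <= 0))
  counts_floor <- sapply(c(100, 200, 300, 500, 800), function(fl)
    find_maxima_3d(st, spot_params(noise_tolerance = 50, min_intensity = fl), fp)$count)
  expect_true(all(diff(counts_floor) <= 0))
})

test_that("presets fix the documented parameters", {
  conf <- spot_preset("confocal")
  expect_identical(conf$noise_tolerance, 100)
  expect_identical(conf$min_intensity, 250)
  expect_identical(conf$closing_radius_px, 1L)
  wf <- spot_preset("widefield")
  expect_identical(wf$min_intensity, "auto-huang")
  expect_identical(wf$noise_tolerance, "auto")
  # the run configuration plumbs the preset through to the spot stage
  expect_identical(nmj_config(preset = "confocal")$spot$noise_tolerance, 100)
  expect_identical(nmj_config(preset = "confocal")$spot$min_intensity, 250)
  expect_identical(nmj_config(preset = "widefield")$spot$min_intensity, "auto-huang")
})

test_that("active zones are counted within outline-and-ROI only", {
  s <- generate_nmj(synth_spec(seed = 41, spot_count = 15L))
  roi <- rasterize_polygon(s$roi, dim(s$pair$marker_stack)[1:2])
  flat <- max_projection(s$pair$marker_stack)
  outline <- segment_outline(flat, roi)
  ss <- count_active_zones(s$pair, outline, roi, spot_params())
  expect_equal(ss$count, nrow(s$truth$spot_coordinates))
  # an empty footprint errors
  expect_error(count_active_zones(s$pair, outline & FALSE, roi, spot_params()),
               "footprint")
})

test_that("noise below half the tolerance barely moves the count", {
  set.seed(83)
  st <- array(0, dim = c(50, 50, 10))
  for (i in 1:10)
    st <- add_spot(st, sample(8:42, 1), sample(8:42, 1), sample(3:8, 1))
  fp <- matrix(TRUE, 50, 50)
  p <- spot_params(noise_tolerance = 100, min_intensity = 250)
  base <- find_maxima_3d(st, p, fp)$count
  noisy <- st + array(runif(length(st), -45, 45), dim = dim(st))
  noisy[noisy < 0] <- 0
  pert <- find_maxima_3d(noisy, p, fp)$count
  expect_lte(abs(pert - base), max(1, ceiling(0.02 * base)))
})
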