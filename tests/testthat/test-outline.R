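cal1 <- calibration(px_per_um_xy = 1)

test_that("rolling-ball subtraction flattens smooth backgrounds, keeps spots", {
  expect_equal(subtract_background(matrix(100, 40, 40), 10),
               matrix(0, 40, 40))
  # constant + small bright spot: spot amplitude preserved, background gone
  img <- matrix(10, 60, 60)
  img[30:32, 30:32] <- 10 + 500
  sb <- subtract_background(img, 20)
  expect_gt(max(sb[30:32, 30:32]), 0.9 * 500)
  expect_lt(max(sb[-(25:37), -(25:37)]), 0.05 * 500)
  # shallow ramp + spots: peak heights preserved within 10%
  ramp <- outer(seq(0, 5, length.out = 60), seq(0, 5, length.out = 60), "+")
  img2 <- ramp
  for (cc in c(15, 45)) img2[cc + (-1:1), cc + (-1:1)] <- img2[cc + (-1:1), cc + (-1:1)] + 300
  sb2 <- subtract_background(img2, 20)
  for (cc in c(15, 45))
    expect_lt(abs(max(sb2[cc + (-1:1), cc + (-1:1)]) - 300), 30)
})

test_that("rolling-ball equals the grey-opening oracle on a small fixture", {
  set.seed(3)
  img <- matrix(runif(20 * 22, 0, 100), 20, 22)
  r <- 4
  # literal oracle: background(x) = max over ball positions touching from
  # below; equivalently erosion then dilation with the ball height profile
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  h <- sqrt(r^2 - off$dy^2 - off$dx^2)
  ero <- matrix(Inf, 20, 22)
  for (i in 1:20) for (j in 1:22) {
    for (k in seq_len(nrow(off))) {
      y <- i + off$dy[k]; x <- j + off$dx[k]
      if (y >= 1 && y <= 20 && x >= 1 && x <= 22)
        ero[i, j] <- min(ero[i, j], img[y, x] - h[k])
    }
  }
  bg <- matrix(-Inf, 20, 22)
  for (i in 1:20) for (j in 1:22) {
    for (k in seq_len(nrow(off))) {
      y <- i - off$dy[k]; x <- j - off$dx[k]
      if (y >= 1 && y <= 20 && x >= 1 && x <= 22)
        bg[i, j] <- max(bg[i, j], ero[y, x] + h[k])
    }
  }
  expect_equal(subtract_background(img, r), pmax(img - bg, 0), tolerance = 1e-12)
})

test_that("outline segmentation removes small specks only when the filter is on", {
  set.seed(12)
  roi <- matrix(TRUE, 120, 120)
  img <- matrix(5, 120, 120)
  img[disc_mask(120, 120, 60, 60, 15)] <- 800   # terminal, ~700 px
  img[20:24, 20:25] <- 800                      # 30-px speck
  img[100:104, 90:95] <- 800                    # 30-px speck
  on <- segment_outline(img, roi, min_particle = 100, filter_on = TRUE)
  off <- segment_outline(img, roi, min_particle = 100, filter_on = FALSE)
  expect_false(any(on[20:24, 20:25]))
  expect_true(any(off[20:24, 20:25]))
  expect_true(any(on[disc_mask(120, 120, 60, 60, 10)]))
  # blank ROI: flagged, not an error
  blank <- segment_outline(matrix(5, 20, 20), matrix(TRUE, 20, 20))
  expect_true(attr(blank, "no_terminal"))
})

test_that("area is calibrated pixel count and additive over components", {
  m <- matrix(FALSE, 80, 80)
  m[disc_mask(80, 80, 20, 20, 8)] <- TRUE
  a1 <- measure_area(m, cal1)
  m2 <- m; m2[disc_mask(80, 80, 60, 60, 11)] <- TRUE
  a2 <- measure_area(matrix(disc_mask(80, 80, 60, 60, 11), 80, 80), cal1)
  expect_equal(measure_area(m2, cal1), a1 + a2)
  expect_equal(measure_area(m, calibration(px_per_um_xy = 6.932)),
               sum(m) / 6.932^2)
  expect_error(measure_area(matrix(FALSE, 4, 4), cal1), "empty")
})

test_that("perimeter follows the center-trace convention", {
  sq <- matrix(FALSE, 20, 20); sq[5:15, 5:15] <- TRUE
  expect_equal(measure_perimeter(sq, cal1), 40)     # 11x11 square
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(measure_perimeter(one, cal1), 0)     # degenerate, documented
  disc <- matrix(disc_mask(120, 120, 60, 60, 50), 120, 120)
  expect_lt(abs(measure_perimeter(disc, cal1) - 2 * pi * 50) / (2 * pi * 50), 0.05)
  # inner contours count: a hole adds boundary length
  holed <- sq; holed[8:12, 8:12] <- FALSE
  expect_gt(measure_perimeter(holed, cal1), 40)
  expect_error(measure_perimeter(matrix(FALSE, 3, 3), cal1), "empty")
})

test_that("watershed splits overlapping discs and applies the 100-px floor", {
  m <- matrix(FALSE, 60, 120)
  m[disc_mask(60, 120, 30, 30, 10)] <- TRUE
  m[disc_mask(60, 120, 30, 46, 10)] <- TRUE       # centers 16 px apart
  bs <- count_boutons_watershed(m, 100)
  expect_equal(bs$count, 2L)
  expect_equal(length(bs$areas), 2L)
  single <- matrix(disc_mask(60, 60, 30, 30, 12), 60, 60)
  expect_equal(count_boutons_watershed(single, 100)$count, 1L)
  small <- matrix(disc_mask(40, 40, 20, 20, 5), 40, 40)  # ~78 px < 100
  expect_equal(count_boutons_watershed(small, 100)$count, 0L)
  empty <- count_boutons_watershed(matrix(FALSE, 10, 10), 100)
  expect_equal(empty$count, 0L)
})

test_that("disc chains of length 1..6 at 1.6 r spacing each yield k boutons", {
  r <- 10
  for (k in 1:6) {
    m <- matrix(FALSE, 60, 40 + 16 * k)
    for (i in seq_len(k))
      m[disc_mask(60, 40 + 16 * k, 30, 20 + 16 * (i - 1), r)] <- TRUE
    expect_equal(count_boutons_watershed(m, 100)$count, k,
                 label = sprintf("chain of %d discs", k))
  }
})
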