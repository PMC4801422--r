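test_that("all four selectors separate two well-separated spikes", {
  cnt <- rep(0, 256)
  cnt[11] <- 100; cnt[201] <- 100   # bins 10 and 200
  for (m in c("renyi", "li", "huang", "moments")) {
    t <- auto_threshold_fun(m)(cnt)
    expect_gte(t, 10)
    expect_lt(t, 200)
  }
})

test_that("each selector matches its exhaustive-scan oracle on seeded mixtures", {
  oracles <- list(renyi = oracle_renyi, li = oracle_li,
                  huang = oracle_huang, moments = oracle_moments)
  for (seed in 1:100) {
    cnt <- random_mixture_histogram(seed)
    for (m in names(oracles)) {
      expect_identical(auto_threshold_fun(m)(cnt),
                       as.integer(oracles[[m]](cnt)),
                       label = sprintf("%s selector, seed %d", m, seed))
    }
  }
})

test_that("selectors are count-scale invariant, deterministic, in range", {
  for (seed in c(3, 17, 42)) {
    cnt <- random_mixture_histogram(seed)
    for (m in c("renyi", "li", "huang", "moments")) {
      f <- auto_threshold_fun(m)
      t1 <- f(cnt)
      expect_identical(t1, f(cnt))              # deterministic
      expect_identical(t1, f(cnt * 7L))         # scale invariant
      expect_gte(t1, 0); expect_lte(t1, 255)
    }
  }
})

test_that("degenerate histograms are rejected", {
  cnt <- rep(0, 256); cnt[100] <- 500
  for (m in c("renyi", "li", "huang", "moments"))
    expect_error(auto_threshold_fun(m)(cnt), "degenerate")
  expect_error(histogram256(numeric(0)))
})

test_that("uniform histogram yields a stable interior threshold", {
  cnt <- rep(10, 256)
  for (m in c("renyi", "li", "huang", "moments")) {
    t <- auto_threshold_fun(m)(cnt)
    expect_identical(t, auto_threshold_fun(m)(cnt))
    expect_gte(t, 1); expect_lte(t, 254)
  }
})

test_that("moments threshold sits near the center of a symmetric histogram", {
  z <- 0:255
  cnt <- round(1e4 * exp(-0.5 * ((z - 128) / 30)^2)) + 1L
  t <- moments_threshold(cnt)
  expect_lt(abs(t - 128), 6)
})

test_that("Li gives a wider (lower) segmentation than Renyi on a shoulder histogram", {
  # low-contrast unimodal background plus a dim shoulder of foreground,
  # the regime where the skeleton stage needs the wider Li segmentation
  set.seed(11)
  x <- c(rnorm(5e4, 60, 18), rnorm(6e3, 140, 30))
  cnt <- tabulate(pmin(pmax(round(x), 0), 255) + 1L, nbins = 256L)
  expect_lte(li_threshold(cnt), renyi_entropy_threshold(cnt))
})

test_that("histogram256 bins over the data range and maps 16-bit data", {
  x <- c(0, 1000, 4000, 65535)
  h <- histogram256(x)
  expect_equal(sum(h$counts), 4)
  expect_equal(h$lo, 0); expect_equal(h$hi, 65535)
  # threshold_mask applies 'strictly above the chosen bin'
  img <- matrix(c(10, 10, 10, 200, 200, 210), 2, 3)
  fg <- threshold_mask(img, "li")
  expect_true(all(fg[img >= 200]))
  expect_false(any(fg[img == 10]))
})
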