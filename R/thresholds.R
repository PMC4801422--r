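## Automatic histogram threshold selection.
##
## All four selectors used by the pipeline operate on a 256-bin histogram
## and return a bin index t in 0..255; foreground is defined as bins
## strictly greater than t. Ties are broken towards the smallest
## qualifying bin. 8- and 16-bit images are mapped to 256 bins over the
## per-image [min, max] range before selection (the classical
## auto-threshold criteria are 8-bit histogram methods).

#' Build a 256-bin intensity histogram
#'
#' Bins span the closed range `[lo, hi]` linearly; the top edge is
#' inclusive. With the default range the per-image minimum and maximum are
#' used, which is how the pipeline maps 16-bit data onto the 8-bit
#' histogram methods.
#'
#' @param x numeric vector, matrix or array of intensities.
#' @param range optional length-2 numeric; defaults to `range(x)`.
#' @return An object of class `histogram256` with fields `counts`
#'   (256 integers), `lo`, `hi` and `width` (bin width).
#' @export
histogram256 <- function(x, range = NULL) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities")
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (hi > lo) {
    idx <- pmin(floor((x - lo) / (hi - lo) * 256), 255)
  } else {
    idx <- rep(0L, length(x))
  }
  counts <- tabulate(idx + 1L, nbins = 256L)
  structure(list(counts = counts, lo = lo, hi = hi,
                 width = if (hi > lo) (hi - lo) / 256 else 0),
            class = "histogram256")
}

as_counts256 <- function(hist) {
  if (inherits(hist, "histogram256")) hist <- hist$counts
  hist <- as.numeric(hist)
  if (length(hist) != 256L) stop("expected a 256-bin histogram")
  if (any(hist < 0) || sum(hist) <= 0) stop("invalid histogram counts")
  hist
}

check_nondegenerate <- function(p) {
  if (sum(p > 0) < 2L) stop("degenerate histogram: fewer than 2 occupied bins")
}

## Candidate thresholds: both classes must carry mass, so t ranges from the
## first occupied bin to one before the last occupied bin.
candidate_range <- function(p) {
  occ <- which(p > 0)
  seq.int(occ[1L] - 1L, occ[length(occ)] - 1L - 1L)  # 0-based bins
}

#' Renyi-entropy automatic threshold
#'
#' Entropy-based threshold selection following Sahoo's three-order scheme
#' as popularized by the common open-source auto-threshold suite: the
#' thresholds maximizing the two-class Renyi entropy at orders rho -> 1
#' (the Shannon/Kapur limit), rho = 1/2 and rho = 2 are combined by the
#' published weighting rule into a single threshold.
#'
#' @param hist a [histogram256] or a plain 256-long vector of counts.
#' @return Integer bin index t in 0..255; foreground is bins `> t`.
#' @export
renyi_entropy_threshold <- function(hist) {
  p <- as_counts256(hist); p <- p / sum(p)
  check_nondegenerate(p)
  ts <- candidate_range(p)
  P1 <- cumsum(p)
  t1 <- entropy_argmax(p, ts, rho = 1)
  t2 <- entropy_argmax(p, ts, rho = 0.5)
  t3 <- entropy_argmax(p, ts, rho = 2)
  ## sort the three candidate thresholds
  s <- sort(c(t1, t2, t3))
  t_a <- s[1L]; t_b <- s[2L]; t_c <- s[3L]
  if (abs(t_a - t_b) <= 5) {
    if (abs(t_b - t_c) <= 5) { b1 <- 1; b2 <- 2; b3 <- 1 }
    else                      { b1 <- 0; b2 <- 1; b3 <- 3 }
  } else {
    if (abs(t_b - t_c) <= 5) { b1 <- 3; b2 <- 1; b3 <- 0 }
    else                      { b1 <- 1; b2 <- 2; b3 <- 1 }
  }
  omega <- P1[t_c + 1L] - P1[t_a + 1L]
  t_star <- t_a * (P1[t_a + 1L] + 0.25 * omega * b1) +
    0.25 * t_b * omega * b2 +
    t_c * (1 - P1[t_c + 1L] + 0.25 * omega * b3)
  as.integer(floor(t_star))
}

## argmax over candidate thresholds of the two-class Renyi entropy of the
## given order (rho = 1 is the Shannon/Kapur limit); smallest bin wins ties.
entropy_argmax <- function(p, ts, rho) {
  P <- cumsum(p)
  best <- -Inf; best_t <- ts[1L]
  for (t in ts) {
    Pt <- P[t + 1L]; Qt <- 1 - Pt
    if (Pt <= 0 || Qt <= 0) next
    lo <- p[seq_len(t + 1L)] / Pt
    hi <- p[(t + 2L):256] / Qt
    if (rho == 1) {
      lo <- lo[lo > 0]; hi <- hi[hi > 0]
      crit <- -sum(lo * log(lo)) - sum(hi * log(hi))
    } else {
      crit <- (log(sum(lo^rho)) + log(sum(hi^rho))) / (1 - rho)
    }
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

#' Li minimum-cross-entropy automatic threshold
#'
#' Minimizes Li and Lee's cross-entropy criterion between the image
#' histogram and its two-level reconstruction, by exhaustive scan over all
#' candidate thresholds. Bin values enter the criterion 1-based so the
#' zero bin carries weight. On low-contrast terminal-marker images this
#' selector sits at or below the Renyi threshold, giving the somewhat
#' wider segmentation the skeleton stage relies on.
#'
#' @inheritParams renyi_entropy_threshold
#' @return Integer bin index t in 0..255; foreground is bins `> t`.
#' @export
li_threshold <- function(hist) {
  p <- as_counts256(hist); p <- p / sum(p)
  check_nondegenerate(p)
  z <- 1:256                       # 1-based bin values
  zp <- z * p
  A <- cumsum(zp); Atot <- A[256]
  P <- cumsum(p)
  ts <- candidate_range(p)
  best <- Inf; best_t <- ts[1L]
  for (t in ts) {
    Pt <- P[t + 1L]; Qt <- 1 - Pt
    if (Pt <= 0 || Qt <= 0) next
    mu1 <- A[t + 1L] / Pt
    mu2 <- (Atot - A[t + 1L]) / Qt
    crit <- -A[t + 1L] * log(mu1) - (Atot - A[t + 1L]) * log(mu2)
    if (crit < best - 1e-12) { best <- crit; best_t <- t }
  }
  as.integer(best_t)
}

#' Huang fuzzy automatic threshold
#'
#' Minimizes Huang and Wang's measure of fuzziness: each bin is assigned a
#' membership to its class (below/above threshold) that decays with the
#' distance to the class mean, and the Shannon entropy of the membership is
#' accumulated over the histogram.
#'
#' @inheritParams renyi_entropy_threshold
#' @return Integer bin index t in 0..255; foreground is bins `> t`.
#' @export
huang_threshold <- function(hist) {
  cnt <- as_counts256(hist)
  p <- cnt / sum(cnt)
  check_nondegenerate(p)
  occ <- which(p > 0)
  C <- occ[length(occ)] - occ[1L]   # dynamic range in bins
  z <- 0:255
  P <- cumsum(p); A <- cumsum(z * p); Atot <- A[256]
  ts <- candidate_range(p)
  best <- Inf; best_t <- ts[1L]
  for (t in ts) {
    Pt <- P[t + 1L]; Qt <- 1 - Pt
    if (Pt <= 0 || Qt <= 0) next
    mu0 <- A[t + 1L] / Pt
    mu1 <- (Atot - A[t + 1L]) / Qt
    u <- ifelse(z <= t, 1 / (1 + abs(z - mu0) / C), 1 / (1 + abs(z - mu1) / C))
    f <- -u * log(u) - (1 - u) * log(1 - u)
    f[u >= 1 - 1e-12] <- 0
    crit <- sum(p * f)
    if (crit < best - 1e-12) { best <- crit; best_t <- t }
  }
  as.integer(best_t)
}

#' Moment-preserving (Tsai) automatic threshold
#'
#' Chooses the threshold whose below-threshold mass fraction best matches
#' the binary fraction p0 derived from preserving the first three grey
#' moments of the histogram in a two-level image.
#'
#' @inheritParams renyi_entropy_threshold
#' @return Integer bin index t in 0..255; foreground is bins `> t`.
#' @export
moments_threshold <- function(hist) {
  p <- as_counts256(hist); p <- p / sum(p)
  check_nondegenerate(p)
  z <- 0:255
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (!is.finite(disc) || disc < 0) stop("moment system has no real roots")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)       # fraction below threshold
  P <- cumsum(p)
  ts <- candidate_range(p)
  d <- abs(P[ts + 1L] - p0)
  as.integer(ts[which.min(d)])      # which.min takes the first (smallest bin)
}

#' Look up an auto-threshold selector by name
#'
#' @param method one of `"renyi"`, `"li"`, `"huang"`, `"moments"`.
#' @return The selector function.
#' @export
auto_threshold_fun <- function(method = c("renyi", "li", "huang", "moments")) {
  switch(match.arg(method),
         renyi = renyi_entropy_threshold,
         li = li_threshold,
         huang = huang_threshold,
         moments = moments_threshold)
}

#' Threshold an image with an automatic selector
#'
#' Computes the 256-bin histogram of `image` (restricted to `mask` when
#' given), runs the named selector and returns the binary foreground mask
#' (strictly above the selected bin). Pixels outside `mask` are always
#' background.
#'
#' @param image numeric matrix or array.
#' @param method selector name, see [auto_threshold_fun()].
#' @param mask optional logical array of the same shape.
#' @return Logical array of the same shape as `image`.
#' @export
threshold_mask <- function(image, method = "renyi", mask = NULL) {
  vals <- if (is.null(mask)) image else image[mask]
  h <- histogram256(vals)
  t <- auto_threshold_fun(method)(h)
  bin <- bin_index(image, h)
  fg <- bin > t
  if (!is.null(mask)) fg <- fg & mask
  fg
}

## Map intensities to the 0..255 bin index of a histogram256.
bin_index <- function(x, hist) {
  if (hist$width == 0) return(array(0L, dim = dim(x) %||% length(x)))
  idx <- pmin(floor((x - hist$lo) / (hist$hi - hist$lo) * 256), 255)
  idx[idx < 0] <- 0L
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
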