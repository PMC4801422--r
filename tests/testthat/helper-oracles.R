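# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit loops, direct criterion evaluation) so
# they share no code path with the package implementations they check.

# --- exhaustive-scan threshold oracles -------------------------------------

oracle_candidates <- function(p) {
  occ <- which(p > 0)
  seq.int(occ[1] - 1L, occ[length(occ)] - 2L)
}

# Two-class Renyi entropy of order rho at threshold t (rho = 1 -> Shannon).
oracle_renyi_component <- function(counts, rho) {
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA
  for (t in oracle_candidates(p)) {
    P <- sum(p[seq_len(t + 1)]); Q <- 1 - P
    if (P <= 0 || Q <= 0) next
    lo <- p[seq_len(t + 1)] / P
    hi <- p[(t + 2):256] / Q
    crit <- if (rho == 1) {
      lo <- lo[lo > 0]; hi <- hi[hi > 0]
      -sum(lo * log(lo)) - sum(hi * log(hi))
    } else {
      (log(sum(lo^rho)) + log(sum(hi^rho))) / (1 - rho)
    }
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# Full Renyi rule: three component thresholds combined by the published
# beta-weighting.
oracle_renyi <- function(counts) {
  p <- counts / sum(counts)
  s <- sort(c(oracle_renyi_component(counts, 1),
              oracle_renyi_component(counts, 0.5),
              oracle_renyi_component(counts, 2)))
  if (abs(s[1] - s[2]) <= 5) {
    if (abs(s[2] - s[3]) <= 5) b <- c(1, 2, 1) else b <- c(0, 1, 3)
  } else {
    if (abs(s[2] - s[3]) <= 5) b <- c(3, 1, 0) else b <- c(1, 2, 1)
  }
  P1 <- cumsum(p)
  omega <- P1[s[3] + 1] - P1[s[1] + 1]
  floor(s[1] * (P1[s[1] + 1] + 0.25 * omega * b[1]) +
          0.25 * s[2] * omega * b[2] +
          s[3] * (1 - P1[s[3] + 1] + 0.25 * omega * b[3]))
}

oracle_li <- function(counts) {
  p <- counts / sum(counts)
  z <- 1:256
  best <- Inf; best_t <- NA
  for (t in oracle_candidates(p)) {
    below <- seq_len(t + 1); above <- (t + 2):256
    P <- sum(p[below]); Q <- sum(p[above])
    if (P <= 0 || Q <= 0) next
    m1 <- sum(z[below] * p[below]) / P
    m2 <- sum(z[above] * p[above]) / Q
    crit <- -sum(z[below] * p[below]) * log(m1) -
      sum(z[above] * p[above]) * log(m2)
    if (crit < best - 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

oracle_huang <- function(counts) {
  p <- counts / sum(counts)
  occ <- which(p > 0)
  C <- occ[length(occ)] - occ[1]
  z <- 0:255
  best <- Inf; best_t <- NA
  for (t in oracle_candidates(p)) {
    below <- seq_len(t + 1); above <- (t + 2):256
    P <- sum(p[below]); Q <- sum(p[above])
    if (P <= 0 || Q <= 0) next
    mu0 <- sum(z[below] * p[below]) / P
    mu1 <- sum(z[above] * p[above]) / Q
    S <- 0
    for (g in 0:255) {
      if (p[g + 1] == 0) next
      u <- if (g <= t) 1 / (1 + abs(g - mu0) / C) else 1 / (1 + abs(g - mu1) / C)
      if (u < 1 - 1e-12)
        S <- S + p[g + 1] * (-u * log(u) - (1 - u) * log(1 - u))
    }
    if (S < best - 1e-12) { best <- S; best_t <- t }
  }
  best_t
}

oracle_moments <- function(counts) {
  p <- counts / sum(counts)
  z <- 0:255
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  p0 <- (z1 - m1) / (z1 - z0)
  best <- Inf; best_t <- NA
  cum <- 0
  P <- cumsum(p)
  for (t in oracle_candidates(p)) {
    d <- abs(P[t + 1] - p0)
    if (d < best - 1e-12) { best <- d; best_t <- t }
  }
  best_t
}

# Random two-Gaussian mixture histogram (integer counts over 256 bins).
random_mixture_histogram <- function(seed) {
  set.seed(seed)
  mu <- sort(runif(2, 20, 230))
  if (diff(mu) < 40) mu[2] <- mu[1] + 40
  sd_ <- runif(2, 5, 20)
  w <- runif(1, 0.2, 0.8)
  n <- 2e4
  x <- c(rnorm(round(n * w), mu[1], sd_[1]), rnorm(round(n * (1 - w)), mu[2], sd_[2]))
  x <- pmin(pmax(round(x), 0), 255)
  tabulate(x + 1L, nbins = 256L)
}

# --- geometry oracles ------------------------------------------------------

# Brute-force point-in-polygon (even-odd with boundary inclusion) over
# every pixel center.
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  on_boundary <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
      on_boundary <- TRUE
  }
  if (on_boundary) return(TRUE)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

disc_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Longest vertex-simple endpoint-to-endpoint path by plain recursive
# enumeration over a weighted edge list (columns from, to, w); a
# self-loop may terminate a path at its last vertex. Endpoints supplied.
oracle_longest_path <- function(edges, endpoints) {
  best <- 0
  extend <- function(v, seen, len) {
    if (v %in% endpoints && len > best) best <<- len
    for (e in seq_len(nrow(edges))) {
      a <- edges$from[e]; b <- edges$to[e]
      if (a != v && b != v) next
      if (a == b) {
        if (v %in% endpoints && len + edges$w[e] > best) best <<- len + edges$w[e]
        next
      }
      nxt <- if (a == v) b else a
      if (nxt %in% seen) next
      extend(nxt, c(seen, nxt), len + edges$w[e])
    }
  }
  for (s in endpoints) extend(s, s, 0)
  best
}
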