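## Synthetic NMJ generator: branched tubular terminals with bouton
## swellings (marker channel) and punctate active zones (spot channel),
## rendered as two-channel z-stacks with out-of-focus blur, background
## and sensor noise, together with the full ground truth (topology,
## bouton count, spot coordinates). Written in the pipeline's file
## dialect so the complete workflow runs end-to-end without real data.

#' Specification for one synthetic NMJ
#'
#' @param seed integer RNG seed; the generated stacks are bit-identical
#'   for equal specs and seeds.
#' @param img_size `c(height, width)` in pixels.
#' @param k_islands number of disconnected terminal compartments.
#' @param k_branches total number of skeleton branches over all islands
#'   (a single island supports 1, 3, 4, 5, ... branches; 2 is
#'   topologically impossible).
#' @param marker_style `"dlg1"` (continuous tube with swellings and
#'   shallow constrictions) or `"syt"` (disjoint bright boutons with
#'   fully dark interbouton gaps).
#' @param tube_width_px full tube width (diameter) in pixels.
#' @param bouton_radius_px bouton disc radius in pixels.
#' @param bouton_spacing_px arc spacing of bouton centers along branches.
#' @param spot_count number of planted active zones.
#' @param spot_min_separation_px minimum 3D separation between spots.
#' @param spot_z_halfwidth spots are planted within this many planes of
#'   the focal plane (active zones spread through the terminal depth).
#' @param amplitude foreground intensity of both channels.
#' @param background `"constant"`, `"ramp"` or `"blobs"`.
#' @param bg_level background intensity level.
#' @param noise_sd Gaussian sensor-noise standard deviation (0 for the
#'   noiseless reference conditions).
#' @param defocus relative intensity of out-of-focus planes (1 =
#'   realistic wide-field haze, which blurs interbouton constrictions the
#'   way real Dlg1 stainings do; 0 = an in-focus specimen, the noiseless
#'   reference conditions under which every ground-truth field is
#'   recoverable exactly).
#' @param psf_sigma_px in-focus Gaussian blur sigma in pixels.
#' @param cal a [calibration()] (defaults to the 63x wide-field geometry:
#'   42 planes, 0.3 um z-step, 6.932 px/um).
#' @param nmj_id identifier used in file names.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, img_size = c(256L, 256L), k_islands = 2L,
                       k_branches = 6L, marker_style = c("dlg1", "syt"),
                       tube_width_px = 2, bouton_radius_px = 7,
                       bouton_spacing_px = 18, spot_count = 25L,
                       spot_min_separation_px = 8, spot_z_halfwidth = 6L,
                       amplitude = 1000,
                       background = c("constant", "ramp", "blobs"),
                       bg_level = 100, noise_sd = 0, defocus = 1, psf_sigma_px = 1,
                       cal = calibration(), nmj_id = sprintf("SYN%03d", seed)) {
  marker_style <- match.arg(marker_style)
  background <- match.arg(background)
  stopifnot(k_islands >= 1, k_branches >= k_islands,
            spot_min_separation_px > 2 * psf_sigma_px)
  if (marker_style == "syt" && bouton_radius_px <= tube_width_px / 2)
    stop("syt style requires bouton radius above the tube half-width")
  structure(as.list(environment()), class = "synth_spec")
}

## ---- topology -----------------------------------------------------------

## Distance from points (px, py) to the segment (x1,y1)-(x2,y2).
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

seg_len <- function(e) sqrt((e$x2 - e$x1)^2 + (e$y2 - e$y1)^2)

## Random tree topology for one island inside a bounding box, grown by
## recursive arm addition with a minimum inter-arm angle of 30 degrees
## (avoids rasterization merges that would silently change the planted
## topology). Returns list(edges=data.frame(x1,y1,x2,y2),
## n_branches, n_junctions).
grow_island <- function(n_branches, bbox, clearance) {
  ## arms must separate by at least 45 degrees: at narrower angles the
  ## rasterized junction wedge displaces the medial axis and leaves no
  ## feasible position for the first on-arm bouton (close enough to avoid
  ## a bare stretch, far enough not to touch the sister arm)
  min_angle <- 45 * pi / 180
  margin <- clearance
  ## branch lengths scale with the available box so small test frames
  ## still grow valid (if small) trees
  Lf <- max(bbox[3] - bbox[1], bbox[4] - bbox[2]) - 2 * margin
  if (Lf < 15) stop("bounding box too small for an island")
  trunk_range <- c(min(80, 0.5 * Lf), min(110, 0.75 * Lf))
  arm_range <- c(min(40, 0.4 * Lf), min(60, 0.6 * Lf))
  rand_in <- function(lo, hi) lo + (hi - lo) * runif(1)
  inside <- function(x, y) x > bbox[1] + margin && x < bbox[3] - margin &&
    y > bbox[2] + margin && y < bbox[4] - margin
  ## trunk
  for (try in 1:200) {
    cx <- rand_in(bbox[1] + margin, bbox[3] - margin)
    cy <- rand_in(bbox[2] + margin, bbox[4] - margin)
    th <- runif(1, 0, pi)
    L <- runif(1, trunk_range[1], trunk_range[2])
    x1 <- cx - cos(th) * L / 2; y1 <- cy - sin(th) * L / 2
    x2 <- cx + cos(th) * L / 2; y2 <- cy + sin(th) * L / 2
    if (inside(x1, y1) && inside(x2, y2)) break
    if (try == 200) stop("could not place island trunk")
  }
  edges <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  junctions <- data.frame(x = numeric(0), y = numeric(0), deg = integer(0))
  n_edges <- 1L
  ## Collision: sampled arm points must stay `clearance` away from every
  ## existing branch, except that the stretch of the arm immediately next
  ## to its attachment point is naturally close to the edges meeting
  ## there (at a 30 degree opening the separation grows as ~s/2, so the
  ## first 2*clearance of arc length is exempted for touching edges).
  sample_pts <- function(x1, y1, x2, y2) {
    L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    t <- seq(2 / L, 1, by = 2 / L)
    cbind(x1 + t * (x2 - x1), y1 + t * (y2 - y1), t * L)
  }
  collision <- function(x1, y1, x2, y2, host = integer(0)) {
    pts <- sample_pts(x1, y1, x2, y2)
    for (i in seq_len(nrow(edges))) {
      touching <- (i %in% host) ||
        (abs(edges$x1[i] - x1) + abs(edges$y1[i] - y1) < 1e-6) ||
        (abs(edges$x2[i] - x1) + abs(edges$y2[i] - y1) < 1e-6)
      keep <- if (touching) pts[, 3] > 2 * clearance else rep(TRUE, nrow(pts))
      if (!any(keep)) next
      d <- dist_to_segment(pts[keep, 1], pts[keep, 2], edges$x1[i],
                           edges$y1[i], edges$x2[i], edges$y2[i])
      if (any(d < clearance)) return(TRUE)
    }
    FALSE
  }
  angle_of <- function(x1, y1, x2, y2) atan2(y2 - y1, x2 - x1)
  ang_ok <- function(a, refs) all(abs(((a - refs + pi) %% (2 * pi)) - pi) > min_angle)
  add_arm_new_point <- function() {
    for (try in 1:80) {
      ei <- sample.int(nrow(edges), 1)
      e <- edges[ei, ]
      t <- runif(1, 0.4, 0.6)
      ax <- e$x1 + t * (e$x2 - e$x1); ay <- e$y1 + t * (e$y2 - e$y1)
      refs <- c(angle_of(ax, ay, e$x1, e$y1), angle_of(ax, ay, e$x2, e$y2))
      a <- runif(1, 0, 2 * pi)
      if (!ang_ok(a, refs)) next
      L <- runif(1, arm_range[1], arm_range[2])
      bx <- ax + cos(a) * L; by <- ay + sin(a) * L
      if (!inside(bx, by)) next
      if (collision(ax, ay, bx, by, host = ei)) next
      ## split edge ei at the attachment point and append the arm
      edges[ei, c("x2", "y2")] <<- c(ax, ay)
      edges[nrow(edges) + 1L, ] <<- c(ax, ay, e$x2, e$y2)
      edges[nrow(edges) + 1L, ] <<- c(ax, ay, bx, by)
      junctions[nrow(junctions) + 1L, ] <<- c(ax, ay, 3L)
      n_edges <<- n_edges + 2L
      return(TRUE)
    }
    FALSE
  }
  add_arm_at_junction <- function() {
    if (nrow(junctions) == 0) return(FALSE)
    for (try in 1:80) {
      ji <- sample.int(nrow(junctions), 1)
      jx <- junctions$x[ji]; jy <- junctions$y[ji]
      near <- which(abs(edges$x1 - jx) + abs(edges$y1 - jy) < 1e-6 |
                      abs(edges$x2 - jx) + abs(edges$y2 - jy) < 1e-6)
      refs <- vapply(near, function(i) {
        e <- edges[i, ]
        if (abs(e$x1 - jx) + abs(e$y1 - jy) < 1e-6)
          angle_of(jx, jy, e$x2, e$y2) else angle_of(jx, jy, e$x1, e$y1)
      }, 0)
      a <- runif(1, 0, 2 * pi)
      if (!ang_ok(a, refs)) next
      L <- runif(1, arm_range[1], arm_range[2])
      bx <- jx + cos(a) * L; by <- jy + sin(a) * L
      if (!inside(bx, by)) next
      if (collision(jx, jy, bx, by)) next
      edges[nrow(edges) + 1L, ] <<- c(jx, jy, bx, by)
      junctions$deg[ji] <<- junctions$deg[ji] + 1L
      n_edges <<- n_edges + 1L
      return(TRUE)
    }
    FALSE
  }
  remaining <- n_branches - 1L
  guard <- 0L
  while (remaining > 0L) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not grow island to the requested branch count")
    if (remaining >= 2L) {
      if (add_arm_new_point()) remaining <- remaining - 2L
    } else {
      if (!add_arm_at_junction())
        stop("infeasible topology: cannot add a single branch without a junction")
      remaining <- remaining - 1L
    }
  }
  list(edges = edges, n_branches = n_edges,
       n_junctions = nrow(junctions), junctions = junctions)
}

## Longest endpoint-to-endpoint path of a planted island, by recursive
## enumeration on the exact planted geometry (the trees are tiny).
planted_longest_path <- function(edges) {
  key <- function(x, y) sprintf("%.4f_%.4f", x, y)
  nodes <- unique(c(key(edges$x1, edges$y1), key(edges$x2, edges$y2)))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  lens <- seg_len(edges)
  for (i in seq_len(nrow(edges))) {
    a <- key(edges$x1[i], edges$y1[i]); b <- key(edges$x2[i], edges$y2[i])
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = lens[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = lens[i]))
  }
  best <- 0
  walk <- function(v, seen, acc) {
    if (acc > best) best <<- acc
    nb <- adj[[v]]
    for (i in seq_len(NROW(nb))) {
      if (nb$to[i] %in% seen) next
      walk(nb$to[i], c(seen, nb$to[i]), acc + nb$w[i])
    }
  }
  for (v in nodes) walk(v, v, 0)
  best
}

## Bouton centers along the planted branches, spaced by `spacing`, kept
## clear of branch endpoints and junctions, and never closer to each
## other than a physical separation floor (two swellings closer than
## their diameter would fuse into one and invalidate the planted count).
place_boutons <- function(edges, spacing, end_clear, min_sep = 0.9 * spacing,
                          seed_centers = NULL, seed_excl = min_sep,
                          other_clear = 0, stride = 2) {
  ## junction points are seeded first: branch points carry a swelling, and
  ## an unswollen junction wedge would read as a spurious bouton
  ## downstream. The filled wedge around a junction extends well into its
  ## arms, so on-arm beads keep the larger `seed_excl` distance from
  ## junction boutons (a bead inside the wedge has no constriction to
  ## split at).
  n_seed <- if (is.null(seed_centers)) 0L else nrow(seed_centers)
  centers <- if (n_seed == 0L)
    matrix(numeric(0), ncol = 2) else unname(as.matrix(seed_centers))
  for (i in seq_len(nrow(edges))) {
    L <- seg_len(edges[i, ])
    if (L < 2 * end_clear + 1) next
    ux <- (edges$x2[i] - edges$x1[i]) / L
    uy <- (edges$y2[i] - edges$y1[i]) / L
    ## walk the branch, placing a center whenever the separation floor
    ## allows; advancing in small steps after a blocked position keeps
    ## bare tube stretches short (long unswollen stretches would read as
    ## spurious boutons after the watershed)
    si <- end_clear
    while (si <= L - end_clear) {
      p <- c(edges$x1[i] + ux * si, edges$y1[i] + uy * si)
      dists <- if (nrow(centers)) sqrt((centers[, 1] - p[1])^2 +
                                         (centers[, 2] - p[2])^2) else numeric(0)
      lim <- c(rep(seed_excl, min(n_seed, length(dists))),
               rep(min_sep, max(0, length(dists) - n_seed)))
      ## a swelling must not touch branches other than its own (it would
      ## bridge them and change the planted topology)
      clear_ok <- TRUE
      if (other_clear > 0) {
        for (j in seq_len(nrow(edges))) {
          if (j == i) next
          if (dist_to_segment(p[1], p[2], edges$x1[j], edges$y1[j],
                              edges$x2[j], edges$y2[j]) < other_clear) {
            clear_ok <- FALSE; break
          }
        }
      }
      if (clear_ok && all(dists >= lim)) {
        centers <- rbind(centers, p)
        si <- si + max(spacing, stride)
      } else {
        si <- si + stride
      }
    }
  }
  centers
}

## Split a total branch budget over islands. Each island starts as one
## unbranched path; adding an arm at a fresh interior point costs two
## branches (the host branch splits), adding one at an existing junction
## costs one. Some totals (e.g. one island, two branches) are
## topologically impossible.
distribute_branches <- function(k_branches, k_islands) {
  per <- rep(1L, k_islands)
  rest <- k_branches - k_islands
  i <- 1L
  while (rest >= 2L) {
    per[i] <- per[i] + 2L
    rest <- rest - 2L
    i <- i %% k_islands + 1L
  }
  if (rest == 1L) {
    j <- which(per >= 3L)[1]
    if (is.na(j))
      stop("infeasible branch/island combination: ", k_branches,
           " branches cannot be realized on ", k_islands, " island(s)")
    per[j] <- per[j] + 1L
  }
  per
}

#' Generate a random planted tree topology
#'
#' Grows `k_islands` disconnected trees with `k_branches` branches in
#' total by recursive arm addition (minimum inter-arm angle 30 degrees,
#' collision-checked against the requested clearance), without rendering
#' any image. Useful for mask-level skeleton fixtures.
#'
#' @param k_branches total branch count over all islands.
#' @param k_islands number of disconnected trees.
#' @param img_size `c(height, width)` bounding frame in pixels.
#' @param clearance minimum distance between non-adjacent arms (px).
#' @param seed RNG seed.
#' @return List with `edges` (data.frame x1,y1,x2,y2,island),
#'   `n_branches`, `n_branching_points`, `n_islands`,
#'   `total_length_px` and `longest_path_px`.
#' @export
generate_topology <- function(k_branches, k_islands, img_size = c(192L, 192L),
                              clearance = 10, seed = 1L) {
  if (exists(".Random.seed", .GlobalEnv)) {
    old_seed <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, .GlobalEnv))
  }
  set.seed(seed)
  per <- distribute_branches(k_branches, k_islands)
  strip_w <- img_size[2] / k_islands
  islands <- vector("list", k_islands)
  for (ii in seq_len(k_islands)) {
    bbox <- c((ii - 1) * strip_w, 0, ii * strip_w, img_size[1])
    islands[[ii]] <- grow_island(per[ii], bbox, clearance)
  }
  edges <- do.call(rbind, lapply(seq_len(k_islands), function(ii)
    cbind(islands[[ii]]$edges, island = ii)))
  list(edges = edges,
       n_branches = sum(vapply(islands, `[[`, 0L, "n_branches")),
       n_branching_points = sum(vapply(islands, `[[`, 0L, "n_junctions")),
       n_islands = k_islands,
       total_length_px = sum(seg_len(edges)),
       longest_path_px = max(vapply(islands, function(is)
         planted_longest_path(is$edges), 0)))
}

#' Rasterize a planted tree as a tubular binary mask
#'
#' @param edges data.frame with columns x1,y1,x2,y2 (0-based pixel
#'   coordinates).
#' @param dims `c(height, width)`.
#' @param tube_width_px full tube width (diameter) in pixels.
#' @return Logical matrix: pixels within half the tube width of any
#'   branch segment.
#' @export
rasterize_tree <- function(edges, dims, tube_width_px = 3) {
  footprint_mask(dims, edges, matrix(numeric(0), ncol = 2), "dlg1",
                 tube_width_px / 2, 0)
}

## ---- rendering ----------------------------------------------------------

## Footprint mask of tubes (dlg1 only) and bouton discs, with radii
## shrunk by `shrink` (used to keep planted spots clear of the margin).
footprint_mask <- function(dims, edges, centers, style, tube_r, bouton_r,
                           shrink = 0) {
  h <- dims[1]; w <- dims[2]
  px <- rep(0:(w - 1), each = h)   # x of each pixel center, column-major
  py <- rep(0:(h - 1), times = w)
  m <- rep(FALSE, h * w)
  if (style == "dlg1") {
    r <- max(tube_r - shrink, 0.5)
    for (i in seq_len(nrow(edges)))
      m <- m | dist_to_segment(px, py, edges$x1[i], edges$y1[i],
                               edges$x2[i], edges$y2[i]) <= r
  }
  rb <- max(bouton_r - shrink, 0.5)
  for (i in seq_len(NROW(centers)))
    m <- m | ((px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= rb^2)
  matrix(m, h, w)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0.01) return(img)
  EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
}

render_background <- function(dims, model, level) {
  h <- dims[1]; w <- dims[2]
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  yy <- matrix(rep(0:(h - 1), times = w), h, w)
  switch(model,
         constant = matrix(level, h, w),
         ramp = level * (0.5 + xx / w + 0.3 * yy / h),
         blobs = {
           bg <- matrix(level * 0.5, h, w)
           for (i in 1:3) {
             cx <- runif(1, 0, w); cy <- runif(1, 0, h)
             s <- runif(1, w / 6, w / 3)
             bg <- bg + level * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * s^2))
           }
           bg
         })
}

#' Generate one synthetic NMJ stack pair with ground truth
#'
#' Builds the planted topology, renders marker and spot channel z-stacks
#' (16-bit integer intensities) and records the ground truth. Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return List of class `nmj_synthesis` with elements `pair`
#'   (an [nmj_stack_pair()]), `truth` (list: `n_islands`, `n_branches`,
#'   `n_branching_points`, `polyline_total_length_um`, `longest_path_um`,
#'   `n_boutons`, `spot_coordinates` (y/x/z matrix, 1-based)), `roi`
#'   (an [roi_polygon()] around the terminal) and `spec`.
#' @export
generate_nmj <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", .GlobalEnv)) {
    old_seed <- get(".Random.seed", .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, .GlobalEnv))
  }
  set.seed(spec$seed)
  dims <- spec$img_size
  cal <- spec$cal
  nz <- cal$n_planes
  tube_r <- spec$tube_width_px / 2
  clearance <- 2 * spec$bouton_radius_px + 10
  ## partition the frame into vertical strips, one island per strip
  k <- spec$k_islands
  strip_w <- dims[2] / k
  per_island <- distribute_branches(spec$k_branches, k)
  islands <- vector("list", k)
  for (ii in seq_len(k)) {
    bbox <- c((ii - 1) * strip_w, 0, ii * strip_w, dims[1])
    islands[[ii]] <- grow_island(per_island[ii], bbox, clearance)
  }
  edges <- do.call(rbind, lapply(seq_len(k), function(ii)
    cbind(islands[[ii]]$edges, island = ii)))
  n_branches <- sum(vapply(islands, `[[`, 0L, "n_branches"))
  n_junctions <- sum(vapply(islands, `[[`, 0L, "n_junctions"))
  total_len_px <- sum(seg_len(edges))
  longest_px <- max(vapply(islands, function(is)
    planted_longest_path(is$edges), 0))
  junction_pts <- do.call(rbind, lapply(islands, function(is)
    as.matrix(is$junctions[, c("x", "y"), drop = FALSE])))
  ## tubular (dlg1) terminals need dense bouton coverage: any bare tube
  ## stretch longer than ~the separation floor would itself exceed the
  ## watershed area floor and read as a spurious bouton. Vesicle (syt)
  ## terminals have no tube, so beads spread at the nominal spacing with
  ## fully dark gaps.
  if (spec$marker_style == "dlg1") {
    centers <- place_boutons(edges, spec$bouton_spacing_px,
                             end_clear = spec$bouton_radius_px - 2,
                             min_sep = spec$bouton_spacing_px,
                             seed_centers = junction_pts,
                             other_clear = spec$bouton_radius_px +
                               spec$tube_width_px / 2 + 6,
                             stride = 2)
  } else {
    centers <- place_boutons(edges, spec$bouton_spacing_px + 4,
                             end_clear = spec$bouton_radius_px + 4,
                             min_sep = spec$bouton_spacing_px + 4,
                             seed_centers = junction_pts,
                             other_clear = spec$bouton_radius_px +
                               spec$tube_width_px / 2 + 6,
                             stride = 2)
  }
  fp <- footprint_mask(dims, edges, centers, spec$marker_style,
                       tube_r, spec$bouton_radius_px)
  ## ---- spots --------------------------------------------------------
  fp_inner <- footprint_mask(dims, edges, centers, spec$marker_style,
                             tube_r, spec$bouton_radius_px, shrink = 3)
  cand <- which(fp_inner)
  if (length(cand) == 0) stop("footprint too thin to host spots")
  z0 <- ceiling(nz / 2)
  zlo <- max(1, z0 - spec$spot_z_halfwidth); zhi <- min(nz, z0 + spec$spot_z_halfwidth)
  spots <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(spots) < spec$spot_count) {
    tries <- tries + 1L
    if (tries > 400L * spec$spot_count)
      stop("infeasible spot packing: cannot satisfy the minimum separation")
    i <- cand[sample.int(length(cand), 1)]
    y <- (i - 1) %% dims[1] + 1; x <- (i - 1) %/% dims[1] + 1
    z <- sample(zlo:zhi, 1)
    if (nrow(spots) > 0) {
      d <- sqrt((spots[, 1] - y)^2 + (spots[, 2] - x)^2 + (spots[, 3] - z)^2)
      if (min(d) < spec$spot_min_separation_px) next
    }
    spots <- rbind(spots, c(y, x, z))
  }
  colnames(spots) <- c("y", "x", "z")
  ## ---- render marker channel ----------------------------------------
  marker2d <- spec$amplitude * fp
  bg <- render_background(dims, spec$background, spec$bg_level)
  defocus_rate <- 1.5     # extra blur sigma per plane away from focus
  focus_sigma <- 2        # planes; axial intensity fall-off
  marker <- array(0, dim = c(dims, nz))
  for (z in seq_len(nz)) {
    wz <- exp(-0.5 * ((z - z0) / focus_sigma)^2)
    if (z != z0) wz <- wz * spec$defocus
    if (wz < 1e-4) { marker[, , z] <- bg; next }
    sig <- spec$psf_sigma_px + defocus_rate * abs(z - z0)
    marker[, , z] <- gaussian_blur(marker2d, sig) * wz + bg
  }
  ## ---- render spot channel ------------------------------------------
  spotstack <- array(0, dim = c(dims, nz))
  sxy <- max(spec$psf_sigma_px, 1)
  sz <- 1
  wrad <- ceiling(3 * sxy)
  for (s in seq_len(nrow(spots))) {
    y <- spots[s, 1]; x <- spots[s, 2]; zc <- spots[s, 3]
    ys <- max(1, y - wrad):min(dims[1], y + wrad)
    xs <- max(1, x - wrad):min(dims[2], x + wrad)
    zs <- max(1, zc - 3):min(nz, zc + 3)
    gy <- exp(-0.5 * ((ys - y) / sxy)^2)
    gx <- exp(-0.5 * ((xs - x) / sxy)^2)
    gz <- exp(-0.5 * ((zs - zc) / sz)^2)
    blob <- spec$amplitude * outer(outer(gy, gx), gz)
    spotstack[ys, xs, zs] <- spotstack[ys, xs, zs] + blob
  }
  spotstack <- spotstack + array(rep(bg * 0.3, nz), dim = c(dims, nz))
  ## ---- noise + quantization -----------------------------------------
  if (spec$noise_sd > 0) {
    marker <- marker + array(rnorm(length(marker), 0, spec$noise_sd),
                             dim = dim(marker))
    spotstack <- spotstack + array(rnorm(length(spotstack), 0, spec$noise_sd),
                                   dim = dim(spotstack))
  }
  quantize <- function(a) {
    a <- round(a); a[a < 0] <- 0; a[a > 65535] <- 65535
    array(as.integer(a), dim = dim(a))
  }
  pair <- nmj_stack_pair(spec$nmj_id, marker_stack = quantize(marker),
                         spot_stack = quantize(spotstack), cal = cal)
  ## ---- ROI: padded convex hull of the terminal footprint -------------
  idx <- which(fp)
  ys <- (idx - 1) %% dims[1]; xs <- (idx - 1) %/% dims[1]
  hull <- grDevices::chull(xs, ys)
  hx <- xs[hull]; hy <- ys[hull]
  cx <- mean(hx); cy <- mean(hy)
  pad <- 8
  vn <- sqrt((hx - cx)^2 + (hy - cy)^2)
  hx <- pmin(pmax(hx + (hx - cx) / vn * pad, 0), dims[2] - 1)
  hy <- pmin(pmax(hy + (hy - cy) / vn * pad, 0), dims[1] - 1)
  roi <- roi_polygon(spec$nmj_id, hx, hy)
  truth <- list(n_islands = k, n_branches = n_branches,
                n_branching_points = n_junctions,
                polyline_total_length_um = total_len_px / cal$px_per_um_xy,
                longest_path_um = longest_px / cal$px_per_um_xy,
                n_boutons = nrow(centers),
                spot_coordinates = spots)
  structure(list(pair = pair, truth = truth, roi = roi, spec = spec),
            class = "nmj_synthesis")
}

#' Write synthetic NMJs as a per-plane fixture directory
#'
#' Emits each synthesis as per-plane TIFFs named by the pipeline's default
#' filename pattern (`<id>_z<zz>_ch<k>.tif`, channel 1 = spot channel,
#' channel 2 = marker channel), an ROI polygon file per id, and a
#' tab-separated ground-truth manifest.
#'
#' @param syntheses list of [generate_nmj()] results.
#' @param directory output directory (created if needed).
#' @return Data frame manifest (one row per id), invisibly; also written
#'   as `ground_truth.tsv` in `directory`.
#' @export
write_fixture_directory <- function(syntheses, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(syntheses, function(s) {
    id <- s$pair$nmj_id
    d <- dim(s$pair$marker_stack)
    for (z in seq_len(d[3])) {
      write_tiff_stack(s$pair$spot_stack[, , z],
                       file.path(directory, sprintf("%s_z%02d_ch1.tif", id, z)))
      write_tiff_stack(s$pair$marker_stack[, , z],
                       file.path(directory, sprintf("%s_z%02d_ch2.tif", id, z)))
    }
    write_roi(s$roi, dir = directory)
    t <- s$truth
    data.frame(nmj_id = id, n_islands = t$n_islands,
               n_branches = t$n_branches,
               n_branching_points = t$n_branching_points,
               total_length_um = t$polyline_total_length_um,
               longest_path_um = t$longest_path_um,
               n_boutons = t$n_boutons,
               n_spots = nrow(t$spot_coordinates))
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nmj_id = character(0), n_islands = integer(0),
               n_branches = integer(0), n_branching_points = integer(0),
               total_length_um = numeric(0), longest_path_um = numeric(0),
               n_boutons = integer(0), n_spots = integer(0))
  write.table(manifest, file.path(directory, "ground_truth.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
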