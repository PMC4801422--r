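## Terminal-outline segmentation on the marker-channel projection and the
## outline-derived features: NMJ area, perimeter, and watershed-based
## bouton count.

#' Segment the NMJ outline
#'
#' Background-subtracts the flat marker image (rolling ball, radius 20 by
#' default), restricts to the ROI, and thresholds with the Renyi-entropy
#' selector computed on within-ROI pixels only (intensity statistics
#' outside the ROI would bias the histogram). Optionally removes
#' connected components smaller than `min_particle` pixels ("Remove small
#' particles", floor 100 px by default), which guards against background
#' speckle in e.g. Hrp stainings.
#'
#' @param flat_marker 2D numeric matrix (flat marker-channel projection).
#' @param roi logical ROI mask of the same shape.
#' @param min_particle small-particle floor in pixels.
#' @param filter_on apply the small-particle filter?
#' @param ball_radius rolling-ball radius in pixels.
#' @param method threshold selector (the main macro uses `"renyi"`).
#' @return Logical outline mask with attribute `no_terminal` (TRUE when
#'   thresholding found no foreground; the mask is then all-FALSE).
#' @export
segment_outline <- function(flat_marker, roi, min_particle = 100L,
                            filter_on = TRUE, ball_radius = 20,
                            method = "renyi") {
  stopifnot(identical(dim(flat_marker), dim(roi)))
  img <- subtract_background(flat_marker, ball_radius)
  img <- apply_roi(img, roi)
  mask <- tryCatch(threshold_mask(img, method, mask = roi),
                   error = function(e) array(FALSE, dim = dim(img)))
  if (filter_on && any(mask)) mask <- remove_small_particles(mask, min_particle)
  attr(mask, "no_terminal") <- !any(mask)
  mask
}

#' Measure mask area in square micrometres
#'
#' @param mask logical outline mask.
#' @param cal a [calibration()] object.
#' @return Area in um^2 (pixel count / px_per_um^2).
#' @export
measure_area <- function(mask, cal) {
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  n / cal$px_per_um_xy^2
}

## Moore-neighbour boundary tracing. `mask` is padded internally; `start`
## is c(row, col) of a boundary pixel and `back` the background neighbour
## the trace enters from. Returns the ordered contour as an n x 2 matrix
## of (row, col) pixel centers (closed implicitly; single pixels give one
## row).
moore_trace <- function(mask, start, back) {
  ## clockwise Moore neighbourhood starting at north
  nb <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
               ncol = 2, byrow = TRUE)
  at <- function(p) mask[p[1], p[2]]
  contour <- matrix(start, ncol = 2)
  p <- start; b <- back
  first_next <- NULL
  repeat {
    ## index of b in p's neighbourhood
    db <- b - p
    k0 <- which(nb[, 1] == db[1] & nb[, 2] == db[2])
    found <- FALSE
    for (s in 1:8) {
      k <- (k0 + s - 1L) %% 8L + 1L
      q <- p + nb[k, ]
      if (at(q)) {
        b <- p + nb[(k - 2L) %% 8L + 1L, ]
        found <- TRUE
        break
      }
    }
    if (!found) break                     # isolated pixel
    if (is.null(first_next)) {
      first_next <- q
    } else if (all(p == start) && all(q == first_next)) {
      break                               # Jacob's stopping criterion
    }
    contour <- rbind(contour, q)
    p <- q
  }
  if (nrow(contour) > 1) contour <- contour[-nrow(contour), , drop = FALSE]
  contour
}

contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  cl <- rbind(contour, contour[1, ])
  steps <- abs(diff(cl))
  sum(ifelse(steps[, 1] + steps[, 2] == 2, sqrt(2), 1))
}

#' Measure mask perimeter in micrometres
#'
#' Total boundary length over all connected components, tracing each outer
#' and inner (hole) contour as the closed polygon through boundary-pixel
#' centers and summing step lengths (1 for axial, sqrt(2) for diagonal
#' moves). A single isolated pixel contributes 0 by this center-trace
#' convention.
#'
#' @param mask logical outline mask.
#' @param cal a [calibration()] object.
#' @return Perimeter in um.
#' @export
measure_perimeter <- function(mask, cal) {
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  pm <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  total <- 0
  ## outer contours: one per 8-connected component; start at the first
  ## pixel in column-major scan, whose left neighbour is background.
  lab <- label_components(pm, 8L)
  nlab <- attr(lab, "n_labels")
  for (l in seq_len(nlab)) {
    i <- which(lab == l)[1]
    start <- c((i - 1L) %% nrow(pm) + 1L, (i - 1L) %/% nrow(pm) + 1L)
    total <- total + contour_length(moore_trace(pm, start, start + c(0L, -1L)))
  }
  ## inner contours: 4-connected background components not touching the
  ## border are holes; trace the object boundary around each, starting at
  ## the object pixel above the hole's first pixel.
  bg <- label_components(!pm, 4L)
  nbg <- attr(bg, "n_labels")
  if (nbg > 0) {
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    for (l in setdiff(seq_len(nbg), border_labs)) {
      i <- which(bg == l)[1]
      hole1 <- c((i - 1L) %% nrow(pm) + 1L, (i - 1L) %/% nrow(pm) + 1L)
      start <- hole1 + c(0L, -1L)       # object pixel left of the hole
      total <- total + contour_length(moore_trace(pm, start, hole1))
    }
  }
  total / cal$px_per_um_xy
}

#' Split an outline mask into boutons by watershed
#'
#' Boutons appear as swellings separated by constrictions of the
#' terminal; the Euclidean distance transform of the outline peaks inside
#' each swelling, and a watershed of the (inverted) distance map splits
#' the mask at the constrictions. Resulting regions with area at or above
#' `min_bouton_area` (100 px by default, an empirically set floor) are
#' counted as boutons; smaller fragments stay part of the outline for
#' area/perimeter but do not count.
#'
#' @param mask logical outline mask.
#' @param min_bouton_area area floor in pixels.
#' @param tolerance watershed merge tolerance on the distance map
#'   (regional maxima shallower than this against their saddle are merged
#'   with the dominant neighbouring region; 0.5 suppresses the spurious
#'   half-pixel maxima of a discrete distance transform, the convention
#'   of EDM-based binary watersheds).
#' @return A `bouton_set`: list with `labels` (integer matrix, split
#'   regions above the floor, relabeled 1..count), `count` and `areas`
#'   (pixel counts per label).
#' @export
count_boutons_watershed <- function(mask, min_bouton_area = 100L,
                                    tolerance = 0.5) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) {
    return(structure(list(labels = array(0L, dim = dim(mask)), count = 0L,
                          areas = integer(0)), class = "bouton_set"))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- EBImage::imageData(ws)
  bouton_set_from_labels(lab, min_bouton_area)
}

bouton_set_from_labels <- function(lab, min_area) {
  nlab <- max(lab)
  if (nlab == 0) {
    return(structure(list(labels = array(0L, dim = dim(lab)), count = 0L,
                          areas = integer(0)), class = "bouton_set"))
  }
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= min_area)
  out <- array(0L, dim = dim(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  structure(list(labels = out, count = length(keep),
                 areas = as.integer(sizes[keep])),
            class = "bouton_set")
}

#' @export
print.bouton_set <- function(x, ...) {
  cat(sprintf("<bouton_set> %d boutons, areas %s px\n", x$count,
              paste(x$areas, collapse = ", ")))
  invisible(x)
}
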