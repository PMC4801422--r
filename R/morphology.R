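## Grey-level morphology primitives shared by the segmentation stages.

## Offsets of a disc (2D) or ball (3D) of integer radius r as an
## integer matrix with one row per offset (columns: dy, dx[, dz]).
disc_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, ]
  as.matrix(g)
}

ball_offsets_3d <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r, dz = -r:r)
  g <- g[g$dy^2 + g$dx^2 + g$dz^2 <= r^2 + 1e-9, ]
  as.matrix(g)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grey-level opening of the image by
#' a ball-shaped (non-flat, spherical cap) structuring function of the
#' given radius — the classical rolling-ball construction: the background
#' under each pixel is the highest position of a ball of that radius
#' rolled beneath the intensity surface — and subtracts it, clipping at
#' zero. Effective for the smooth out-of-focus haze around NMJ terminals
#' when the radius comfortably exceeds the structure diameter scale.
#'
#' @param image 2D numeric matrix.
#' @param radius ball radius in pixels (pipeline default 20).
#' @return Background-subtracted matrix, same shape, non-negative.
#' @export
subtract_background <- function(image, radius = 20) {
  stopifnot(is.matrix(image), radius >= 1)
  off <- disc_offsets(radius)
  h <- sqrt(pmax(radius^2 - off[, "dy"]^2 - off[, "dx"]^2, 0))
  er <- cpp_grey_morph_2d(image, as.integer(off[, "dx"]),
                          as.integer(off[, "dy"]), h, dilate = FALSE)
  bg <- cpp_grey_morph_2d(er, as.integer(off[, "dx"]),
                          as.integer(off[, "dy"]), h, dilate = TRUE)
  pmax(image - bg, 0)
}

#' 3D grey-level closing
#'
#' Grey dilation followed by grey erosion with a flat discrete ball of the
#' given radius (radius 0 is the identity). Fills small dark gaps inside
#' bright puncta so that intensity dips within one active zone do not
#' split its local maximum.
#'
#' @param stack 3D numeric array (y, x, z).
#' @param radius_px integer radius of the structuring element.
#' @return Closed stack; pointwise `>=` the input.
#' @export
grey_close_3d <- function(stack, radius_px = 1L) {
  stopifnot(length(dim(stack)) == 3L, radius_px >= 0)
  if (radius_px == 0L) return(stack)
  off <- ball_offsets_3d(radius_px)
  off <- off[, c("dy", "dx", "dz"), drop = FALSE]
  d <- dim(stack)
  dil <- cpp_flat_morph_3d(as.numeric(stack), d, off, dilate = TRUE)
  ero <- cpp_flat_morph_3d(dil, d, off, dilate = FALSE)
  array(ero, dim = d)
}

## Connectivity offset tables.
offsets_2d <- function(connectivity = 8L) {
  g <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = 0L)
  g <- g[!(g$d1 == 0 & g$d2 == 0), ]
  if (connectivity == 4L) g <- g[abs(g$d1) + abs(g$d2) == 1L, ]
  as.matrix(g)
}

offsets_3d_26 <- function() {
  g <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1)
  g <- g[!(g$d1 == 0 & g$d2 == 0 & g$d3 == 0), ]
  as.matrix(g)
}

#' Label connected components
#'
#' Connected-component labeling of a logical 2D matrix (4- or
#' 8-connectivity) or 3D array (26-connectivity), labels assigned in
#' raster-scan order from 1.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 for 2D input; 3D input always uses 26.
#' @return Integer array of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  d <- dim(mask)
  if (length(d) == 2L) {
    off <- offsets_2d(connectivity)
    dims <- c(d, 1L)
  } else if (length(d) == 3L) {
    off <- offsets_3d_26()
    dims <- d
  } else stop("mask must be 2D or 3D")
  lab <- cpp_label(as.logical(mask), as.integer(dims), off)
  n <- attr(lab, "n_labels")
  lab <- array(as.integer(lab), dim = d)
  attr(lab, "n_labels") <- n
  lab
}

#' Remove connected components below an area floor
#'
#' @param mask logical matrix.
#' @param min_px minimum component area in pixels (components `< min_px`
#'   are deleted; 8-connectivity).
#' @return Filtered logical matrix.
#' @export
remove_small_particles <- function(mask, min_px) {
  lab <- label_components(mask, 8L)
  if (attr(lab, "n_labels") == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_labels"))
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim = dim(mask))
}

#' Skeletonize a binary mask
#'
#' Homotopy-preserving two-subiteration (Guo-Hall) thinning to a
#' one-pixel-wide, 8-connected skeleton: the medial axis along the center
#' of the terminal. The number of connected components is preserved and
#' the output is a subset of the input.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_thin(mask)
}

#' Extend skeleton tips to the centerline ends
#'
#' Thinning retracts free branch ends by roughly the local half-width,
#' systematically shortening length measurements. This helper walks each
#' endpoint outward along its terminal direction, within the original
#' segmentation mask, for as long as the distance-to-boundary stays at
#' the endpoint's local radius — which places the tip at the end of the
#' centerline rather than at the retracted thinning limit.
#'
#' @param skel logical skeleton mask (thinning output).
#' @param mask the segmentation mask the skeleton was computed from.
#' @param slack tolerated drop of the distance map below the endpoint
#'   radius before the walk stops (pixels).
#' @return The extended skeleton (still a subset of `mask`).
#' @export
extend_skeleton_tips <- function(skel, mask, slack = 0.7) {
  stopifnot(identical(dim(skel), dim(mask)))
  if (!any(skel)) return(skel)
  d <- dim(skel)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  nc <- neighbor_count(skel)
  ends <- which(skel & nc == 1L)
  nb <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  for (i in ends) {
    r0 <- (i - 1L) %% d[1] + 1L; c0 <- (i - 1L) %/% d[1] + 1L
    ## terminal direction: away from the single neighbour
    dir <- NULL
    for (k in seq_len(nrow(nb))) {
      rr <- r0 + nb[k, 1]; cc <- c0 + nb[k, 2]
      if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2] && skel[rr, cc])
        dir <- -nb[k, ]
    }
    if (is.null(dir)) next
    rad <- dm[r0, c0]
    pr <- r0; pc <- c0
    for (s in 1:20) {
      qr <- pr + dir[1]; qc <- pc + dir[2]
      if (qr < 1 || qr > d[1] || qc < 1 || qc > d[2]) break
      if (!mask[qr, qc] || dm[qr, qc] < rad - slack) break
      ## do not fuse with unrelated skeleton pixels
      touches <- FALSE
      for (k in seq_len(nrow(nb))) {
        tr <- qr + nb[k, 1]; tc <- qc + nb[k, 2]
        if (tr == pr && tc == pc) next
        if (tr >= 1 && tr <= d[1] && tc >= 1 && tc <= d[2] && skel[tr, tc])
          touches <- TRUE
      }
      if (touches) break
      skel[qr, qc] <- TRUE
      pr <- qr; pc <- qc
    }
  }
  skel
}
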