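## Active-zone counting in the spot (Brp) channel: 3D grey closing, 3D
## local-maxima detection with plateau merging and a prominence test,
## and an intensity floor, all restricted to the NMJ outline.

#' Spot-detection parameters
#'
#' @param closing_radius_px radius of the 3D grey-closing structuring
#'   element (default 1, a small ball).
#' @param noise_tolerance prominence a maximum must have over its
#'   surrounding saddle to count, in intensity units; `"auto"` uses 10%
#'   of the within-footprint dynamic range.
#' @param min_intensity peak-intensity floor; `"auto-huang"` derives it
#'   from the Huang threshold of the within-footprint histogram.
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(closing_radius_px = 1L, noise_tolerance = "auto",
                        min_intensity = "auto-huang") {
  stopifnot(closing_radius_px >= 0)
  if (is.numeric(noise_tolerance)) stopifnot(noise_tolerance >= 0)
  structure(list(closing_radius_px = as.integer(closing_radius_px),
                 noise_tolerance = noise_tolerance,
                 min_intensity = min_intensity),
            class = "spot_params")
}

#' Spot-detection presets
#'
#' The wide-field preset determines the intensity floor automatically
#' (Huang) and uses a prominence tolerance of 10% of the dynamic range;
#' the confocal preset fixes maxima noise tolerance 100 and puncta
#' intensity floor 250.
#'
#' @param preset `"widefield"` or `"confocal"`.
#' @return A [spot_params()] object.
#' @export
spot_preset <- function(preset = c("widefield", "confocal")) {
  preset <- match.arg(preset)
  if (preset == "confocal") {
    spot_params(closing_radius_px = 1L, noise_tolerance = 100,
                min_intensity = 250)
  } else {
    spot_params(closing_radius_px = 1L, noise_tolerance = "auto",
                min_intensity = "auto-huang")
  }
}

#' Find 3D local intensity maxima (spots)
#'
#' A voxel is maximal when it is `>=` all of its 26 neighbours; mutually
#' touching maximal voxels (26-connectivity) collapse into one spot,
#' reported at their centroid ("local maxima ... do not touch other local
#' maxima, horizontally/vertically or diagonally"). Spots are then
#' filtered by (i) peak intensity `>= min_intensity` (Huang-derived floor
#' when `"auto-huang"`), (ii) x/y position inside `footprint`, and (iii)
#' prominence: a spot survives only if no strictly higher voxel is
#' reachable without descending more than `noise_tolerance` below its
#' peak.
#'
#' @param stack 3D numeric array (y, x, z), typically grey-closed.
#' @param params a [spot_params()].
#' @param footprint 2D logical mask restricting spot x/y positions (the
#'   NMJ outline intersected with the ROI).
#' @return A `spot_set`: list with `coordinates` (matrix, columns
#'   y/x/z, voxel centroids, 1-based), `count`, `peaks` (peak
#'   intensities) and the resolved `min_intensity`/`noise_tolerance`.
#' @export
find_maxima_3d <- function(stack, params = spot_params(), footprint) {
  d <- dim(stack)
  stopifnot(length(d) == 3L, identical(d[1:2], dim(footprint)))
  if (!any(footprint)) stop("empty footprint")
  inside <- stack[rep(footprint, d[3])]
  min_int <- params$min_intensity
  if (identical(min_int, "auto-huang")) {
    h <- histogram256(inside)
    t <- huang_threshold(h)
    min_int <- h$lo + (t + 1) * h$width
  }
  tol <- params$noise_tolerance
  if (identical(tol, "auto")) tol <- 0.1 * diff(range(inside))
  maxima <- cpp_local_maxima_3d(as.numeric(stack), d)
  maxima <- array(maxima, dim = d)
  ## only consider maxima above the floor and inside the footprint
  maxima <- maxima & (stack >= min_int) &
    array(rep(footprint, d[3]), dim = d)
  lab <- label_components(maxima)
  n <- attr(lab, "n_labels")
  if (n == 0L) {
    return(structure(list(coordinates = matrix(numeric(0), ncol = 3,
                                               dimnames = list(NULL, c("y", "x", "z"))),
                          count = 0L, peaks = numeric(0),
                          min_intensity = min_int, noise_tolerance = tol),
                     class = "spot_set"))
  }
  idx <- which(lab > 0)
  grp <- lab[idx]
  ys <- (idx - 1L) %% d[1] + 1L
  xs <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  zs <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  cy <- tapply(ys, grp, mean); cx <- tapply(xs, grp, mean)
  cz <- tapply(zs, grp, mean)
  peaks <- tapply(stack[idx], grp, max)
  seeds <- tapply(idx, grp, `[`, 1L) - 1L   # 0-based linear seeds
  keep <- cpp_prominence_keep(as.numeric(stack), d,
                              as.integer(seeds), as.numeric(peaks), tol)
  coords <- cbind(y = as.numeric(cy), x = as.numeric(cx),
                  z = as.numeric(cz))[keep, , drop = FALSE]
  structure(list(coordinates = coords, count = sum(keep),
                 peaks = as.numeric(peaks)[keep],
                 min_intensity = min_int, noise_tolerance = tol),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spots (floor %.1f, tolerance %.1f)\n",
              x$count, x$min_intensity, x$noise_tolerance))
  invisible(x)
}

#' Count active zones in an NMJ stack pair
#'
#' Applies the 3D grey closing to the spot channel, then detects 3D local
#' maxima restricted to the footprint `outline & roi` (active zones are
#' only counted within the recognized terminal).
#'
#' @param pair an [nmj_stack_pair()].
#' @param outline logical outline mask (marker channel segmentation).
#' @param roi logical ROI mask.
#' @param params a [spot_params()] or the result of [spot_preset()].
#' @return A `spot_set` (see [find_maxima_3d()]).
#' @export
count_active_zones <- function(pair, outline, roi, params = spot_params()) {
  footprint <- outline & roi
  if (!any(footprint)) stop("empty footprint: no terminal outline inside ROI")
  closed <- grey_close_3d(pair$spot_stack, params$closing_radius_px)
  find_maxima_3d(closed, params, footprint)
}
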