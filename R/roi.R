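## Region-of-interest handling. ROIs are closed polygons (one per NMJ,
## drawn by a human to restrict the analysis to the type-1b terminal),
## stored as plain-text vertex lists and rasterized to binary masks with a
## pixel-center even-odd rule. Coordinates are 0-based, x rightward,
## y downward.

#' Construct an ROI polygon
#'
#' @param nmj_id specimen identifier.
#' @param x,y numeric vertex coordinates (pixels, 0-based).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(nmj_id, x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(nmj_id = nmj_id, x = as.numeric(x), y = as.numeric(y)),
            class = "roi_polygon")
}

## Signed shoelace area in px^2 (positive for counter-clockwise in a
## y-down raster frame the sign is flipped, but we only use |area|).
shoelace_px2 <- function(poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon area in square micrometres
#'
#' Shoelace area of the closed polygon divided by the squared pixel
#' calibration. Used e.g. for externally supplied muscle outlines measured
#' at low magnification.
#'
#' @param poly an [roi_polygon()].
#' @param px_per_um pixels per micrometre of the image the polygon was
#'   drawn on.
#' @return Area in um^2.
#' @export
polygon_area <- function(poly, px_per_um = 1) {
  a <- abs(shoelace_px2(poly))
  if (a == 0) stop("degenerate polygon (zero area)")
  a / px_per_um^2
}

#' Rasterize an ROI polygon to a binary mask
#'
#' A pixel belongs to the mask iff its center (col - 1, row - 1) in 0-based
#' coordinates lies inside or on the closed polygon, by the even-odd rule.
#' Vertices outside the frame are allowed; the mask is implicitly clipped.
#'
#' @param poly an [roi_polygon()].
#' @param shape integer vector `c(height, width)` of the target image.
#' @return Logical matrix of dimension `shape` (class `roi_mask` semantics:
#'   at least one `TRUE` pixel).
#' @export
rasterize_polygon <- function(poly, shape) {
  if (abs(shoelace_px2(poly)) == 0) stop("degenerate polygon (zero area)")
  h <- shape[1]; w <- shape[2]
  px <- poly$x; py <- poly$y; n <- length(px)
  mask <- matrix(FALSE, h, w)
  xs <- 0:(w - 1L)
  for (row in seq_len(h)) {
    yc <- row - 1
    inside <- rep(FALSE, w)
    on_edge <- rep(FALSE, w)
    j <- n
    for (i in seq_len(n)) {
      x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
      ## edge crossing test for the horizontal scanline y = yc
      if ((y1 > yc) != (y2 > yc)) {
        xint <- x1 + (yc - y1) / (y2 - y1) * (x2 - x1)
        inside <- xor(inside, xs < xint)
        on_edge <- on_edge | abs(xs - xint) < 1e-9
      }
      ## points exactly on a horizontal edge
      if (y1 == yc && y2 == yc) {
        lo <- min(x1, x2); hi <- max(x1, x2)
        on_edge <- on_edge | (xs >= lo - 1e-9 & xs <= hi + 1e-9)
      }
      if (y1 == yc) on_edge <- on_edge | abs(xs - x1) < 1e-9
      j <- i
    }
    mask[row, ] <- inside | on_edge
  }
  if (!any(mask)) stop("polygon rasterizes to an empty mask")
  mask
}

#' Apply an ROI mask to an image or stack
#'
#' Pixels outside the mask are set to zero; for 3D input the same 2D mask
#' is applied to every plane. Idempotent.
#'
#' @param image 2D matrix or 3D array (y, x[, z]).
#' @param roi logical matrix matching the x/y shape.
#' @return Same-shaped array.
#' @export
apply_roi <- function(image, roi) {
  d <- dim(image)
  if (!identical(d[1:2], dim(roi)))
    stop("ROI shape does not match image x/y shape")
  if (length(d) == 2L) {
    image[!roi] <- 0
  } else {
    image <- image * as.numeric(rep(roi, d[3]))
    dim(image) <- d
  }
  image
}

#' Read an ROI polygon from a text file
#'
#' The format is one vertex per line, `x<TAB>y`, 0-based pixel coordinates;
#' lines starting with `#` are ignored. The NMJ id defaults to the file
#' name stripped of its `.roi.txt` suffix.
#'
#' @param path file path.
#' @param nmj_id optional id override.
#' @return An [roi_polygon()].
#' @export
read_roi <- function(path, nmj_id = NULL) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("x", "y"))
  if (is.null(nmj_id))
    nmj_id <- sub("\\.roi\\.txt$", "", basename(path))
  roi_polygon(nmj_id, tab$x, tab$y)
}

#' Write an ROI polygon to a text file
#'
#' @param poly an [roi_polygon()].
#' @param path destination; defaults to `<nmj_id>.roi.txt` in `dir`.
#' @param dir directory used when `path` is missing.
#' @return The path, invisibly.
#' @export
write_roi <- function(poly, path = NULL, dir = ".") {
  if (is.null(path)) path <- file.path(dir, paste0(poly$nmj_id, ".roi.txt"))
  writeLines(c("# nmjmorph ROI polygon: x<TAB>y, 0-based pixel coordinates",
               sprintf("%g\t%g", poly$x, poly$y)), path)
  invisible(path)
}
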