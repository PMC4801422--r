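## Stack assembly: discover per-plane TIFF files, decode NMJ id / z-plane /
## channel from the filename, and assemble two-channel hyperstacks plus
## maximum-intensity projections ("flat stacks").

#' Default filename pattern for per-plane TIFFs
#'
#' A regular expression with named-like capture groups in fixed order
#' (nmj_id, z, channel). It matches names such as `NMJ007_z03_ch2.tif`.
#' Microscope export conventions vary, so the pattern is a parameter
#' everywhere filenames are decoded.
#' @export
default_filename_pattern <- function() {
  "^(.+)_z([0-9]+)_ch([0-9]+)\\.tiff?$"
}

#' Acquisition calibration
#'
#' @param px_per_um_xy pixels per micrometre in x/y (63x wide-field default
#'   6.932; the 10x snapshot objective is 1.096; confocal 60x is 4.83).
#' @param z_step_um micrometres per z-plane (default 0.3).
#' @param n_planes advisory number of planes per channel (default 42);
#'   the actual depth always comes from the files.
#' @return An object of class `nmj_calibration`.
#' @export
calibration <- function(px_per_um_xy = 6.932, z_step_um = 0.3, n_planes = 42L) {
  stopifnot(px_per_um_xy > 0, z_step_um > 0, n_planes >= 1)
  structure(list(px_per_um_xy = px_per_um_xy, z_step_um = z_step_um,
                 n_planes = as.integer(n_planes)),
            class = "nmj_calibration")
}

#' Decode NMJ id, z-plane and channel from a filename
#'
#' @param filename file name or path.
#' @param pattern regular expression with three capture groups
#'   (nmj_id, z, channel); see [default_filename_pattern()].
#' @return A list with `nmj_id`, `z` (integer, 1-based) and `channel`
#'   (1 or 2), or `NULL` when the name does not match the pattern
#'   (unrecognized files are skipped by the callers, with a warning).
#' @export
parse_filename <- function(filename, pattern = default_filename_pattern()) {
  fn <- basename(filename)
  m <- regexec(pattern, fn)
  g <- regmatches(fn, m)[[1]]
  if (length(g) == 0L) return(NULL)
  if (length(g) < 4L) stop("pattern must define 3 capture groups (id, z, channel)")
  z <- suppressWarnings(as.integer(g[3]))
  ch <- suppressWarnings(as.integer(g[4]))
  if (is.na(z) || z < 1L) stop("z-plane index out of range in '", fn, "'")
  if (is.na(ch) || !(ch %in% 1:2)) stop("channel out of range in '", fn, "'")
  list(nmj_id = g[2], z = z, channel = ch)
}

## Read a single- or multi-page grayscale TIFF as an integer-valued matrix
## (or z-stack array, y/x/z). Values are kept in original intensity units.
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra samples
    p
  })
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

## Write an integer-valued matrix or y/x/z array as (multi-page) 16-bit
## grayscale TIFF. Round-trips exactly for values in 0..65535.
write_tiff_stack <- function(arr, path) {
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (min(arr) < 0 || max(arr) > 65535)
    stop("intensities outside the 16-bit range")
  pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Maximum-intensity z-projection
#'
#' @param stack 3D numeric array (y, x, z).
#' @return 2D matrix, per-pixel maximum over z (the "flat stack").
#' @export
max_projection <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) stop("empty or non-3D stack")
  apply(stack, c(1, 2), max)
}

#' Assemble per-plane TIFFs into two-channel hyperstacks
#'
#' Scans `directory` for files matching `pattern`, groups planes by NMJ id,
#' and for every id with a complete plane set in both channels builds a
#' pair of z-stacks, persisting each channel as `<id>_ch<k>_stack.tif` and
#' its maximum projection as `<id>_ch<k>_flat.tif` in `out_dir`. Ids whose
#' stack files already exist are skipped (idempotent re-runs); ids with
#' missing planes are excluded with a warning.
#'
#' @param directory directory containing per-plane TIFFs.
#' @param pattern filename pattern, see [default_filename_pattern()].
#' @param cal an [calibration()] object attached to each pair.
#' @param out_dir where stacks/flats are written; defaults to `directory`.
#' @return Named list of `nmj_stack_pair` objects (fields `nmj_id`,
#'   `marker_stack` (channel 1... see note), `spot_stack`, `calibration`).
#'   Channel 2 is the terminal/marker channel and channel 1 the active-zone
#'   channel by the package's file convention, mirroring the two-channel
#'   acquisitions (marker = ch2 slot `marker_stack`, spots = ch1 slot
#'   `spot_stack`) — see Details.
#' @details The filename convention maps channel 1 to the active-zone
#'   (spot) channel and channel 2 to the terminal-marker channel. Swap
#'   channels upstream if an acquisition used the opposite order.
#' @export
assemble_stacks <- function(directory, pattern = default_filename_pattern(),
                            cal = calibration(), out_dir = directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  keys <- lapply(files, function(f) {
    k <- tryCatch(parse_filename(f, pattern), error = function(e) {
      warning("skipping '", basename(f), "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(k)) return(NULL)
    c(k, list(path = f))
  })
  keys <- Filter(Negate(is.null), keys)
  unmatched <- setdiff(basename(files), vapply(keys, function(k) basename(k$path), ""))
  unmatched <- unmatched[!grepl("_(stack|flat)\\.tif$|\\.roi\\.txt$|\\.tsv$|\\.txt$", unmatched)]
  if (length(unmatched))
    warning("unrecognized files skipped: ", paste(unmatched, collapse = ", "),
            call. = FALSE)
  ids <- unique(vapply(keys, `[[`, "", "nmj_id"))
  pairs <- list()
  for (id in ids) {
    kk <- keys[vapply(keys, function(k) k$nmj_id == id, TRUE)]
    ok <- TRUE
    chan <- list()
    nmax <- max(vapply(kk, `[[`, 1L, "z"))
    for (ch in 1:2) {
      kc <- kk[vapply(kk, function(k) k$channel == ch, TRUE)]
      zs <- vapply(kc, `[[`, 1L, "z")
      if (length(zs) == 0L || !setequal(zs, seq_len(nmax)) ||
          anyDuplicated(zs)) {
        warning("id '", id, "': incomplete plane set in channel ", ch,
                "; excluded", call. = FALSE)
        ok <- FALSE
        break
      }
      ord <- order(zs)
      planes <- lapply(kc[ord], function(k) {
        p <- tryCatch(read_tiff_stack(k$path), error = function(e) NULL)
        if (is.null(p)) return(NULL)
        p[, , 1L]
      })
      if (any(vapply(planes, is.null, TRUE))) {
        warning("id '", id, "': unreadable plane in channel ", ch,
                "; excluded", call. = FALSE)
        ok <- FALSE
        break
      }
      chan[[ch]] <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
    }
    if (!ok) next
    if (!identical(dim(chan[[1]]), dim(chan[[2]]))) {
      warning("id '", id, "': channel dimensions differ; excluded", call. = FALSE)
      next
    }
    pair <- nmj_stack_pair(id, marker_stack = chan[[2]], spot_stack = chan[[1]],
                           cal = cal)
    stack_paths <- file.path(out_dir, sprintf("%s_ch%d_stack.tif", id, 1:2))
    if (!all(file.exists(stack_paths))) {
      for (ch in 1:2) {
        write_tiff_stack(chan[[ch]], stack_paths[ch])
        write_tiff_stack(max_projection(chan[[ch]]),
                         file.path(out_dir, sprintf("%s_ch%d_flat.tif", id, ch)))
      }
    }
    pairs[[id]] <- pair
  }
  pairs
}

#' Construct an NMJ stack pair
#'
#' @param nmj_id specimen identifier.
#' @param marker_stack 3D array (y, x, z), terminal-marker channel.
#' @param spot_stack 3D array (y, x, z), active-zone channel.
#' @param cal a [calibration()] object.
#' @return An object of class `nmj_stack_pair`.
#' @export
nmj_stack_pair <- function(nmj_id, marker_stack, spot_stack, cal = calibration()) {
  stopifnot(identical(dim(marker_stack), dim(spot_stack)),
            length(dim(marker_stack)) == 3L,
            min(marker_stack) >= 0, min(spot_stack) >= 0)
  structure(list(nmj_id = nmj_id, marker_stack = marker_stack,
                 spot_stack = spot_stack, calibration = cal),
            class = "nmj_stack_pair")
}

#' @export
print.nmj_stack_pair <- function(x, ...) {
  d <- dim(x$marker_stack)
  cat(sprintf("<nmj_stack_pair '%s'> %d x %d px, %d planes, %.3f px/um, %.2f um z-step\n",
              x$nmj_id, d[1], d[2], d[3],
              x$calibration$px_per_um_xy, x$calibration$z_step_um))
  invisible(x)
}
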