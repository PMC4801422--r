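## Batch orchestration reproducing the three-step workflow headlessly:
## convert (stack assembly + projections) -> consume ROI files ->
## analyze (outline, skeleton and spot stages per NMJ), emitting a
## per-NMJ results table, annotated overlay images and quality flags.

#' Pipeline run configuration
#'
#' @param cal a [calibration()].
#' @param marker_kind terminal marker: `"dlg1"`, `"hrp"`, `"syt"`, `"csp"`
#'   (selects the skeleton-stage threshold; Hrp uses Renyi, others Li).
#' @param preset `"widefield"` or `"confocal"`; fixes the spot-stage
#'   defaults (confocal: noise tolerance 100, intensity floor 250).
#' @param min_particle small-particle floor for the outline stage (px).
#' @param small_particle_filter apply the small-particle filter?
#' @param min_bouton_area bouton area floor for the outline watershed (px).
#' @param ball_radius rolling-ball background radius (px).
#' @param spur_prune_um skeleton spur-pruning length (um); 0 disables.
#' @param spot_overrides optional [spot_params()] overriding the preset.
#' @param vesicle_min_area area floor of the vesicle bouton variant (px).
#' @param dilation_radius_px dilation before the vesicle-variant
#'   watershed (px).
#' @param exclude character vector of NMJ ids to skip (the workflow's
#'   human quality checkpoints are consumed as an exclusion list).
#' @return An object of class `nmj_config`.
#' @export
nmj_config <- function(cal = calibration(),
                       marker_kind = c("dlg1", "hrp", "syt", "csp"),
                       preset = c("widefield", "confocal"),
                       min_particle = 100L, small_particle_filter = TRUE,
                       min_bouton_area = 100L, ball_radius = 20,
                       spur_prune_um = 0.5, spot_overrides = NULL,
                       vesicle_min_area = 10L, dilation_radius_px = 2L,
                       exclude = character(0)) {
  marker_kind <- match.arg(marker_kind)
  preset <- match.arg(preset)
  spot <- if (is.null(spot_overrides)) spot_preset(preset) else spot_overrides
  structure(list(cal = cal, marker_kind = marker_kind, preset = preset,
                 min_particle = as.integer(min_particle),
                 small_particle_filter = isTRUE(small_particle_filter),
                 min_bouton_area = as.integer(min_bouton_area),
                 ball_radius = ball_radius, spur_prune_um = spur_prune_um,
                 spot = spot, vesicle_min_area = as.integer(vesicle_min_area),
                 dilation_radius_px = as.integer(dilation_radius_px),
                 exclude = exclude),
            class = "nmj_config")
}

#' Convert per-plane files to hyperstacks and projections
#'
#' Wraps [assemble_stacks()] / [max_projection()]: scans `input_dir` for
#' per-plane TIFFs, writes `<id>_ch<k>_stack.tif` and `<id>_ch<k>_flat.tif`
#' and returns a manifest. Idempotent: already-assembled ids are skipped.
#'
#' @param input_dir directory of per-plane TIFFs.
#' @param config an [nmj_config()].
#' @param pattern filename pattern, see [default_filename_pattern()].
#' @return data.frame manifest with columns `nmj_id`, `n_planes`,
#'   `height`, `width`.
#' @export
run_convert <- function(input_dir, config = nmj_config(),
                        pattern = default_filename_pattern()) {
  pairs <- assemble_stacks(input_dir, pattern, config$cal)
  if (length(pairs) == 0)
    return(data.frame(nmj_id = character(0), n_planes = integer(0),
                      height = integer(0), width = integer(0)))
  do.call(rbind, lapply(pairs, function(p) {
    d <- dim(p$marker_stack)
    data.frame(nmj_id = p$nmj_id, n_planes = d[3], height = d[1],
               width = d[2], row.names = NULL)
  }))
}

#' Analyze one NMJ stack pair
#'
#' Runs the three analysis stages within the ROI: outline (area,
#' perimeter, watershed boutons), skeleton (total length, longest branch
#' length, islands, branches, branching points) and spots (3D active-zone
#' count inside the outline). Stage failures set quality flags instead of
#' aborting.
#'
#' @param pair an [nmj_stack_pair()].
#' @param roi logical ROI mask matching the stack x/y shape (or an
#'   [roi_polygon()], rasterized on the fly).
#' @param config an [nmj_config()].
#' @return A one-row data.frame of class `nmj_result` with the nine
#'   features and a `flags` column (`;`-separated), plus attribute
#'   `detail` carrying the stage objects for overlay rendering.
#' @export
analyze_nmj <- function(pair, roi, config = nmj_config()) {
  if (inherits(roi, "roi_polygon"))
    roi <- rasterize_polygon(roi, dim(pair$marker_stack)[1:2])
  flags <- character(0)
  flat_marker <- max_projection(pair$marker_stack)
  outline <- segment_outline(flat_marker, roi,
                             min_particle = config$min_particle,
                             filter_on = config$small_particle_filter,
                             ball_radius = config$ball_radius)
  area <- per <- 0
  bset <- NULL
  if (attr(outline, "no_terminal")) {
    flags <- c(flags, "no_terminal")
    nb <- 0L
  } else {
    area <- measure_area(outline, config$cal)
    per <- measure_perimeter(outline, config$cal)
    bset <- count_boutons_watershed(outline, config$min_bouton_area)
    nb <- bset$count
  }
  skel_mask <- segment_for_skeleton(flat_marker, roi, config$marker_kind,
                                    ball_radius = config$ball_radius)
  skel <- NULL
  if (attr(skel_mask, "no_terminal")) {
    flags <- c(flags, "empty_skeleton")
    sf <- list(total_length_um = 0, longest_branch_length_um = 0,
               n_islands = 0L, n_branches = 0L, n_branching_points = 0L,
               flags = character(0))
  } else {
    skel <- extend_skeleton_tips(skeletonize(skel_mask), skel_mask)
    graph <- build_skeleton_graph(skel, config$cal, config$spur_prune_um)
    sf <- skeleton_features(graph)
    flags <- c(flags, setdiff(sf$flags, "empty_skeleton"))
  }
  n_spots <- 0L
  sset <- NULL
  if (!attr(outline, "no_terminal")) {
    sset <- tryCatch(count_active_zones(pair, outline, roi, config$spot),
                     error = function(e) NULL)
    if (is.null(sset)) flags <- c(flags, "spot_floor_failed")
    else n_spots <- sset$count
  } else {
    flags <- c(flags, "spot_floor_failed")
  }
  res <- data.frame(nmj_id = pair$nmj_id, area_um2 = area, perimeter_um = per,
                    n_boutons = nb,
                    total_length_um = sf$total_length_um,
                    longest_branch_length_um = sf$longest_branch_length_um,
                    n_islands = sf$n_islands, n_branches = sf$n_branches,
                    n_branching_points = sf$n_branching_points,
                    n_active_zones = n_spots,
                    flags = paste(unique(flags), collapse = ";"),
                    row.names = NULL)
  class(res) <- c("nmj_result", class(res))
  attr(res, "detail") <- list(outline = outline, skeleton = skel,
                              boutons = bset, spots = sset,
                              flat_marker = flat_marker, roi = roi)
  res
}

result_columns <- function(variant = c("main", "bouton")) {
  variant <- match.arg(variant)
  if (variant == "main") {
    c("nmj_id", "area_um2", "perimeter_um", "n_boutons", "total_length_um",
      "longest_branch_length_um", "n_islands", "n_branches",
      "n_branching_points", "n_active_zones", "flags")
  } else {
    c("nmj_id", "n_boutons", "bouton_area_um2", "total_length_um",
      "longest_branch_length_um", "n_islands", "n_branches",
      "n_branching_points", "n_active_zones", "flags")
  }
}

empty_results <- function(variant) {
  cols <- result_columns(variant)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  for (cc in setdiff(cols, c("nmj_id", "flags"))) df[[cc]] <- numeric(0)
  df
}

## Shared batch driver for the two analysis variants.
run_batch <- function(workspace_dir, config, variant, write_overlays) {
  stacks <- list.files(workspace_dir, pattern = "_ch1_stack\\.tif$")
  ids <- sort(sub("_ch1_stack\\.tif$", "", stacks))
  rows <- list()
  for (id in ids) {
    if (id %in% config$exclude) next
    roi_path <- file.path(workspace_dir, paste0(id, ".roi.txt"))
    if (!file.exists(roi_path)) {
      row <- empty_results(variant)[0, ]
      row[1, "nmj_id"] <- id
      for (cc in setdiff(result_columns(variant), c("nmj_id", "flags")))
        row[1, cc] <- NA_real_
      row[1, "flags"] <- "missing_roi"
      rows[[id]] <- row
      next
    }
    ch1 <- read_tiff_stack(file.path(workspace_dir, paste0(id, "_ch1_stack.tif")))
    ch2_path <- file.path(workspace_dir, paste0(id, "_ch2_stack.tif"))
    if (!file.exists(ch2_path)) {
      row <- empty_results(variant)[0, ]
      row[1, "nmj_id"] <- id
      row[1, "flags"] <- "incomplete_stack"
      rows[[id]] <- row
      next
    }
    ch2 <- read_tiff_stack(ch2_path)
    pair <- nmj_stack_pair(id, marker_stack = ch2, spot_stack = ch1,
                           cal = config$cal)
    roi <- rasterize_polygon(read_roi(roi_path, id), dim(ch2)[1:2])
    res <- if (variant == "main") analyze_nmj(pair, roi, config)
           else analyze_nmj_boutons(pair, roi, config)
    if (write_overlays) {
      ov_path <- file.path(workspace_dir, paste0(id, "_annotated.tif"))
      tryCatch(write_overlay(res, ov_path), error = function(e) NULL)
    }
    attr(res, "detail") <- NULL
    rows[[id]] <- res
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else empty_results(variant)
  out <- out[, result_columns(variant)]
  class(out) <- c("nmj_results", "data.frame")
  out
}

#' Run the main analysis over a converted workspace
#'
#' For every id with a hyperstack and an ROI file in `workspace_dir`,
#' runs [analyze_nmj()] and collects one row per NMJ. The table is also
#' written as a UTF-8 tab-separated `nmj_results.txt` with one header
#' row, and a composite annotated image per NMJ (outline yellow,
#' skeleton blue, active zones white) is stored alongside. Ids lacking
#' an ROI are kept with a `missing_roi` flag; stage failures flag, never
#' abort the batch.
#'
#' @param workspace_dir directory holding `<id>_ch<k>_stack.tif` files
#'   and `<id>.roi.txt` polygons (see [run_convert()]).
#' @param config an [nmj_config()].
#' @param write_overlays write annotated images?
#' @return `nmj_results` data.frame (nine features + id + flags).
#' @export
run_analyze <- function(workspace_dir, config = nmj_config(),
                        write_overlays = TRUE) {
  out <- run_batch(workspace_dir, config, "main", write_overlays)
  write.table(out, file.path(workspace_dir, "nmj_results.txt"), sep = "\t",
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  out
}

## Vesicle-marker variant of analyze_nmj: moments threshold + dilation +
## watershed bouton segmentation; bouton area replaces the perimeter and
## the skeleton stage runs on the dilated bouton mask.
analyze_nmj_boutons <- function(pair, roi, config = nmj_config()) {
  if (inherits(roi, "roi_polygon"))
    roi <- rasterize_polygon(roi, dim(pair$marker_stack)[1:2])
  flags <- character(0)
  flat_marker <- max_projection(pair$marker_stack)
  bset <- segment_boutons_vesicle(flat_marker, roi,
                                  min_area = config$vesicle_min_area,
                                  dilation_radius_px = config$dilation_radius_px,
                                  ball_radius = config$ball_radius)
  bf <- bouton_features(bset, config$cal)
  mask <- attr(bset, "mask")
  if (isTRUE(attr(bset, "no_terminal"))) {
    flags <- c(flags, "no_terminal", "empty_skeleton")
    sf <- list(total_length_um = 0, longest_branch_length_um = 0,
               n_islands = 0L, n_branches = 0L, n_branching_points = 0L,
               flags = character(0))
  } else {
    skel <- extend_skeleton_tips(skeletonize(mask), mask)
    graph <- build_skeleton_graph(skel, config$cal, config$spur_prune_um)
    sf <- skeleton_features(graph)
    flags <- c(flags, setdiff(sf$flags, "empty_skeleton"))
  }
  n_spots <- NA_real_
  if (!isTRUE(attr(bset, "no_terminal"))) {
    sset <- tryCatch(count_active_zones(pair, mask, roi, config$spot),
                     error = function(e) NULL)
    if (is.null(sset)) flags <- c(flags, "spot_floor_failed")
    else n_spots <- sset$count
  } else flags <- c(flags, "spot_floor_failed")
  res <- data.frame(nmj_id = pair$nmj_id, n_boutons = bf$n_boutons,
                    bouton_area_um2 = bf$bouton_area_um2,
                    total_length_um = sf$total_length_um,
                    longest_branch_length_um = sf$longest_branch_length_um,
                    n_islands = sf$n_islands, n_branches = sf$n_branches,
                    n_branching_points = sf$n_branching_points,
                    n_active_zones = n_spots,
                    flags = paste(unique(flags), collapse = ";"),
                    row.names = NULL)
  class(res) <- c("nmj_result", class(res))
  attr(res, "detail") <- list(outline = mask, skeleton = NULL, boutons = bset,
                              spots = NULL, flat_marker = flat_marker,
                              roi = roi)
  res
}

#' Run the vesicle-marker bouton variant over a workspace
#'
#' As [run_analyze()], but segmenting boutons with the moments threshold,
#' a dilation step and the 10-px rules appropriate for Syt/Csp stainings;
#' the output columns are the eight features of this variant (bouton
#' area instead of perimeter and NMJ area).
#'
#' @inheritParams run_analyze
#' @return `nmj_results` data.frame (eight features + id + flags),
#'   also written as `nmj_bouton_results.txt`.
#' @export
run_bouton_variant <- function(workspace_dir, config = nmj_config(),
                               write_overlays = FALSE) {
  out <- run_batch(workspace_dir, config, "bouton", write_overlays)
  write.table(out, file.path(workspace_dir, "nmj_bouton_results.txt"),
              sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  out
}

#' @export
print.nmj_results <- function(x, ...) {
  cat(sprintf("<nmj_results> %d NMJ(s)\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a composite annotated image
#'
#' Renders the flat marker image in grey with the recognized outline
#' contour in yellow, the skeleton in blue and detected active zones as
#' white foci, as an RGB TIFF — the reviewable "result picture" of the
#' workflow.
#'
#' @param result an [analyze_nmj()] result carrying its `detail`
#'   attribute.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_overlay <- function(result, path) {
  det <- attr(result, "detail")
  if (is.null(det)) stop("result carries no stage detail")
  base <- det$flat_marker
  base <- base / max(base, 1)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  if (!is.null(det$outline) && any(det$outline)) {
    edge <- det$outline & !shrink_mask(det$outline)
    rgb[, , 1][edge] <- 1; rgb[, , 2][edge] <- 1; rgb[, , 3][edge] <- 0
  }
  if (!is.null(det$skeleton) && any(det$skeleton)) {
    rgb[, , 1][det$skeleton] <- 0; rgb[, , 2][det$skeleton] <- 0.3
    rgb[, , 3][det$skeleton] <- 1
  }
  if (!is.null(det$spots) && det$spots$count > 0) {
    co <- round(det$spots$coordinates)
    for (i in seq_len(nrow(co))) {
      y <- co[i, "y"]; x <- co[i, "x"]
      rgb[y, x, ] <- 1
    }
  }
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  invisible(path)
}

## One-pixel erosion used to draw mask contours.
shrink_mask <- function(mask) {
  d <- dim(mask)
  p <- matrix(FALSE, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & p[(2:(d[1] + 1)) + dr, (2:(d[2] + 1)) + dc]
  }
  out
}
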