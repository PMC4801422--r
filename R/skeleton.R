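## Skeleton extraction on a wider segmentation of the marker channel and
## the five skeleton-derived features: total length, longest branch
## length, islands, branches, branching points.

#' Segment the marker channel for skeletonization
#'
#' The outline threshold (Renyi) is often too restrictive for a faithful
#' skeleton on Dlg1/Syt/Csp stainings, so this stage uses Li's
#' minimum-cross-entropy selector, which yields a somewhat wider
#' segmentation; Hrp-stained terminals keep the Renyi selector.
#'
#' @param flat_marker 2D numeric matrix (flat marker projection).
#' @param roi logical ROI mask.
#' @param marker_kind one of `"dlg1"`, `"syt"`, `"csp"`, `"hrp"`.
#' @param ball_radius rolling-ball radius in pixels.
#' @return Logical mask with attribute `no_terminal`.
#' @export
segment_for_skeleton <- function(flat_marker, roi,
                                 marker_kind = c("dlg1", "syt", "csp", "hrp"),
                                 ball_radius = 20) {
  marker_kind <- match.arg(marker_kind)
  method <- if (marker_kind == "hrp") "renyi" else "li"
  stopifnot(identical(dim(flat_marker), dim(roi)))
  img <- subtract_background(flat_marker, ball_radius)
  img <- apply_roi(img, roi)
  mask <- tryCatch(threshold_mask(img, method, mask = roi),
                   error = function(e) array(FALSE, dim = dim(img)))
  attr(mask, "no_terminal") <- !any(mask)
  mask
}

## Count of 8-neighbours for every skeleton pixel.
neighbor_count <- function(skel) {
  d <- dim(skel)
  p <- matrix(0L, d[1] + 2L, d[2] + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L)] <- skel
  acc <- matrix(0L, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2:(d[1] + 1L)) + dr, (2:(d[2] + 1L)) + dc]
  }
  acc
}

#' Build a weighted branch graph from a skeleton mask
#'
#' Skeleton pixels are classified by their 8-neighbour count: 1 neighbour
#' makes an endpoint, 3 or more a junction pixel; clusters of mutually
#' 8-adjacent junction pixels collapse into a single branching point
#' ("one branching point connects three or more branches"). Branches are
#' traced between node pixels through degree-2 path pixels; geometric
#' length sums unit steps for axial and sqrt(2) for diagonal moves,
#' divided by the pixel calibration. Terminal branches shorter than
#' `spur_prune_um` (default 0.5 um, removing 1-3 px thinning artifacts)
#' are pruned and the classification is recomputed once.
#'
#' @param skel logical skeleton mask (one-pixel-wide curves).
#' @param cal a [calibration()] object.
#' @param spur_prune_um prune terminal branches shorter than this (um);
#'   set to 0 to disable.
#' @return An object of class `skeleton_graph`: list with `nodes`
#'   (data.frame: id, kind `"end"`/`"junction"`/`"isolated"`, component,
#'   y, x of a representative pixel), `edges` (data.frame: from, to,
#'   length_um, component), `n_components`, and the `skel` mask.
#' @export
build_skeleton_graph <- function(skel, cal, spur_prune_um = 0.5) {
  skel <- fill_skeleton_holes(skel)
  g <- skeleton_graph_once(skel, cal)
  if (spur_prune_um > 0 && nrow(g$edges) > 0) {
    endpoint_ids <- g$nodes$id[g$nodes$kind %in% c("end", "isolated")]
    short <- g$edges$length_um < spur_prune_um
    terminal_spur <- short &
      (g$edges$from %in% endpoint_ids | g$edges$to %in% endpoint_ids) &
      !(g$edges$from %in% endpoint_ids & g$edges$to %in% endpoint_ids)
    ## short self-loops at a junction are 1-px holes left by thinning
    tiny_loop <- short & !is.na(g$edges$from) & g$edges$from == g$edges$to
    spur <- terminal_spur | tiny_loop
    if (any(spur)) {
      drop_px <- do.call(rbind, g$edges$interior[spur])
      ## remove spur interior pixels and their endpoint pixels
      for (i in which(spur)) {
        for (nid in c(g$edges$from[i], g$edges$to[i])) {
          if (nid %in% endpoint_ids) {
            px <- g$nodes[g$nodes$id == nid, c("y", "x")]
            drop_px <- rbind(drop_px, as.matrix(px))
          }
        }
      }
      skel2 <- skel
      if (!is.null(drop_px) && nrow(drop_px) > 0)
        skel2[drop_px] <- FALSE
      ## removing a spur can leave its attachment pixel as a bump on the
      ## remaining curve; a final thinning pass restores 1-px geometry
      skel2 <- cpp_thin(skel2)
      g <- skeleton_graph_once(skel2, cal)
    }
  }
  g$edges$interior <- NULL
  g
}

## Thinning can leave 1-2 px background holes where branches cross,
## which would read as spurious micro-loops or twin junctions. Fill them
## and re-thin (the fill creates a small solid block that thins back to
## a clean junction).
fill_skeleton_holes <- function(skel, max_hole_px = 4L) {
  bg <- label_components(!skel, 4L)
  nb <- attr(bg, "n_labels")
  if (nb == 0L) return(skel)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0L], nbins = nb)
  fill <- setdiff(which(sizes <= max_hole_px), border)
  if (length(fill)) {
    skel[array(bg %in% fill, dim = dim(skel))] <- TRUE
    skel <- cpp_thin(skel)
  }
  skel
}

## Geometric length of a traced pixel chain: the chain is resampled
## every few pixels and chord lengths are summed. For purely axial or
## purely diagonal chains this equals the classical step sum (1 per
## axial, sqrt(2) per diagonal move); for oblique chains it removes the
## staircase inflation of the step sum (up to ~8% at worst-case angles).
chord_length <- function(pts, step = 7L) {
  n <- nrow(pts)
  if (n < 2) return(0)
  idx <- unique(c(seq(1L, n, by = step), n))
  p <- pts[idx, , drop = FALSE]
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

## Single pass of pixel classification + branch tracing.
skeleton_graph_once <- function(skel, cal) {
  d <- dim(skel)
  comp <- label_components(skel, 8L)
  ncomp <- attr(comp, "n_labels")
  nc <- neighbor_count(skel)
  nc[!skel] <- -1L
  ## node pixels: endpoints (1 neighbour), isolated (0), junctions (>= 3)
  junc_mask <- skel & nc >= 3L
  jlab <- label_components(junc_mask, 8L)
  njunc <- attr(jlab, "n_labels")
  node_of_pixel <- array(0L, dim = d)   # node id per node pixel
  nodes <- list()
  nid <- 0L
  for (j in seq_len(njunc)) {
    nid <- nid + 1L
    idx <- which(jlab == j)
    node_of_pixel[idx] <- nid
    r <- (idx - 1L) %% d[1] + 1L; c <- (idx - 1L) %/% d[1] + 1L
    nodes[[nid]] <- data.frame(id = nid, kind = "junction",
                               component = comp[idx[1]],
                               y = round(mean(r)), x = round(mean(c)))
  }
  for (i in which(skel & (nc == 1L | nc == 0L))) {
    nid <- nid + 1L
    node_of_pixel[i] <- nid
    r <- (i - 1L) %% d[1] + 1L; c <- (i - 1L) %/% d[1] + 1L
    nodes[[nid]] <- data.frame(id = nid,
                               kind = if (nc[i] == 0L) "isolated" else "end",
                               component = comp[i], y = r, x = c)
  }
  nodes <- if (nid > 0) do.call(rbind, nodes) else
    data.frame(id = integer(), kind = character(), component = integer(),
               y = integer(), x = integer())
  ## trace edges from every node pixel into each non-node neighbour, and
  ## directly between adjacent node pixels of different nodes.
  nb <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  px_len <- function(dr, dc) if (abs(dr) + abs(dc) == 2) sqrt(2) else 1
  edges <- list(); eidx <- 0L
  visited_path <- array(FALSE, dim = d)   # path pixels consumed by a trace
  seen_pair_step <- new.env(hash = TRUE)
  node_pixels <- which(node_of_pixel > 0L)
  for (i in node_pixels) {
    r0 <- (i - 1L) %% d[1] + 1L; c0 <- (i - 1L) %/% d[1] + 1L
    for (k in seq_len(nrow(nb))) {
      r <- r0 + nb[k, 1]; c <- c0 + nb[k, 2]
      if (r < 1 || r > d[1] || c < 1 || c > d[2] || !skel[r, c]) next
      if (node_of_pixel[r, c] > 0L) {
        ## direct node-to-node adjacency (no interior path pixels)
        a <- node_of_pixel[r0, c0]; b <- node_of_pixel[r, c]
        if (a == b) next                   # same junction cluster
        key <- paste(min(a, b), max(a, b), r0, c0, r, c, sep = ",")
        key_rev <- paste(min(a, b), max(a, b), r, c, r0, c0, sep = ",")
        if (!is.null(seen_pair_step[[key]]) || !is.null(seen_pair_step[[key_rev]]))
          next
        seen_pair_step[[key]] <- TRUE
        eidx <- eidx + 1L
        edges[[eidx]] <- list(from = a, to = b,
                              length_um = px_len(nb[k, 1], nb[k, 2]) /
                                cal$px_per_um_xy,
                              component = comp[r0, c0],
                              interior = matrix(integer(0), ncol = 2))
        next
      }
      if (visited_path[r, c]) next
      ## walk along degree-2 path pixels until the next node pixel
      interior <- matrix(c(r, c), ncol = 2)
      origin_id <- node_of_pixel[r0, c0]
      pr <- r0; pc <- c0; cr <- r; cc <- c
      repeat {
        visited_path[cr, cc] <- TRUE
        nxt <- NULL
        for (k2 in seq_len(nrow(nb))) {
          rr <- cr + nb[k2, 1]; cc2 <- cc + nb[k2, 2]
          if (rr < 1 || rr > d[1] || cc2 < 1 || cc2 > d[2]) next
          if (!skel[rr, cc2] || (rr == pr && cc2 == pc)) next
          if (node_of_pixel[rr, cc2] > 0L) {
            ## don't close a trivial loop straight back onto another
            ## pixel of the originating junction cluster
            if (node_of_pixel[rr, cc2] == origin_id && nrow(interior) < 2)
              next
            nxt <- c(rr, cc2, 1L); break
          }
          if (!visited_path[rr, cc2]) nxt <- c(rr, cc2, 0L)
        }
        if (is.null(nxt)) {
          ## closed loop back to start or dead end on visited pixels:
          ## close the cycle to the originating node
          pts <- rbind(c(r0, c0), interior, c(r0, c0))
          eidx <- eidx + 1L
          edges[[eidx]] <- list(from = node_of_pixel[r0, c0],
                                to = node_of_pixel[r0, c0],
                                length_um = chord_length(pts) / cal$px_per_um_xy,
                                component = comp[r0, c0], interior = interior)
          break
        }
        if (nxt[3] == 1L) {
          pts <- rbind(c(r0, c0), interior, nxt[1:2])
          eidx <- eidx + 1L
          edges[[eidx]] <- list(from = node_of_pixel[r0, c0],
                                to = node_of_pixel[nxt[1], nxt[2]],
                                length_um = chord_length(pts) / cal$px_per_um_xy,
                                component = comp[r0, c0], interior = interior)
          break
        }
        pr <- cr; pc <- cc; cr <- nxt[1]; cc <- nxt[2]
        interior <- rbind(interior, nxt[1:2])
      }
    }
  }
  edges <- if (eidx > 0) {
    data.frame(from = vapply(edges, `[[`, 1L, "from"),
               to = vapply(edges, `[[`, 1L, "to"),
               length_um = vapply(edges, `[[`, 1, "length_um"),
               component = vapply(edges, `[[`, 1L, "component"),
               interior = I(lapply(edges, `[[`, "interior")))
  } else {
    data.frame(from = integer(), to = integer(), length_um = numeric(),
               component = integer(), interior = I(list()))
  }
  ## components that are pure cycles (no node pixels at all): count one
  ## closed branch spanning the whole component
  if (ncomp > 0) {
    node_comps <- unique(nodes$component)
    for (ci in setdiff(seq_len(ncomp), node_comps)) {
      idx <- which(comp == ci)
      ## ring length: every pixel has 2 neighbours; sum half of step
      ## lengths over all adjacent pairs
      len <- ring_length(skel, idx, d)
      edges <- rbind(edges,
                     data.frame(from = NA_integer_, to = NA_integer_,
                                length_um = len / cal$px_per_um_xy,
                                component = ci,
                                interior = I(list(matrix(integer(0), ncol = 2)))))
    }
  }
  structure(list(nodes = nodes, edges = edges, n_components = ncomp,
                 skel = skel, calibration = cal),
            class = "skeleton_graph")
}

## Total geometric length of a node-free cycle component (each adjacency
## counted once).
ring_length <- function(skel, idx, d) {
  r <- (idx - 1L) %% d[1] + 1L; c <- (idx - 1L) %/% d[1] + 1L
  len <- 0
  for (i in seq_along(idx)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r[i] + dr; cc <- c[i] + dc
      if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2] || !skel[rr, cc]) next
      len <- len + (if (abs(dr) + abs(dc) == 2) sqrt(2) else 1) / 2
    }
  }
  len
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d components, %d nodes, %d branches, total %.2f um\n",
              x$n_components, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$length_um)))
  invisible(x)
}

#' Compute the five skeleton features
#'
#' Total length is the sum of branch lengths; the longest branch length is
#' the maximal summed length of a cycle-free path between two endpoints
#' (computed exactly by depth-first enumeration; skeleton graphs are small
#' and almost always trees). Islands are connected components of the
#' skeleton; branches are graph edges; branching points are junction
#' nodes. For cyclic graphs with more than `max_nodes_exact` nodes the
#' exact search is replaced by the weighted diameter (longest shortest
#' path) and the result is flagged.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @param max_nodes_exact node-count cap for the exact longest-path search.
#' @return List of class `skeleton_features`: `total_length_um`,
#'   `longest_branch_length_um`, `n_islands`, `n_branches`,
#'   `n_branching_points`, plus `flags` (character vector; `"empty_skeleton"`
#'   or `"longest_path_approx"` when applicable).
#' @export
skeleton_features <- function(graph, max_nodes_exact = 50L) {
  flags <- character(0)
  if (graph$n_components == 0L) {
    return(structure(list(total_length_um = 0, longest_branch_length_um = 0,
                          n_islands = 0L, n_branches = 0L,
                          n_branching_points = 0L, flags = "empty_skeleton"),
                     class = "skeleton_features"))
  }
  ed <- graph$edges
  total <- sum(ed$length_um)
  longest <- 0
  for (ci in seq_len(graph$n_components)) {
    eci <- ed[ed$component == ci, , drop = FALSE]
    nci <- graph$nodes[graph$nodes$component == ci, , drop = FALSE]
    if (nrow(eci) == 0) next
    if (any(is.na(eci$from))) {           # pure cycle: closed path
      longest <- max(longest, sum(eci$length_um))
      next
    }
    if (nrow(nci) > max_nodes_exact) {
      longest <- max(longest, weighted_diameter(nci, eci))
      flags <- union(flags, "longest_path_approx")
    } else {
      longest <- max(longest, longest_endpoint_path(nci, eci))
    }
  }
  structure(list(total_length_um = total, longest_branch_length_um = longest,
                 n_islands = graph$n_components, n_branches = nrow(ed),
                 n_branching_points = sum(graph$nodes$kind == "junction"),
                 flags = flags),
            class = "skeleton_features")
}

#' @export
print.skeleton_features <- function(x, ...) {
  cat(sprintf(paste0("<skeleton_features> total %.2f um, longest %.2f um, ",
                     "%d islands, %d branches, %d branching points\n"),
              x$total_length_um, x$longest_branch_length_um, x$n_islands,
              x$n_branches, x$n_branching_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

## Exact longest endpoint-to-endpoint simple path by DFS over edges with
## vertex-visited marking (parallel edges and self-loops allowed; a
## self-loop may close a path end). Vertex-simple except that the walk may
## end by traversing a self-loop at its last vertex.
longest_endpoint_path <- function(nodes, edges) {
  ends <- nodes$id[nodes$kind %in% c("end", "isolated")]
  ids <- nodes$id
  ## adjacency: list of (edge index) per node
  adj <- lapply(ids, function(v)
    which(edges$from == v | edges$to == v))
  names(adj) <- as.character(ids)
  best <- 0
  ## single node, no endpoints (e.g. junction-only loops): allow any node
  starts <- if (length(ends)) ends else ids
  is_target <- function(v) if (length(ends)) v %in% ends else TRUE
  dfs <- function(v, visited, used_edges, len) {
    if (is_target(v) && len > best) best <<- len
    for (ei in adj[[as.character(v)]]) {
      if (used_edges[ei]) next
      w <- if (edges$from[ei] == v) edges$to[ei] else edges$from[ei]
      if (w == v) {                         # self-loop: traverse and stop
        l2 <- len + edges$length_um[ei]
        if (is_target(v) && l2 > best) best <<- l2
        next
      }
      if (visited[as.character(w)]) next
      visited[as.character(w)] <- TRUE
      used_edges[ei] <- TRUE
      dfs(w, visited, used_edges, len + edges$length_um[ei])
      used_edges[ei] <- FALSE
      visited[as.character(w)] <- FALSE
    }
  }
  for (s in starts) {
    visited <- setNames(rep(FALSE, length(ids)), as.character(ids))
    visited[as.character(s)] <- TRUE
    dfs(s, visited, rep(FALSE, nrow(edges)), 0)
  }
  best
}

## Longest shortest path (weighted diameter) fallback for large cyclic
## graphs: Dijkstra from every node.
weighted_diameter <- function(nodes, edges) {
  ids <- nodes$id
  n <- length(ids)
  idx <- setNames(seq_len(n), as.character(ids))
  best <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u]) || all(done)) break
      done[u] <- TRUE
      uid <- ids[u]
      for (ei in which(edges$from == uid | edges$to == uid)) {
        w <- if (edges$from[ei] == uid) edges$to[ei] else edges$from[ei]
        wi <- idx[as.character(w)]
        if (dist[u] + edges$length_um[ei] < dist[wi])
          dist[wi] <- dist[u] + edges$length_um[ei]
      }
      if (all(done | !is.finite(dist))) break
    }
    best <- max(best, max(dist[is.finite(dist)]))
  }
  best
}
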