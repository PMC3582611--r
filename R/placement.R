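# Globally optimal tile placement via per-direction minimum spanning trees.
#
# The tile grid is an undirected graph whose edges are the adjacent pairs;
# per direction, an edge's weight is the inverse of that direction's
# displacement reliability (+Inf when the reliability is 0, so the tree
# passes through nonstitchable pairs only when connectivity demands it).
# Accumulating offsets along the tree from the anchor tile (0,0) gives
# absolute coordinates, independently per direction.

#' Build the per-direction tile graph
#'
#' @param state A thresholded `stitch_state`.
#' @param direction `"V"`, `"H"` or `"D"`.
#' @return A `tile_graph`: list with `n_rows`, `n_cols` and `edges`, a data
#'   frame with one row per adjacent pair carrying endpoints, `weight`
#'   (`1 / reliability`, `Inf` for reliability 0) and the signed `offset`
#'   from the lower-index to the higher-index tile.
#' @export
build_graph <- function(state, direction) {
  stopifnot(direction %in% .AXES)
  if (length(state$pairs) == 0) {
    return(structure(list(n_rows = state$volume$n_rows,
                          n_cols = state$volume$n_cols,
                          edges = data.frame(a_row = integer(0),
                                             a_col = integer(0),
                                             b_row = integer(0),
                                             b_col = integer(0),
                                             weight = numeric(0),
                                             offset = numeric(0))),
                     class = "tile_graph"))
  }
  edges <- do.call(rbind, lapply(state$pairs, function(p) {
    r <- p$reliability[[direction]]
    data.frame(a_row = p$a_row, a_col = p$a_col,
               b_row = p$b_row, b_col = p$b_col,
               weight = if (r > 0) 1 / r else Inf,
               offset = p$offset[[direction]])
  }))
  structure(list(n_rows = state$volume$n_rows,
                 n_cols = state$volume$n_cols, edges = edges),
            class = "tile_graph")
}

#' Minimum spanning tree of a tile graph
#'
#' Kruskal's algorithm with deterministic tie-breaking: edges are examined
#' in increasing weight, ties resolved lexicographically by endpoint
#' indices; infinite-weight edges sort after every finite weight, so they
#' enter the tree only when no finite spanning tree exists (isolated groups
#' of stitchable tiles still get connected, through the stage-coordinate
#' default).
#'
#' @param graph A [build_graph()] result.
#' @return The `edges` data frame restricted to the
#'   `n_rows * n_cols - 1` tree edges.
#' @export
minimum_spanning_tree <- function(graph) {
  e <- graph$edges
  n_cols <- graph$n_cols
  n <- graph$n_rows * n_cols
  ord <- order(e$weight, e$a_row, e$a_col, e$b_row, e$b_col)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  id <- function(r, c) r * n_cols + c + 1L
  keep <- logical(nrow(e))
  taken <- 0L
  for (i in ord) {
    ra <- find(id(e$a_row[i], e$a_col[i]))
    rb <- find(id(e$b_row[i], e$b_col[i]))
    if (ra != rb) {
      parent[ra] <- rb
      keep[i] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  e[keep, , drop = FALSE]
}

#' Solve globally optimal tile placement
#'
#' For each direction independently: builds the inverse-reliability graph,
#' takes its minimum spanning tree, and traverses it from the anchor tile
#' (0,0) accumulating the nominal offset plus the computed offset of each
#' tree edge (sign flipped when an edge is traversed from the higher- to
#' the lower-index tile; infinite edges carry offset 0, i.e. the
#' stage-coordinate default). Finally all coordinates are translated so the
#' per-direction minimum is 0.
#'
#' @param state A `stitch_state` at stage `thresholded`.
#' @return A `stitch_state` at stage `placed`, with `placements`: a data
#'   frame of absolute per-tile (`v`, `h`, `d`) voxel coordinates.
#' @export
solve_placement <- function(state) {
  .require_stage(state, "thresholded", "place")
  vol <- state$volume
  n_rows <- vol$n_rows; n_cols <- vol$n_cols
  n <- n_rows * n_cols
  nominal <- list(
    V = vapply(vol$tiles, `[[`, numeric(1), "nominal_v"),
    H = vapply(vol$tiles, `[[`, numeric(1), "nominal_h"),
    D = vapply(vol$tiles, `[[`, numeric(1), "nominal_d"))
  coords <- list()
  for (dir in .AXES) {
    tree <- minimum_spanning_tree(build_graph(state, dir))
    stopifnot(nrow(tree) == n - 1L)
    # adjacency list over tree edges
    id <- function(r, c) r * n_cols + c + 1L
    adj <- vector("list", n)
    for (i in seq_len(nrow(tree))) {
      a <- id(tree$a_row[i], tree$a_col[i])
      b <- id(tree$b_row[i], tree$b_col[i])
      off <- if (is.infinite(tree$weight[i])) 0 else tree$offset[i]
      adj[[a]] <- c(adj[[a]], list(list(to = b, off = off, sign = 1)))
      adj[[b]] <- c(adj[[b]], list(list(to = a, off = off, sign = -1)))
    }
    pos <- rep(NA_real_, n)
    pos[1] <- nominal[[dir]][1] # anchor tile (0,0)
    queue <- 1L
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (e in adj[[u]]) {
        if (is.na(pos[e$to])) {
          pos[e$to] <- pos[u] +
            (nominal[[dir]][e$to] - nominal[[dir]][u]) + e$sign * e$off
          queue <- c(queue, e$to)
        }
      }
    }
    stopifnot(!anyNA(pos))
    coords[[dir]] <- as.integer(round(pos - min(pos)))
  }
  placements <- data.frame(
    row = vapply(vol$tiles, `[[`, integer(1), "row"),
    col = vapply(vol$tiles, `[[`, integer(1), "col"),
    v = coords$V, h = coords$H, d = coords$D)
  state$placements <- placements
  state$stage <- "placed"
  state
}
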