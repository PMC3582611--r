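# Projection of redundant per-substack displacements to one displacement
# per pair, reliability thresholding with fall-back to stage coordinates,
# and propagation of stitchable flags to tiles.

#' Thresholding configuration
#'
#' @param reliability_threshold Pairs whose aggregated reliability falls
#'   below this value revert to their nominal stage-coordinate displacement.
#'   Values in `[0.7, 0.8]` work well on typical data; lower values may be
#'   needed for low-contrast or very noisy acquisitions.
#' @param aggregate How the three per-direction reliabilities combine into
#'   the pair-level score that is thresholded: `"min"` (conservative
#'   default: one bad axis misplaces a tile) or `"mean"`.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(reliability_threshold = 0.7,
                             aggregate = c("min", "mean")) {
  stopifnot(reliability_threshold > 0, reliability_threshold < 1)
  structure(list(reliability_threshold = reliability_threshold,
                 aggregate = match.arg(aggregate)),
            class = "threshold_config")
}

#' Project per-substack displacements to one displacement per pair
#'
#' For each direction independently, keeps the offset and reliability of
#' the substack layer with the highest reliability in that direction (ties
#' go to the earliest layer), so the result may mix layers across
#' directions.
#'
#' @param layers Non-empty list of per-substack records, each with `offset`
#'   and `reliability` named per direction.
#' @return List with `offset` and `reliability`, named per direction.
#' @export
project_pair <- function(layers) {
  if (length(layers) == 0) stop_usage("cannot project an empty layer list")
  offset <- stats::setNames(numeric(3), .AXES)
  reliab <- stats::setNames(numeric(3), .AXES)
  for (d in .AXES) {
    rels <- vapply(layers, function(l) l$reliability[[d]], numeric(1))
    k <- which.max(rels) # first maximum: earliest layer on ties
    offset[d] <- layers[[k]]$offset[[d]]
    reliab[d] <- rels[k]
  }
  list(offset = offset, reliability = reliab)
}

#' Projection step
#'
#' Applies [project_pair()] to every pair of a `displacements_computed`
#' state.
#'
#' @param state A `stitch_state` at stage `displacements_computed`.
#' @return A `stitch_state` at stage `projected`.
#' @export
project_displacements <- function(state) {
  .require_stage(state, "displacements_computed", "project")
  for (i in seq_along(state$pairs)) {
    p <- state$pairs[[i]]
    pr <- project_pair(p$layers)
    p$offset <- pr$offset
    p$reliability <- pr$reliability
    p$layers <- list()
    p$default_flag <- FALSE
    p$stitchable <- TRUE
    state$pairs[[i]] <- p
  }
  state$stage <- "projected"
  state
}

#' Threshold one projected pair displacement
#'
#' The pair-level reliability is the aggregate (min by default) of the
#' three per-direction reliabilities. At or above the threshold the pair is
#' kept unchanged; below it the default displacement provided by the stage
#' coordinates is reestablished (offsets are corrections relative to
#' nominal, so they become 0), all reliabilities are set to 0, and the pair
#' is marked nonstitchable.
#'
#' @param pair A projected pair record (`offset`, `reliability`).
#' @param config A [threshold_config()].
#' @return The pair record, updated.
#' @export
threshold_pair <- function(pair, config = threshold_config()) {
  agg <- switch(config$aggregate,
                min = min(pair$reliability),
                mean = mean(pair$reliability))
  if (agg >= config$reliability_threshold) {
    pair$stitchable <- TRUE
    pair$default_flag <- FALSE
  } else {
    pair$offset <- stats::setNames(numeric(3), .AXES)
    pair$reliability <- stats::setNames(numeric(3), .AXES)
    pair$stitchable <- FALSE
    pair$default_flag <- TRUE
  }
  pair
}

#' Mark nonstitchable tiles
#'
#' A tile is nonstitchable iff every one of its incident pairs (up to four;
#' two or three on corners and borders) is nonstitchable: there is then no
#' way to stitch it to any neighbor except through its stage coordinates.
#'
#' @param state A `stitch_state` whose pairs carry `stitchable` flags.
#' @return The state with per-tile `stitchable` flags updated.
#' @export
mark_tiles <- function(state) {
  vol <- state$volume
  for (r in seq_len(vol$n_rows) - 1L) for (c in seq_len(vol$n_cols) - 1L) {
    incident <- Filter(function(p) {
      (p$a_row == r && p$a_col == c) || (p$b_row == r && p$b_col == c)
    }, state$pairs)
    ok <- any(vapply(incident, function(p) isTRUE(p$stitchable), logical(1)))
    state$volume$tiles[[r * vol$n_cols + c + 1L]]$stitchable <- ok
  }
  state
}

#' Thresholding step
#'
#' Applies [threshold_pair()] to every pair of a projected state and
#' propagates stitchability to tiles with [mark_tiles()]. Idempotent for a
#' fixed threshold; raising the threshold can only grow the nonstitchable
#' set.
#'
#' @param state A `stitch_state` at stage `projected` (or `thresholded`,
#'   for re-thresholding after hand edits).
#' @param config A [threshold_config()].
#' @return A `stitch_state` at stage `thresholded`.
#' @export
threshold_displacements <- function(state, config = threshold_config()) {
  if (!(state$stage %in% c("projected", "thresholded")))
    stop_stage("step 'threshold' requires stage 'projected', ",
               "but state is at stage '", state$stage, "'")
  state$pairs <- lapply(state$pairs, threshold_pair, config = config)
  state <- mark_tiles(state)
  state$stage <- "thresholded"
  state
}

#' Textual stitchability report
#'
#' A plain-text map of stitchable and nonstitchable tiles plus a table of
#' per-pair offsets and reliabilities, for eyeballing before editing the
#' XML by hand.
#'
#' @param state A thresholded `stitch_state`.
#' @param file Connection or path passed to [cat()]; default prints to
#'   stdout.
#' @return The report lines, invisibly.
#' @export
stitchability_report <- function(state, file = "") {
  vol <- state$volume
  lines <- c(sprintf("stitchability map (%d x %d tiles): S = stitchable, . = nonstitchable",
                     vol$n_rows, vol$n_cols))
  for (r in seq_len(vol$n_rows) - 1L) {
    row <- vapply(seq_len(vol$n_cols) - 1L, function(c) {
      if (isTRUE(vol_tile(vol, r, c)$stitchable)) "S" else "."
    }, character(1))
    lines <- c(lines, paste0("  ", paste(row, collapse = " ")))
  }
  lines <- c(lines, "", sprintf(
    "%-18s %-4s %-9s %9s %9s %9s %7s %7s %7s",
    "pair", "axis", "stitch", "off_V", "off_H", "off_D",
    "r_V", "r_H", "r_D"))
  for (p in state$pairs) {
    lines <- c(lines, sprintf(
      "(%d,%d)-(%d,%d) %8s %-9s %9g %9g %9g %7.3f %7.3f %7.3f",
      p$a_row, p$a_col, p$b_row, p$b_col, p$axis,
      if (isTRUE(p$stitchable)) "ok" else "DEFAULT",
      p$offset[["V"]], p$offset[["H"]], p$offset[["D"]],
      p$reliability[["V"]], p$reliability[["H"]], p$reliability[["D"]]))
  }
  cat(paste(lines, collapse = "\n"), "\n", file = file)
  invisible(lines)
}
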