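# Pipeline state checkpointing as editable XML.
#
# Every step reads and writes a StitchState so the pipeline can be stopped,
# its metadata hand-edited (offsets, reliabilities, stitchable flags), and
# resumed. Serialization is lossless and canonical: re-saving a loaded file
# reproduces it byte for byte.

.STAGES <- c("imported", "displacements_computed", "projected",
             "thresholded", "placed")

.new_state <- function(stage, volume, pairs = NULL, placements = NULL) {
  if (is.null(pairs))
    pairs <- lapply(.enumerate_pairs(volume$n_rows, volume$n_cols),
                    function(p) { p$layers <- list(); p })
  structure(list(stage = stage, volume = volume, pairs = pairs,
                 placements = placements), class = "stitch_state")
}

#' @export
print.stitch_state <- function(x, ...) {
  cat(sprintf("stitch_state [stage: %s] %d x %d tiles, %d adjacent pairs\n",
              x$stage, x$volume$n_rows, x$volume$n_cols, length(x$pairs)))
  invisible(x)
}

.check_reliability <- function(r, where) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("validation error at ", where,
         ": reliability must be in [0, 1], got ", paste(r, collapse = ", "))
  r
}

#' Save pipeline state to XML
#'
#' Writes the full pipeline state (volume descriptor, per-pair
#' displacements at whatever stage they are in, tile placements) to a
#' self-contained XML file designed to be hand-editable: offsets,
#' reliabilities and stitchable flags can be changed in a text editor and
#' the edited file re-validated on load.
#'
#' @param state A `stitch_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "stitch_state"))
  vol <- state$volume
  doc <- xml2::xml_new_root("stitch_state", stage = state$stage)
  vnode <- xml2::xml_add_child(
    doc, "volume",
    root = vol$root_path,
    rows = as.character(vol$n_rows), cols = as.character(vol$n_cols),
    tile_height_v = as.character(vol$tile_height_v),
    tile_width_h = as.character(vol$tile_width_h),
    n_slices = as.character(vol$n_slices_total),
    bits = as.character(vol$bits),
    voxel_size = paste(fmt_num(vol$voxel_size), collapse = " "))
  for (t in vol$tiles) {
    tn <- xml2::xml_add_child(
      vnode, "tile",
      row = as.character(t$row), col = as.character(t$col),
      nominal_v = as.character(t$nominal_v),
      nominal_h = as.character(t$nominal_h),
      nominal_d = as.character(t$nominal_d),
      stitchable = tolower(as.character(t$stitchable)))
    xml2::xml_add_child(tn, "slices",
                        paste(t$slice_paths, collapse = ";"))
  }
  pnode <- xml2::xml_add_child(doc, "pairs")
  for (p in state$pairs) {
    pn <- xml2::xml_add_child(
      pnode, "pair",
      a_row = as.character(p$a_row), a_col = as.character(p$a_col),
      b_row = as.character(p$b_row), b_col = as.character(p$b_col),
      axis = p$axis)
    if (!is.null(p$stitchable))
      xml2::xml_set_attr(pn, "stitchable", tolower(as.character(p$stitchable)))
    if (!is.null(p$default_flag))
      xml2::xml_set_attr(pn, "default", tolower(as.character(p$default_flag)))
    add_disp <- function(parent, offset, reliability) {
      for (d in .AXES)
        xml2::xml_add_child(parent, "displacement", dir = d,
                            offset = fmt_num(offset[[d]]),
                            reliability = fmt_num(reliability[[d]]))
    }
    if (length(p$layers)) {
      for (l in p$layers) {
        ln <- xml2::xml_add_child(pn, "layer", z0 = as.character(l$z0),
                                  z1 = as.character(l$z1))
        add_disp(ln, l$offset, l$reliability)
      }
    } else if (!is.null(p$offset)) {
      add_disp(pn, p$offset, p$reliability)
    }
  }
  if (!is.null(state$placements)) {
    gnode <- xml2::xml_add_child(doc, "placements")
    for (i in seq_len(nrow(state$placements))) {
      pl <- state$placements[i, ]
      xml2::xml_add_child(gnode, "placement",
                          row = as.character(pl$row),
                          col = as.character(pl$col),
                          v = as.character(pl$v), h = as.character(pl$h),
                          d = as.character(pl$d))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.attr_num <- function(node, name, path) {
  a <- xml2::xml_attr(node, name)
  if (is.na(a)) stop("schema violation at ", path,
                     ": missing attribute '", name, "'")
  x <- suppressWarnings(as.numeric(a))
  if (is.na(x)) stop("schema violation at ", path,
                     ": attribute '", name, "' is not numeric: ", a)
  x
}

.attr_flag <- function(node, name) {
  a <- xml2::xml_attr(node, name)
  if (is.na(a)) return(NULL)
  identical(tolower(a), "true")
}

#' Load pipeline state from XML
#'
#' Parses and validates a state file written by [save_state()] (possibly
#' hand-edited since). Reliabilities must lie in `[0, 1]`; the pair set must
#' cover exactly the grid adjacencies; violations raise an error naming the
#' offending element.
#'
#' @param path XML file path.
#' @return A `stitch_state`.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop_io("state file not found: ", path)
  doc <- xml2::read_xml(path)
  stage <- xml2::xml_attr(doc, "stage")
  if (is.na(stage) || !(stage %in% .STAGES))
    stop("schema violation at /stitch_state: bad or missing stage '",
         stage, "'")

  vnode <- xml2::xml_find_first(doc, "./volume")
  if (inherits(vnode, "xml_missing"))
    stop("schema violation: missing /stitch_state/volume")
  n_rows <- as.integer(.attr_num(vnode, "rows", "/volume"))
  n_cols <- as.integer(.attr_num(vnode, "cols", "/volume"))
  tiles <- vector("list", n_rows * n_cols)
  for (tn in xml2::xml_find_all(vnode, "./tile")) {
    r <- as.integer(.attr_num(tn, "row", "/volume/tile"))
    c <- as.integer(.attr_num(tn, "col", "/volume/tile"))
    slices <- xml2::xml_text(xml2::xml_find_first(tn, "./slices"))
    tiles[[r * n_cols + c + 1L]] <- list(
      row = r, col = c,
      nominal_v = as.integer(.attr_num(tn, "nominal_v", "/volume/tile")),
      nominal_h = as.integer(.attr_num(tn, "nominal_h", "/volume/tile")),
      nominal_d = as.integer(.attr_num(tn, "nominal_d", "/volume/tile")),
      slice_paths = strsplit(slices, ";", fixed = TRUE)[[1]],
      stitchable = isTRUE(.attr_flag(tn, "stitchable"))
    )
  }
  if (any(vapply(tiles, is.null, logical(1))))
    stop("schema violation at /volume: incomplete tile set")
  volume <- structure(list(
    n_rows = n_rows, n_cols = n_cols,
    tile_height_v = as.integer(.attr_num(vnode, "tile_height_v", "/volume")),
    tile_width_h = as.integer(.attr_num(vnode, "tile_width_h", "/volume")),
    n_slices_total = as.integer(.attr_num(vnode, "n_slices", "/volume")),
    voxel_size = as.numeric(strsplit(
      xml2::xml_attr(vnode, "voxel_size"), " ", fixed = TRUE)[[1]]),
    bits = as.integer(.attr_num(vnode, "bits", "/volume")),
    root_path = xml2::xml_attr(vnode, "root"),
    tiles = tiles
  ), class = "tiled_volume")

  expected <- .enumerate_pairs(n_rows, n_cols)
  pair_nodes <- xml2::xml_find_all(doc, "./pairs/pair")
  if (length(pair_nodes) != length(expected))
    stop("schema violation at /pairs: expected ", length(expected),
         " pairs, found ", length(pair_nodes))
  read_disp <- function(node, where) {
    dn <- xml2::xml_find_all(node, "./displacement")
    if (length(dn) != 3)
      stop("schema violation at ", where, ": expected 3 displacements")
    offset <- stats::setNames(numeric(3), .AXES)
    reliability <- stats::setNames(numeric(3), .AXES)
    for (d in dn) {
      dir <- xml2::xml_attr(d, "dir")
      if (!(dir %in% .AXES))
        stop("schema violation at ", where, ": bad dir '", dir, "'")
      offset[dir] <- .attr_num(d, "offset", where)
      reliability[dir] <- .check_reliability(
        .attr_num(d, "reliability", where), where)
    }
    list(offset = offset, reliability = reliability)
  }
  pairs <- vector("list", length(pair_nodes))
  for (i in seq_along(pair_nodes)) {
    pn <- pair_nodes[[i]]
    where <- paste0("/pairs/pair[", i, "]")
    p <- list(a_row = as.integer(.attr_num(pn, "a_row", where)),
              a_col = as.integer(.attr_num(pn, "a_col", where)),
              b_row = as.integer(.attr_num(pn, "b_row", where)),
              b_col = as.integer(.attr_num(pn, "b_col", where)),
              axis = xml2::xml_attr(pn, "axis"))
    if (!(p$axis %in% c("H", "V")))
      stop("schema violation at ", where, ": bad axis '", p$axis, "'")
    e <- expected[[i]]
    if (!identical(unlist(e[c("a_row", "a_col", "b_row", "b_col")],
                          use.names = FALSE),
                   c(p$a_row, p$a_col, p$b_row, p$b_col)))
      stop("schema violation at ", where,
           ": pair set does not match grid adjacencies")
    p$stitchable <- .attr_flag(pn, "stitchable")
    p$default_flag <- .attr_flag(pn, "default")
    lnodes <- xml2::xml_find_all(pn, "./layer")
    if (length(lnodes)) {
      p$layers <- lapply(seq_along(lnodes), function(k) {
        ln <- lnodes[[k]]
        lw <- paste0(where, "/layer[", k, "]")
        c(list(z0 = as.integer(.attr_num(ln, "z0", lw)),
               z1 = as.integer(.attr_num(ln, "z1", lw))),
          read_disp(ln, lw))
      })
    } else {
      p$layers <- list()
      dn <- xml2::xml_find_all(pn, "./displacement")
      if (length(dn)) {
        d <- read_disp(pn, where)
        p$offset <- d$offset
        p$reliability <- d$reliability
      }
    }
    pairs[[i]] <- p
  }

  placements <- NULL
  gnodes <- xml2::xml_find_all(doc, "./placements/placement")
  if (length(gnodes)) {
    placements <- do.call(rbind, lapply(gnodes, function(g) {
      data.frame(row = as.integer(.attr_num(g, "row", "/placements")),
                 col = as.integer(.attr_num(g, "col", "/placements")),
                 v = as.integer(.attr_num(g, "v", "/placements")),
                 h = as.integer(.attr_num(g, "h", "/placements")),
                 d = as.integer(.attr_num(g, "d", "/placements")))
    }))
  }
  .new_state(stage, volume, pairs, placements)
}

# Stage-machine guard used by every step.
.require_stage <- function(state, expected, step) {
  if (!identical(state$stage, expected))
    stop_stage("step '", step, "' requires stage '", expected,
               "', but state is at stage '", state$stage, "'")
  invisible(state)
}

# Nominal stage-coordinate displacement of pair b relative to a, per axis.
.nominal_displacement <- function(volume, p) {
  a <- vol_tile(volume, p$a_row, p$a_col)
  b <- vol_tile(volume, p$b_row, p$b_col)
  stats::setNames(c(b$nominal_v - a$nominal_v,
                    b$nominal_h - a$nominal_h,
                    b$nominal_d - a$nominal_d), .AXES)
}
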