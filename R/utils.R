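# Internal helpers shared across the pipeline.

# Axis order used everywhere: V (rows, slow image axis), H (columns), D
# (slice index). All voxel coordinates are 0-based, intervals half-open.
.AXES <- c("V", "H", "D")

the <- new.env(parent = emptyenv())

.reset_counters <- function() {
  the$slice_reads <- character(0)
  the$resident_substacks <- 0L
  the$peak_resident_substacks <- 0L
  the$peak_fused_slices <- 0L
}
.reset_counters()

.count_read <- function(path) {
  the$slice_reads <- c(the$slice_reads, path)
  invisible(NULL)
}

.substack_loaded <- function() {
  the$resident_substacks <- the$resident_substacks + 1L
  the$peak_resident_substacks <-
    max(the$peak_resident_substacks, the$resident_substacks)
  invisible(NULL)
}

.substack_released <- function(n = 1L) {
  the$resident_substacks <- the$resident_substacks - as.integer(n)
  invisible(NULL)
}

#' Instrumentation counters for I/O and memory contracts
#'
#' The alignment and merge steps are written to touch each slice file once
#' per step and to keep a bounded number of substacks / fused slices in
#' memory. These hooks expose the counters so the contracts can be asserted:
#' `reset_io_stats()` zeroes them, `io_stats()` returns the current values.
#'
#' @return `io_stats()` returns a list with elements `slice_reads` (number
#'   of slice-file reads since the last reset), `distinct_slice_reads`
#'   (distinct files read), `peak_resident_substacks` (maximum number of
#'   tile substacks simultaneously held during alignment) and
#'   `peak_fused_slices` (maximum number of fused output slices
#'   simultaneously held during merging).
#' @export
io_stats <- function() {
  list(
    slice_reads = length(the$slice_reads),
    distinct_slice_reads = length(unique(the$slice_reads)),
    peak_resident_substacks = the$peak_resident_substacks,
    peak_fused_slices = the$peak_fused_slices
  )
}

#' @rdname io_stats
#' @export
reset_io_stats <- function() {
  .reset_counters()
  invisible(NULL)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Number formatting that survives text round-trips: shortest of %.15g/%.17g
# that parses back to the same double, so re-serializing a parsed file is a
# byte-level no-op.
fmt_num <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return("NA")
    s <- sprintf("%.15g", xi)
    if (as.numeric(s) == xi) s else sprintf("%.17g", xi)
  }, character(1))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("stitch3d_usage_error", "error")))
}

stop_stage <- function(...) {
  stop(errorCondition(paste0(...), class = c("stitch3d_stage_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("stitch3d_io_error", "error")))
}
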