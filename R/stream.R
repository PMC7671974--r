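# Core containers: kinematic streams, column layouts, skill levels.

#' Manipulator identifiers
#'
#' The four manipulators of a teleoperated surgical robot: the two
#' surgeon-side hand controllers (masters) and the two patient-side
#' instrument arms (slaves).
#'
#' @return character vector of the four canonical manipulator ids.
#' @export
manipulator_ids <- function() {
  c("master_left", "master_right", "slave_left", "slave_right")
}

#' Skill levels in ascending order of experience
#'
#' Self-declared skill classes by hours of robotic operating experience:
#' novice (< 10 h), intermediate (10--100 h), expert (> 100 h).
#'
#' @return character vector `c("novice", "intermediate", "expert")`.
#' @export
skill_levels <- function() c("novice", "intermediate", "expert")

#' Construct a kinematic stream
#'
#' A `kinematic_stream` holds the per-frame Cartesian tool-tip positions of
#' one trial, one `n x 3` matrix (columns x, y, z, in meters) per
#' manipulator, sampled at a fixed rate.
#'
#' @param positions named list of numeric matrices with 3 columns; names are
#'   drawn from [manipulator_ids()]; all matrices must have the same number
#'   of rows (frames). Zero-row matrices give a valid empty stream.
#' @param sample_rate_hz positive sampling rate (default 30, the JIGSAWS
#'   recording rate).
#' @return an object of class `kinematic_stream`.
#' @export
kinematic_stream <- function(positions, sample_rate_hz = 30) {
  if (!is.list(positions) || is.null(names(positions)) ||
      any(!nzchar(names(positions))))
    stopf("positions must be a named list of n x 3 matrices")
  bad <- setdiff(names(positions), manipulator_ids())
  if (length(bad))
    stopf("unknown manipulator id(s): %s", paste(bad, collapse = ", "))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stopf("sample_rate_hz must be a single positive number")
  positions <- lapply(positions, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stopf("each position matrix must have 3 columns (x, y, z)")
    if (nrow(m) > 0 && (!is.numeric(m) || any(!is.finite(m))))
      stopf("positions must be finite numbers")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  n <- vapply(positions, nrow, integer(1))
  if (length(unique(n)) > 1)
    stopf("all manipulators must have the same number of frames")
  structure(
    list(positions = positions, sample_rate_hz = sample_rate_hz),
    class = "kinematic_stream"
  )
}

#' Number of frames in a kinematic stream
#' @param stream a [kinematic_stream()].
#' @return integer frame count.
#' @export
n_samples <- function(stream) {
  stopifnot(inherits(stream, "kinematic_stream"))
  if (!length(stream$positions)) return(0L)
  nrow(stream$positions[[1]])
}

#' @export
print.kinematic_stream <- function(x, ...) {
  cat(sprintf(
    "<kinematic_stream> %d frames @ %g Hz (%.2f s), manipulators: %s\n",
    n_samples(x), x$sample_rate_hz, n_samples(x) / x$sample_rate_hz,
    paste(names(x$positions), collapse = ", ")
  ))
  invisible(x)
}

#' JIGSAWS-style 76-column layout
#'
#' Describes how the 76 whitespace-separated values of one frame map onto
#' manipulators: four blocks of 19 channels each (3 position, 9 rotation
#' matrix, 3 linear velocity, 3 angular velocity, 1 gripper angle), the
#' Cartesian position occupying the first three columns of each block. The
#' block order is configurable because the recording documentation and some
#' secondary descriptions disagree on it.
#'
#' @param manipulator_order permutation of [manipulator_ids()] giving the
#'   block order. The default follows the dataset's own file documentation:
#'   left master, right master, left slave, right slave.
#' @return an object of class `jigsaws_layout`.
#' @export
jigsaws_layout <- function(manipulator_order = c(
                             "master_left", "master_right",
                             "slave_left", "slave_right")) {
  if (!setequal(manipulator_order, manipulator_ids()) ||
      length(manipulator_order) != 4)
    stopf("manipulator_order must be a permutation of the four manipulator ids")
  structure(
    list(
      manipulator_order = manipulator_order,
      block_size = 19L,
      position_cols = 1:3,
      n_columns = 76L
    ),
    class = "jigsaws_layout"
  )
}

# columns of the position triple of one manipulator under a layout
layout_position_cols <- function(layout, manipulator) {
  i <- match(manipulator, layout$manipulator_order)
  if (is.na(i)) stopf("manipulator '%s' not in layout", manipulator)
  (i - 1L) * layout$block_size + layout$position_cols
}
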