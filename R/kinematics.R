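# Kinematic skill metrics: time, path length, movement count.

#' Distances between consecutive 3-D points
#'
#' For points A and B the distance is
#' `sqrt((xB-xA)^2 + (yB-yA)^2 + (zB-zA)^2)`; applied along a trajectory of
#' n points it yields the n-1 partial distances whose sum is the path
#' length and which, at a fixed sample rate, form the displacement-per-
#' interval (speed) signal used for movement counting.
#'
#' @param positions numeric matrix with 3 columns (x, y, z), one row per
#'   sample; at least one row.
#' @return numeric vector of length `nrow(positions) - 1` (length 0 for a
#'   single point).
#' @export
interpoint_distances <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stopf("positions must have 3 columns (x, y, z)")
  if (nrow(positions) < 1) stopf("at least one point is required")
  assert_finite_numeric(c(positions), "coordinates")
  if (nrow(positions) == 1) return(numeric(0))
  d <- diff(positions)
  sqrt(rowSums(d * d))
}

#' Total path length of a trajectory
#'
#' `PL = sum_i d_i`: the sum of the Euclidean distances between neighboring
#' samples, in the units of the coordinates (meters throughout this
#' package). Computed on the raw, unsmoothed positions.
#'
#' @inheritParams interpoint_distances
#' @return non-negative scalar path length.
#' @export
path_length <- function(positions) {
  sum(interpoint_distances(positions))
}

#' Trial duration from the sample count
#'
#' Recordings run at a fixed rate, so trial time is the number of frames
#' divided by the rate (seconds).
#'
#' @param sample_count non-negative integer number of frames.
#' @param sample_rate_hz positive sampling rate (default 30 Hz).
#' @return time in seconds.
#' @export
trial_time <- function(sample_count, sample_rate_hz = 30) {
  if (!is.numeric(sample_count) || length(sample_count) != 1 ||
      !is.finite(sample_count) || sample_count < 0)
    stopf("sample_count must be a single non-negative number")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stopf("sample_rate_hz must be a single positive number")
  sample_count / sample_rate_hz
}

#' Gaussian smoothing of a 1-D signal
#'
#' Discrete convolution with a truncated, unit-sum Gaussian kernel
#' (truncation radius `ceiling(4 * sigma)` samples) under reflective
#' (symmetric) edge padding, so constants are preserved exactly and the
#' output has the same length as the input.
#'
#' @param signal numeric vector, length >= 1.
#' @param sigma_samples kernel standard deviation in samples, > 0.
#' @return smoothed numeric vector, same length as `signal`.
#' @export
smooth_gaussian <- function(signal, sigma_samples) {
  assert_finite_numeric(signal, "signal")
  if (!length(signal)) stopf("signal must have length >= 1")
  if (!is.numeric(sigma_samples) || length(sigma_samples) != 1 ||
      !is.finite(sigma_samples) || sigma_samples <= 0)
    stopf("sigma_samples must be a single positive number")
  n <- length(signal)
  r <- as.integer(ceiling(4 * sigma_samples))
  kernel <- stats::dnorm(-r:r, sd = sigma_samples)
  kernel <- kernel / sum(kernel)
  # symmetric reflection index (a b c | c b a | a b c ...), period 2n
  reflect <- function(i) {
    j <- (i - 1L) %% (2L * n)
    j <- ifelse(j < 0L, j + 2L * n, j)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  padded <- signal[reflect(seq.int(1L - r, n + r))]
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

#' Strict local maxima above a height threshold, with minimum separation
#'
#' Candidate peaks are interior samples strictly greater than both
#' neighbors and strictly exceeding `min_height`. Candidates closer than
#' `min_separation` samples are resolved in favor of the higher peak; on an
#' exact height tie the earlier peak is kept.
#'
#' @param signal numeric vector.
#' @param min_height height threshold (strict).
#' @param min_separation minimum index distance between retained peaks.
#' @return increasing integer vector of peak indices.
#' @export
find_peaks <- function(signal, min_height, min_separation = 1) {
  assert_finite_numeric(signal, "signal")
  n <- length(signal)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[signal[i] > signal[i - 1] & signal[i] > signal[i + 1] &
              signal[i] > min_height]
  if (!length(cand) || min_separation <= 1) return(cand)
  ord <- cand[order(-signal[cand], cand)]  # height desc, earlier first on tie
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_separation))
      kept <- c(kept, p)
  }
  sort(kept)
}

#' Segment a trajectory into movements by smoothed-speed peaks
#'
#' A movement is a displacement burst whose speed rises to a maximum and
#' returns near zero. The per-interval displacement signal `d_i` (speed
#' times the sample interval) is smoothed with a Gaussian filter and the
#' movements are counted as the local high peaks of the smoothed signal.
#'
#' @param positions numeric matrix with 3 columns, one row per sample.
#' @param sigma_samples Gaussian smoothing sigma in samples (default 5,
#'   about 0.17 s at 30 Hz).
#' @param min_peak_height absolute height threshold in meters per interval;
#'   `NULL` (default) uses the adaptive rule: 10% of the smoothed signal's
#'   maximum for the trial.
#' @param min_peak_separation minimum distance between peaks in samples
#'   (default `2 * sigma_samples`).
#' @return an object of class `movement_segmentation`: list with `signal`
#'   (raw d_i), `smoothed`, `peaks` (indices into the interval signal),
#'   `count`, and the parameters used.
#' @export
count_movements <- function(positions, sigma_samples = 5,
                            min_peak_height = NULL,
                            min_peak_separation = 2 * sigma_samples) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) {
    message("fewer than 2 samples: returning 0 movements")
    return(structure(
      list(signal = numeric(0), smoothed = numeric(0), peaks = integer(0),
           count = 0L, sigma_samples = sigma_samples,
           min_peak_height = min_peak_height %||% NA_real_,
           min_peak_separation = min_peak_separation),
      class = "movement_segmentation"))
  }
  d <- interpoint_distances(positions)
  s <- smooth_gaussian(d, sigma_samples)
  thr <- min_peak_height %||% (0.1 * max(s))
  peaks <- find_peaks(s, thr, min_peak_separation)
  structure(
    list(signal = d, smoothed = s, peaks = peaks, count = length(peaks),
         sigma_samples = sigma_samples, min_peak_height = thr,
         min_peak_separation = min_peak_separation),
    class = "movement_segmentation")
}

#' @export
print.movement_segmentation <- function(x, ...) {
  cat(sprintf(
    "<movement_segmentation> %d movements (sigma = %g samples, height > %.3g, separation >= %g)\n",
    x$count, x$sigma_samples, x$min_peak_height, x$min_peak_separation))
  invisible(x)
}

#' Compute the three skill metrics for a trial
#'
#' Per requested manipulator: task time (frames / rate; identical across
#' manipulators), path length on the raw positions, and the movement count
#' from the Gaussian-smoothed displacement signal. The default manipulator
#' set is the two master (hand-controller) arms, on which the classical
#' path-length metric is defined; the slaves are available on request.
#'
#' @param stream a [kinematic_stream()].
#' @param manipulators manipulator ids to analyze (default the two masters).
#' @param sigma_samples,min_peak_height,min_peak_separation movement-
#'   counting parameters, see [count_movements()].
#' @return data frame of class `motion_metrics`, one row per manipulator,
#'   columns `manipulator`, `time_s`, `path_length_m`, `movements`.
#' @export
compute_metrics <- function(stream,
                            manipulators = c("master_left", "master_right"),
                            sigma_samples = 5, min_peak_height = NULL,
                            min_peak_separation = 2 * sigma_samples) {
  stopifnot(inherits(stream, "kinematic_stream"))
  missing <- setdiff(manipulators, names(stream$positions))
  if (length(missing))
    stopf("manipulator(s) not in stream: %s (available: %s)",
          paste(missing, collapse = ", "),
          paste(names(stream$positions), collapse = ", "))
  t_s <- trial_time(n_samples(stream), stream$sample_rate_hz)
  rows <- lapply(manipulators, function(m) {
    p <- stream$positions[[m]]
    pl <- if (nrow(p) >= 1) path_length(p) else 0
    seg <- if (nrow(p) >= 2)
      count_movements(p, sigma_samples, min_peak_height, min_peak_separation)
    else NULL
    data.frame(manipulator = m, time_s = t_s, path_length_m = pl,
               movements = if (is.null(seg)) 0L else seg$count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motion_metrics", class(out))
  out
}

#' Export a manipulator's trajectory for plotting
#'
#' Returns the raw position sequence with time stamps, suitable for 3-D
#' trajectory plots or CSV export. The coordinate origin is the instrument
#' position convention of the recording (first-sample/startup pose).
#'
#' @param stream a [kinematic_stream()].
#' @param manipulator one manipulator id present in the stream.
#' @return data frame with columns `t`, `x`, `y`, `z`.
#' @export
trajectory_export <- function(stream, manipulator) {
  stopifnot(inherits(stream, "kinematic_stream"))
  if (!manipulator %in% names(stream$positions))
    stopf("manipulator '%s' not in stream (available: %s)", manipulator,
          paste(names(stream$positions), collapse = ", "))
  p <- stream$positions[[manipulator]]
  n <- nrow(p)
  data.frame(t = (seq_len(n) - 1) / stream$sample_rate_hz,
             x = p[, 1], y = p[, 2], z = p[, 3])
}
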