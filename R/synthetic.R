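# Synthetic trial and cohort generation with known ground truth.

#' Minimum-jerk displacement profile
#'
#' The canonical smooth point-to-point reaching profile
#' `x(t) = A * (10 tau^3 - 15 tau^4 + 6 tau^5)`, `tau = t/T`: displacement
#' rises monotonically from 0 to the amplitude `A` while the speed is
#' bell-shaped, zero at both ends with a single interior maximum of
#' `1.875 * A / T` at `tau = 1/2` -- exactly the verbal definition of a
#' single surgical movement used by the movement counter.
#'
#' @param amplitude total displacement A >= 0 (meters).
#' @param duration movement duration T > 0 (seconds).
#' @param t time points in `[0, T]` (values outside are clamped).
#' @return displacement at each `t`.
#' @export
minimum_jerk_displacement <- function(amplitude, duration, t) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stopf("amplitude must be a single non-negative number")
  if (!is.numeric(duration) || length(duration) != 1 ||
      !is.finite(duration) || duration <= 0)
    stopf("duration must be a single positive number")
  tau <- pmin(pmax(t / duration, 0), 1)
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Specify a synthetic trial
#'
#' A trial is a sequence of `n_movements` discrete point-to-point movements
#' with minimum-jerk (bell-shaped-velocity) profiles, each along its own
#' direction drawn uniformly on the sphere, separated by stationary pauses,
#' sampled at `sample_rate_hz`, with i.i.d. Gaussian position noise added
#' per axis per sample. `pauses` has `n_movements + 1` entries: a lead-in
#' pause, the inter-movement pauses and a tail pause.
#'
#' @param n_movements number of movements K >= 0.
#' @param amplitudes per-movement amplitudes in meters (recycled to K).
#' @param durations per-movement durations in seconds (> 0, recycled to K).
#' @param pauses pause durations in seconds (> 0, recycled to K + 1).
#' @param noise_sd position noise standard deviation in meters (>= 0).
#' @param sample_rate_hz sampling rate (default 30).
#' @param manipulators manipulators to synthesize (default both masters;
#'   each gets independent directions and noise from the same movement
#'   schedule).
#' @param seed integer seed for directions and noise, or `NULL` to use the
#'   current RNG stream.
#' @return an object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(n_movements, amplitudes = 0.08,
                                 durations = 0.6, pauses = 0.75,
                                 noise_sd = 0, sample_rate_hz = 30,
                                 manipulators = c("master_left",
                                                  "master_right"),
                                 seed = NULL) {
  if (!is.numeric(n_movements) || length(n_movements) != 1 ||
      n_movements < 0 || n_movements != round(n_movements))
    stopf("n_movements must be a single non-negative integer")
  k <- as.integer(n_movements)
  amplitudes <- rep_len(as.numeric(amplitudes), max(k, 1))[seq_len(k)]
  durations <- rep_len(as.numeric(durations), max(k, 1))[seq_len(k)]
  pauses <- rep_len(as.numeric(pauses), k + 1L)
  if (k > 0 && (any(amplitudes < 0) || any(durations <= 0)))
    stopf("amplitudes must be >= 0 and durations > 0")
  if (any(pauses <= 0)) stopf("pauses must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (sample_rate_hz <= 0) stopf("sample_rate_hz must be > 0")
  structure(
    list(n_movements = k, amplitudes = amplitudes, durations = durations,
         pauses = pauses, noise_sd = noise_sd,
         sample_rate_hz = sample_rate_hz, manipulators = manipulators,
         seed = seed),
    class = "synthetic_trial_spec")
}

#' Draw a random trial specification from the recovery-suite world
#'
#' The distributions the package's recovery tests sample from: amplitudes
#' uniform on 0.04--0.12 m, durations 0.4--0.8 s, pauses 0.5--1.0 s and
#' position noise sd uniform on 0 to 5e-5 m (sub-0.1 mm, the scale of
#' encoder-derived teleoperation kinematics; see the methods vignette for
#' why rectified distance noise forbids much larger values under the
#' adaptive peak threshold).
#'
#' @param n_movements movement count (default: uniform on 1..20).
#' @param seed integer seed, or `NULL`.
#' @return a [synthetic_trial_spec()].
#' @export
sample_trial_spec <- function(n_movements = NULL, seed = NULL) {
  with_seed(seed, {
    k <- n_movements %||% sample.int(20L, 1)
    synthetic_trial_spec(
      n_movements = k,
      amplitudes = stats::runif(k, 0.04, 0.12),
      durations = stats::runif(k, 0.4, 0.8),
      pauses = stats::runif(k + 1, 0.5, 1.0),
      noise_sd = stats::runif(1, 0, 5e-5),
      seed = if (is.null(seed)) NULL else seed + 1L)
  })
}

# unit vector uniform on the sphere
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v * v))
    if (n > 1e-12) return(v / n)
  }
}

#' Generate a synthetic trial with ground truth
#'
#' Deterministic given `spec$seed`: the same spec and seed reproduce the
#' stream bit for bit.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return list with `stream` (a [kinematic_stream()]) and `truth`: a list
#'   holding `n_movements`, `path_length_m` (noiseless, per manipulator:
#'   the sum of amplitudes), `time_s` (`samples / rate`), `n_samples` and
#'   `peak_times` (movement midpoints, seconds).
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  k <- spec$n_movements
  rate <- spec$sample_rate_hz
  starts <- numeric(k)
  t0 <- spec$pauses[1]
  for (j in seq_len(k)) {
    starts[j] <- t0
    t0 <- t0 + spec$durations[j] + spec$pauses[j + 1]
  }
  total <- t0
  n <- as.integer(round(total * rate)) + 1L
  t <- (seq_len(n) - 1) / rate
  build_hand <- function() {
    p <- matrix(0, nrow = n, ncol = 3)
    for (j in seq_len(k)) {
      u <- runit3()
      disp <- minimum_jerk_displacement(
        spec$amplitudes[j], spec$durations[j],
        pmin(pmax(t - starts[j], 0), spec$durations[j]))
      p <- p + outer(disp, u)
    }
    if (spec$noise_sd > 0)
      p <- p + matrix(stats::rnorm(3 * n, sd = spec$noise_sd), ncol = 3)
    p
  }
  pos <- with_seed(spec$seed, {
    out <- lapply(spec$manipulators, function(m) build_hand())
    names(out) <- spec$manipulators
    out
  })
  stream <- kinematic_stream(pos, rate)
  truth <- list(
    n_movements = k,
    path_length_m = sum(spec$amplitudes),
    time_s = n / rate,
    n_samples = n,
    peak_times = starts + spec$durations / 2,
    spec = spec)
  list(stream = stream, truth = truth)
}

default_skill_params <- function() {
  # calibrated to the direction and left-hand scale of published group
  # tables: novices are slow with many movements and long paths, experts
  # few focused movements; GRS means/sds follow the suturing pattern
  # (intermediates scored highest there).
  list(
    novice = list(n_movements = c(40, 10), amplitude = c(0.075, 0.015),
                  duration = c(1.0, 0.15), pause = c(2.4, 0.6),
                  noise_sd = 5e-5, grs = c(17.5, 4.4)),
    intermediate = list(n_movements = c(60, 8), amplitude = c(0.05, 0.01),
                        duration = c(0.6, 0.1), pause = c(0.85, 0.2),
                        noise_sd = 5e-5, grs = c(25.1, 4.1)),
    expert = list(n_movements = c(15, 5), amplitude = c(0.115, 0.02),
                  duration = c(1.2, 0.2), pause = c(5.5, 1.0),
                  noise_sd = 5e-5, grs = c(16.3, 3.7))
  )
}

#' Specify a synthetic cohort
#'
#' Describes a JIGSAWS-like cohort: participants per skill level, trials
#' per participant and exercise, and per-skill sampling distributions
#' (mean, sd pairs) for movement count, amplitude, duration, pause and the
#' trial GRS total (drawn from a rounded normal truncated to 6..30). The
#' defaults emulate the published cohort: 4 novices (B, G, H, I), 2
#' intermediates (C, F), 2 experts (D, E), up to 5 repetitions, three
#' exercises, with group-level time/path-length/movement ordering of the
#' published motion-analysis tables (novice > expert).
#'
#' @param exercises exercises to simulate.
#' @param participants named list of participant letters per skill level.
#' @param trials_per_participant repetitions per participant (max 5).
#' @param skill_params named list (novice/intermediate/expert) of lists
#'   with `n_movements`, `amplitude`, `duration`, `pause` (each `c(mean,
#'   sd)`), `noise_sd` and `grs` (`c(mean, sd)`).
#' @param sample_rate_hz sampling rate.
#' @param slave_scale master-to-slave mirror scale used when writing
#'   76-column files.
#' @param seed integer seed making the cohort fully reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(exercises = EXERCISES,
                        participants = list(
                          novice = c("B", "G", "H", "I"),
                          intermediate = c("C", "F"),
                          expert = c("D", "E")),
                        trials_per_participant = 5,
                        skill_params = default_skill_params(),
                        sample_rate_hz = 30, slave_scale = 1, seed = 1) {
  exercises <- exercise_from_token(exercises)
  if (!setequal(names(participants), skill_levels()))
    stopf("participants must be a named list over %s",
          paste(skill_levels(), collapse = ", "))
  if (trials_per_participant < 1 || trials_per_participant > 5)
    stopf("trials_per_participant must be in 1..5")
  for (sk in skill_levels()) {
    p <- skill_params[[sk]]
    if (is.null(p) || !all(c("n_movements", "amplitude", "duration",
                             "pause", "noise_sd", "grs") %in% names(p)))
      stopf("skill_params$%s is incomplete", sk)
  }
  structure(
    list(exercises = exercises, participants = participants,
         trials_per_participant = as.integer(trials_per_participant),
         skill_params = skill_params, sample_rate_hz = sample_rate_hz,
         slave_scale = slave_scale, seed = seed),
    class = "cohort_spec")
}

# positive truncated normal draw (mean, sd), floored at `lo`
rtrunc <- function(n, ms, lo) pmax(lo, stats::rnorm(n, ms[1], ms[2]))

#' Generate a synthetic cohort on disk
#'
#' Writes a directory tree in the same dialect the readers consume --
#' `<Exercise>/kinematics/<Exercise>_<P>00<r>.txt` 76-column files plus
#' `<Exercise>/meta_file_<Exercise>.txt` metadata -- so the full analysis
#' pipeline runs on the output unchanged. Deterministic given the spec
#' seed.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `records` (the trial metadata as a
#'   data frame) and `truth` (per trial x manipulator ground-truth data
#'   frame: movement count, noiseless path length, time).
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  skill_letter <- c(novice = "N", intermediate = "I", expert = "E")
  records <- list(); truth <- list()
  with_seed(spec$seed, {
    for (ex in spec$exercises) {
      token <- exercise_file_token(ex)
      kdir <- file.path(dir, token, "kinematics")
      dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
      meta_lines <- character(0)
      for (sk in skill_levels()) {
        pars <- spec$skill_params[[sk]]
        for (pp in spec$participants[[sk]]) {
          for (rep_i in seq_len(spec$trials_per_participant)) {
            # each hand gets its own independently drawn movement schedule;
            # the shorter hand rests (holds its final pose) until the trial
            # ends so both share one frame count
            hands <- lapply(c("master_left", "master_right"), function(h) {
              k <- max(1L, as.integer(round(stats::rnorm(
                1, pars$n_movements[1], pars$n_movements[2]))))
              tspec <- synthetic_trial_spec(
                n_movements = k,
                amplitudes = rtrunc(k, pars$amplitude, 0.01),
                durations = rtrunc(k, pars$duration, 0.2),
                pauses = rtrunc(k + 1, pars$pause, 0.5),
                noise_sd = pars$noise_sd,
                sample_rate_hz = spec$sample_rate_hz,
                manipulators = h, seed = NULL)
              generate_trial(tspec)
            })
            names(hands) <- c("master_left", "master_right")
            n <- max(vapply(hands, function(h) h$truth$n_samples,
                            integer(1)))
            pos <- lapply(hands, function(h) {
              p <- h$stream$positions[[1]]
              if (nrow(p) < n)
                p <- rbind(p, matrix(rep(p[nrow(p), ], n - nrow(p)),
                                     ncol = 3, byrow = TRUE))
              p
            })
            trial_stream <- kinematic_stream(pos, spec$sample_rate_hz)
            fname <- sprintf("%s_%s00%d.txt", token, pp, rep_i)
            write_jigsaws(trial_stream, file.path(kdir, fname),
                          slave_scale = spec$slave_scale)
            grs_total <- min(30L, max(6L, as.integer(round(
              stats::rnorm(1, pars$grs[1], pars$grs[2])))))
            items <- grs_items_from_total(grs_total)
            meta_lines <- c(meta_lines, sprintf(
              "%s_%s00%d\t%s\t%d\t%s", token, pp, rep_i, skill_letter[[sk]],
              grs_total, paste(items, collapse = " ")))
            records[[length(records) + 1L]] <- data.frame(
              exercise = ex, participant = pp, repetition = rep_i,
              skill_level = sk, grs_total = grs_total,
              stringsAsFactors = FALSE)
            for (h in names(hands))
              truth[[length(truth) + 1L]] <- data.frame(
                exercise = ex, participant = pp, repetition = rep_i,
                skill_level = sk, manipulator = h,
                n_movements = hands[[h]]$truth$n_movements,
                path_length_m = hands[[h]]$truth$path_length_m,
                time_s = n / spec$sample_rate_hz,
                stringsAsFactors = FALSE)
          }
        }
      }
      writeLines(meta_lines, file.path(dir, token,
                                       sprintf("meta_file_%s.txt", token)))
    }
  })
  invisible(list(dir = dir, records = do.call(rbind, records),
                 truth = do.call(rbind, truth)))
}

#' Read a cohort specification from a JSON config file
#'
#' The JSON object may set any argument of [cohort_spec()]; `skill_params`
#' entries are merged over the defaults.
#'
#' @param path path to the JSON file.
#' @return a [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stopf("cohort spec not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("exercises", "trials_per_participant", "sample_rate_hz",
               "slave_scale", "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$participants))
    args$participants <- lapply(cfg$participants, as.character)
  if (!is.null(cfg$skill_params)) {
    sp <- default_skill_params()
    for (sk in names(cfg$skill_params))
      for (f in names(cfg$skill_params[[sk]]))
        sp[[sk]][[f]] <- as.numeric(cfg$skill_params[[sk]][[f]])
    args$skill_params <- sp
  }
  do.call(cohort_spec, args)
}
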