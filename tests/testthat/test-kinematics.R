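# Geometry, smoothing and movement counting.

test_that("interpoint distances follow the Euclidean formula", {
  expect_equal(interpoint_distances(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(interpoint_distances(rbind(c(1, 1, 1), c(1, 1, 1))), 0)
  expect_equal(interpoint_distances(rbind(c(0, 0, 0), c(1, 1, 1))), sqrt(3))
  expect_length(interpoint_distances(matrix(1:3, 1)), 0)
  expect_error(interpoint_distances(rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
})

test_that("path length sums partial distances and handles degenerate input", {
  square_walk <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(path_length(square_walk), 3)
  expect_equal(path_length(matrix(c(2, 5, 7), 1)), 0)
  expect_equal(path_length(matrix(1, 10, 3)), 0)

  # monotone minimum-jerk movement: PL equals the net displacement
  t <- seq(0, 1, length.out = 1000)
  disp <- minimum_jerk_displacement(0.2, 1, t)
  u <- c(1, 2, 2) / 3
  p <- outer(disp, u)
  expect_equal(path_length(p), 0.2, tolerance = 1e-9)
  expect_equal(path_length(p), pl_oracle(p), tolerance = 1e-12)
})

test_that("path length is rigid-invariant, scales linearly and obeys the triangle bound", {
  set.seed(11)
  for (i in 1:20) {
    p <- matrix(rnorm(3 * sample(2:200, 1)), ncol = 3)
    pl <- path_length(p)
    R <- rand_rotation()
    shift <- rnorm(3)
    moved <- sweep(p %*% t(R), 2, shift, "+")
    expect_equal(path_length(moved), pl, tolerance = 1e-9)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(path_length(p * c_scale), c_scale * pl, tolerance = 1e-12)
    expect_gte(pl + 1e-12, sqrt(sum((p[nrow(p), ] - p[1, ])^2)))
    # additive over concatenation at a shared endpoint
    k <- sample(2:(nrow(p)), 1)
    expect_equal(path_length(p[1:k, , drop = FALSE]) +
                   path_length(p[k:nrow(p), , drop = FALSE]),
                 pl, tolerance = 1e-12)
  }
})

test_that("trial time is samples over rate and additive", {
  expect_equal(trial_time(300, 30), 10)
  expect_equal(trial_time(0), 0)
  expect_equal(trial_time(4110, 30), 137)
  expect_error(trial_time(-1), "non-negative")
  expect_error(trial_time(10, 0), "positive")
  set.seed(2)
  n1 <- sample(1e4, 20); n2 <- sample(1e4, 20)
  expect_equal(trial_time(n1[1] + n2[1]) ,
               trial_time(n1[1]) + trial_time(n2[1]))
  for (i in 1:20)
    expect_equal(trial_time(n1[i] + n2[i]),
                 trial_time(n1[i]) + trial_time(n2[i]))
})

test_that("gaussian smoothing preserves constants, mass and linear interiors", {
  expect_equal(smooth_gaussian(rep(3.7, 50), 2), rep(3.7, 50))
  imp <- c(rep(0, 30), 1, rep(0, 30))
  expect_equal(sum(smooth_gaussian(imp, 2)), 1, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 100)
  sm <- smooth_gaussian(ramp, 3)
  interior <- 20:80  # beyond the kernel radius from either edge
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-9)
  expect_error(smooth_gaussian(1:10, 0), "positive")

  set.seed(8)
  for (sigma in c(0.7, 2, 5)) {
    x <- rnorm(40)
    expect_equal(smooth_gaussian(x, sigma), conv_oracle(x, sigma),
                 tolerance = 1e-12)
  }
})

test_that("find_peaks equals the naive scan without separation and prunes with it", {
  set.seed(9)
  for (i in 1:50) {
    s <- abs(rnorm(sample(10:500, 1)))
    thr <- quantile(s, runif(1))
    expect_equal(find_peaks(s, thr, 1), naive_peaks(s, thr))
  }
  # of two close peaks the higher is kept; equal heights keep the earlier
  s <- c(0, 5, 0, 7, 0, 0, 0, 0, 0, 0, 0, 4, 0)
  expect_equal(find_peaks(s, 0.5, 4), c(4L, 12L))
  s_tie <- c(0, 5, 0, 5, 0)
  expect_equal(find_peaks(s_tie, 0.5, 4), 2L)
})

test_that("movement counting recovers constructed trials", {
  # static trajectory
  expect_equal(count_movements(matrix(1, 100, 3))$count, 0)
  # fewer than 2 points is a logged zero, not an error
  expect_message(seg <- count_movements(matrix(0, 1, 3)), "fewer than 2")
  expect_equal(seg$count, 0)

  # 5 well-separated noiseless minimum-jerk movements
  tr <- generate_trial(synthetic_trial_spec(5, amplitudes = 0.1,
                                            durations = 0.6, pauses = 1,
                                            noise_sd = 0, seed = 21))
  seg <- count_movements(tr$stream$positions$master_left)
  expect_equal(seg$count, 5)
  expect_true(all(diff(seg$peaks) > 0))
  # peaks land near the movement midpoints
  expect_equal(seg$peaks / 30, tr$truth$peak_times, tolerance = 0.1)

  # single movement with speed-signal noise at 1% of the peak speed
  tr1 <- generate_trial(synthetic_trial_spec(1, amplitudes = 0.1,
                                             durations = 0.6, pauses = 1,
                                             noise_sd = 0, seed = 22))
  d <- interpoint_distances(tr1$stream$positions$master_left)
  set.seed(23)
  d_noisy <- d + rnorm(length(d), sd = 0.01 * max(d))
  sm <- smooth_gaussian(d_noisy, 5)
  expect_length(find_peaks(sm, 0.1 * max(sm), 10), 1)
})

test_that("noiseless synthetic trials are counted exactly for K in 1..20", {
  for (k in 1:20) {
    tr <- generate_trial(synthetic_trial_spec(
      k, amplitudes = 0.08, durations = 0.5, pauses = 0.6, noise_sd = 0,
      seed = 100 + k))
    expect_equal(count_movements(tr$stream$positions$master_left)$count, k)
  }
})

test_that("compute_metrics assembles per-manipulator metrics", {
  static <- kinematic_stream(list(master_left = matrix(0.3, 300, 3),
                                  master_right = matrix(0.1, 300, 3)), 30)
  m <- compute_metrics(static)
  expect_equal(m$time_s, c(10, 10))
  expect_equal(m$path_length_m, c(0, 0))
  expect_equal(m$movements, c(0L, 0L))

  tr <- generate_trial(synthetic_trial_spec(
    4, amplitudes = 0.1, durations = 0.5, pauses = 0.8, noise_sd = 0,
    manipulators = "master_left", seed = 31))
  s <- tr$stream
  # motion on the left hand only; right hand static
  s$positions$master_right <- matrix(0, n_samples(s), 3)
  m2 <- compute_metrics(s)
  left <- m2[m2$manipulator == "master_left", ]
  expect_equal(left$path_length_m, 0.4, tolerance = 1e-9)
  expect_equal(left$movements, 4L)
  expect_equal(m2$path_length_m[m2$manipulator == "master_right"], 0)
  expect_equal(m2$time_s, rep(tr$truth$time_s, 2))
  expect_error(compute_metrics(s, "slave_left"), "not in stream")
})

test_that("trajectory export returns raw ordered points consistent with PL", {
  set.seed(13)
  pos <- list(master_left = matrix(cumsum(rnorm(45, sd = 0.01)), ncol = 3))
  s <- kinematic_stream(pos, 30)
  tr <- trajectory_export(s, "master_left")
  expect_equal(nrow(tr), 15)
  expect_equal(tr$t, (0:14) / 30)
  expect_equal(path_length(as.matrix(tr[, c("x", "y", "z")])),
               compute_metrics(s, "master_left")$path_length_m)
  expect_error(trajectory_export(s, "slave_left"), "not in stream")
  s0 <- kinematic_stream(list(master_left = matrix(numeric(0), ncol = 3)))
  expect_equal(nrow(trajectory_export(s0, "master_left")), 0)
})

test_that("noise can only lengthen the expected path", {
  for (seed in 1:10) {
    base <- synthetic_trial_spec(3, amplitudes = 0.1, durations = 0.5,
                                 pauses = 0.7, noise_sd = 0, seed = seed)
    noisy <- base; noisy$noise_sd <- 5e-5
    pl0 <- path_length(generate_trial(base)$stream$positions$master_left)
    pl1 <- path_length(generate_trial(noisy)$stream$positions$master_left)
    expect_gte(pl1, pl0)
  }
})
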