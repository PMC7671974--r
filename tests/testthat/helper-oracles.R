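# Independent oracles and fixture builders shared across the test files.

# brute-force path length: explicit loop over consecutive point pairs
pl_oracle <- function(p) {
  s <- 0
  if (nrow(p) < 2) return(0)
  for (i in 2:nrow(p)) s <- s + sqrt(sum((p[i, ] - p[i - 1, ])^2))
  s
}

# full-enumeration two-sided Mann-Whitney p for the min-U statistic
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(pooled)
  u_min <- function(idx) {
    Ua <- sum(r[idx]) - na * (na + 1) / 2
    min(Ua, na * nb - Ua)
  }
  Uobs <- u_min(seq_len(na))
  Us <- utils::combn(N, na, u_min)
  min(1, mean(Us <= Uobs))
}

# naive strict-local-maxima scan (no separation pruning)
naive_peaks <- function(s, thr) {
  out <- integer(0)
  for (i in seq_along(s)) {
    if (i > 1 && i < length(s) && s[i] > s[i - 1] && s[i] > s[i + 1] &&
        s[i] > thr)
      out <- c(out, i)
  }
  out
}

# direct convolution with a truncated unit-sum Gaussian kernel under
# symmetric reflection, written as an explicit double loop
conv_oracle <- function(x, sigma) {
  n <- length(x)
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect1 <- function(i) {
    j <- (i - 1) %% (2 * n)
    if (j < 0) j <- j + 2 * n
    if (j < n) j + 1 else 2 * n - j
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (m in -r:r) acc <- acc + k[m + r + 1] * x[reflect1(i + m)]
    out[i] <- acc
  }
  out
}

# random proper rotation matrix
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# one valid 76-column kinematics line; positions of the first block set
# explicitly, remaining channels filled with small constants
row76 <- function(xyz = c(0.1, 0.2, 0.3)) {
  vals <- rep(0.5, 76)
  vals[1:3] <- xyz
  paste(format(vals, trim = TRUE), collapse = " ")
}

# minimal wide metrics + records pair for the stats table tests
fake_cohort_frames <- function(n_per_group = c(novice = 8, intermediate = 6,
                                               expert = 6),
                               time_means = c(novice = 120,
                                              intermediate = 90,
                                              expert = 60),
                               grs_means = c(novice = 12, intermediate = 18,
                                             expert = 24),
                               seed = 1) {
  participants <- list(novice = c("B", "G", "H", "I"),
                       intermediate = c("C", "F"), expert = c("D", "E"))
  set.seed(seed)
  rows <- list()
  for (sk in names(n_per_group)) {
    for (i in seq_len(n_per_group[[sk]])) {
      pp <- participants[[sk]][(i - 1) %% length(participants[[sk]]) + 1]
      rep_i <- (i - 1) %/% length(participants[[sk]]) + 1
      rows[[length(rows) + 1L]] <- data.frame(
        exercise = "suturing", participant = pp, repetition = rep_i,
        skill_level = sk,
        time_s = rnorm(1, time_means[[sk]], 5),
        left_path_length = rnorm(1, time_means[[sk]] / 50, 0.1),
        left_movements = rpois(1, time_means[[sk]] / 3),
        right_path_length = rnorm(1, time_means[[sk]] / 100, 0.05),
        right_movements = rpois(1, time_means[[sk]] / 4),
        grs_total = min(30, max(6, round(rnorm(1, grs_means[[sk]], 2)))),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  list(metrics = d[, c("exercise", "participant", "repetition", "time_s",
                       "left_path_length", "left_movements",
                       "right_path_length", "right_movements")],
       records = d[, c("exercise", "participant", "repetition",
                       "skill_level", "grs_total")])
}

default_skill_params_for_test <- function() {
  surgkin:::default_skill_params()
}

# small, fast strong-effect cohort spec for end-to-end tests
strong_effect_cohort <- function(seed, trials = 3) {
  cohort_spec(
    exercises = "suturing",
    trials_per_participant = trials,
    skill_params = list(
      novice = list(n_movements = c(25, 3), amplitude = c(0.08, 0.01),
                    duration = c(0.5, 0.05), pause = c(0.6, 0.05),
                    noise_sd = 5e-5, grs = c(12, 2)),
      intermediate = list(n_movements = c(15, 3), amplitude = c(0.08, 0.01),
                          duration = c(0.5, 0.05), pause = c(0.6, 0.05),
                          noise_sd = 5e-5, grs = c(18, 2)),
      expert = list(n_movements = c(8, 2), amplitude = c(0.08, 0.01),
                    duration = c(0.5, 0.05), pause = c(0.6, 0.05),
                    noise_sd = 5e-5, grs = c(24, 2))),
    seed = seed)
}
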