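# Statistical layer: group summaries, Mann-Whitney U, correlations,
# strength bands, trend lines, and the skill comparison table.

#' Per-group mean and sample standard deviation
#'
#' Summaries of the "mean +/- SD by skill level" kind. The SD is the sample
#' (n-1) standard deviation, reported as `NA` for singleton groups. Empty
#' groups are dropped with a warning.
#'
#' @param values numeric vector.
#' @param groups vector of group labels, same length as `values`; factor
#'   level order is preserved.
#' @return data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, groups) {
  if (length(values) != length(groups))
    stopf("values and groups must have the same length")
  assert_finite_numeric(values, "values")
  groups <- as.factor(groups)
  empty <- levels(groups)[!levels(groups) %in% unique(as.character(groups))]
  if (length(empty))
    warnf("empty group(s) omitted: %s", paste(empty, collapse = ", "))
  present <- levels(groups)[levels(groups) %in% unique(as.character(groups))]
  rows <- lapply(present, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# number of rank assignments with U_a <= U, by the classical recurrence
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1); integer counts keep the
# final p a single exact division, bit-identical to full enumeration
mw_count_le <- function(U, m, n) {
  arr <- array(0, dim = c(m + 1, n + 1, m * n + 1))
  arr[1, , 1] <- 1
  arr[, 1, 1] <- 1
  for (i in seq_len(m)) for (j in seq_len(n)) for (u in 0:(i * j)) {
    a <- if (u - j >= 0) arr[i, j + 1, u - j + 1] else 0
    arr[i + 1, j + 1, u + 1] <- a + arr[i + 1, j, u + 1]
  }
  sum(arr[m + 1, n + 1, seq_len(floor(U) + 1)])
}

# exact two-sided p for the min-U statistic via the null U distribution
mw_exact_p <- function(U, na, nb) {
  min(1, 2 * mw_count_le(U, na, nb) / choose(na + nb, na))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test between two independent samples. `U` is the smaller of the
#' two one-sided U statistics computed from midranks. The p-value is exact
#' (from the null distribution of U) when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U`, `p`, `method` ("exact" or "normal") and the
#'   sample sizes `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  assert_finite_numeric(a, "a"); assert_finite_numeric(b, "b")
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stopf("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  ties <- anyDuplicated(pooled) > 0
  if (!ties && na <= 8 && nb <= 8) {
    p <- mw_exact_p(U, na, nb)
    method <- "exact"
  } else {
    N <- na + nb
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      mu <- na * nb / 2
      z <- (U - mu + 0.5) / sqrt(sigma2)  # U <= mu, correct toward center
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method, n_a = na, n_b = nb)
}

#' Correlation strength band
#'
#' Classifies the magnitude of a correlation coefficient: `|r| > 0.7`
#' strong, `> 0.5` moderate, `> 0.3` weak, otherwise negligible (strict
#' inequalities; the sign is reported separately by the correlation
#' functions).
#'
#' @param r numeric vector of correlation coefficients in `[-1, 1]`.
#' @return character vector of labels.
#' @export
classify_correlation <- function(r) {
  assert_finite_numeric(r, "r")
  if (any(abs(r) > 1 + 1e-12)) stopf("|r| must not exceed 1")
  a <- pmin(abs(r), 1)
  ifelse(a > 0.7, "strong",
         ifelse(a > 0.5, "moderate",
                ifelse(a > 0.3, "weak", "negligible")))
}

correlation_result <- function(method, r, p, n) {
  structure(
    list(method = method, r = r, p = p, n = n,
         strength = classify_correlation(r)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s correlation> r = %.3f (%s), p = %.4g, n = %d\n",
              x$method, x$r, x$strength, x$p, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return a `correlation_result` with fields `method`, `r`, `p`, `n`,
#'   `strength`.
#' @export
pearson_r <- function(x, y) {
  assert_finite_numeric(x, "x"); assert_finite_numeric(y, "y")
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1 - 1e-15) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  correlation_result("pearson", r, p, n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; ties share midranks. The p-value uses
#' the same t transform as [pearson_r()], appropriate for the moderate
#' sample sizes of trial data. Suitable for correlating an ordinal skill
#' coding (novice = 1, intermediate = 2, expert = 3) with scores.
#'
#' @param x,y numeric (or ordinal, coercible) vectors of equal length,
#'   n >= 3; the ranks of each must not be constant.
#' @return a `correlation_result` with `method = "spearman"`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  rx <- rank(as.numeric(x)); ry <- rank(as.numeric(y))
  out <- pearson_r(rx, ry)
  out$method <- "spearman"
  out
}

#' Encode skill levels as ordinals
#'
#' novice = 1, intermediate = 2, expert = 3.
#'
#' @param skill character vector of skill levels.
#' @return integer vector.
#' @export
skill_ordinal <- function(skill) {
  out <- match(skill, skill_levels())
  if (anyNA(out))
    stopf("unknown skill level: %s", paste(skill[is.na(out)], collapse = ", "))
  out
}

#' Ordinary least-squares trend line
#'
#' Slope and intercept for scatter-plot annotation.
#'
#' @param x,y numeric vectors of equal length, n >= 2; `x` must vary.
#' @return list with `slope` and `intercept`.
#' @export
linear_trend <- function(x, y) {
  assert_finite_numeric(x, "x"); assert_finite_numeric(y, "y")
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("at least 2 observations are required")
  if (stats::sd(x) == 0) stopf("trend undefined: x has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

# parameters of the comparison table, in reporting order
comparison_parameters <- function() {
  c("time", "left_path_length", "left_movements",
    "right_path_length", "right_movements", "grs")
}

skill_pairs <- function() {
  list(novice_intermediate = c("novice", "intermediate"),
       intermediate_expert = c("intermediate", "expert"),
       novice_expert = c("novice", "expert"))
}

#' Skill comparison table for one or more exercises
#'
#' For each exercise and parameter (time, left/right path length, left/right
#' movements, GRS total) computes the per-skill mean +/- SD, the three
#' pairwise Mann-Whitney p-values (novice/intermediate, intermediate/expert,
#' novice/expert) with significance flags at `alpha`, and the Pearson
#' correlation of each kinematic parameter with the GRS total (pooled over
#' all skill levels of the exercise); plus, per exercise, the Spearman
#' correlation of the ordinal skill level with GRS.
#'
#' @param metrics data frame with one row per trial and columns `exercise`,
#'   `participant`, `repetition`, `time_s`, `left_path_length`,
#'   `left_movements`, `right_path_length`, `right_movements` (as produced
#'   by the pipeline; see [run_analysis()]).
#' @param records a `trial_records` data frame (see [read_meta()]).
#' @param alpha significance level (default 0.05).
#' @param holm apply a Holm correction across the three pairwise tests of
#'   each parameter before flagging (off by default; raw p-values are always
#'   reported).
#' @return list with data frames `comparisons` (one row per exercise x
#'   parameter) and `spearman` (one row per exercise).
#' @export
skill_comparison_table <- function(metrics, records, alpha = 0.05,
                                   holm = FALSE) {
  key <- function(d) paste(d$exercise, d$participant, d$repetition)
  idx <- match(key(metrics), key(records))
  if (anyNA(idx))
    stopf("metric rows without a matching trial record: %s",
          paste(key(metrics)[is.na(idx)], collapse = "; "))
  metrics$skill_level <- records$skill_level[idx]
  metrics$grs_total <- records$grs_total[idx]
  param_col <- c(time = "time_s", left_path_length = "left_path_length",
                 left_movements = "left_movements",
                 right_path_length = "right_path_length",
                 right_movements = "right_movements", grs = "grs_total")
  comp_rows <- list(); sp_rows <- list()
  for (ex in unique(metrics$exercise)) {
    d <- metrics[metrics$exercise == ex, , drop = FALSE]
    for (par in comparison_parameters()) {
      v <- d[[param_col[[par]]]]
      gs <- group_summary(v, factor(d$skill_level, levels = skill_levels()))
      ps <- vapply(skill_pairs(), function(pair) {
        a <- v[d$skill_level == pair[1]]
        b <- v[d$skill_level == pair[2]]
        if (!length(a) || !length(b)) return(NA_real_)  # group absent
        mann_whitney_u(a, b)$p
      }, numeric(1))
      flag_p <- if (holm) stats::p.adjust(ps, method = "holm") else ps
      cr <- if (par != "grs" && stats::sd(v) > 0 && stats::sd(d$grs_total) > 0)
        pearson_r(v, d$grs_total) else NULL
      stat <- function(g, f) {
        i <- match(g, gs$group)
        if (is.na(i)) NA_real_ else gs[[f]][i]
      }
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        exercise = ex, parameter = par,
        n_novice = stat("novice", "n"), mean_novice = stat("novice", "mean"),
        sd_novice = stat("novice", "sd"),
        n_intermediate = stat("intermediate", "n"),
        mean_intermediate = stat("intermediate", "mean"),
        sd_intermediate = stat("intermediate", "sd"),
        n_expert = stat("expert", "n"), mean_expert = stat("expert", "mean"),
        sd_expert = stat("expert", "sd"),
        p_novice_intermediate = ps[[1]], p_intermediate_expert = ps[[2]],
        p_novice_expert = ps[[3]],
        sig_novice_intermediate = !is.na(flag_p[[1]]) & flag_p[[1]] < alpha,
        sig_intermediate_expert = !is.na(flag_p[[2]]) & flag_p[[2]] < alpha,
        sig_novice_expert = !is.na(flag_p[[3]]) & flag_p[[3]] < alpha,
        pearson_r_grs = if (is.null(cr)) NA_real_ else cr$r,
        pearson_p_grs = if (is.null(cr)) NA_real_ else cr$p,
        pearson_strength = if (is.null(cr)) NA_character_ else cr$strength,
        stringsAsFactors = FALSE)
    }
    sp <- tryCatch(spearman_rho(skill_ordinal(d$skill_level), d$grs_total),
                   error = function(e) NULL)  # e.g. single skill group
    sp_rows[[length(sp_rows) + 1L]] <- data.frame(
      exercise = ex, n = nrow(d),
      spearman_r = if (is.null(sp)) NA_real_ else sp$r,
      spearman_p = if (is.null(sp)) NA_real_ else sp$p,
      strength = if (is.null(sp)) NA_character_ else sp$strength,
      stringsAsFactors = FALSE)
  }
  list(comparisons = do.call(rbind, comp_rows),
       spearman = do.call(rbind, sp_rows))
}
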