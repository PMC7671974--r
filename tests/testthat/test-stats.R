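# Statistical layer.

test_that("group summaries give mean and sample SD, dropping empty groups", {
  gs <- group_summary(c(1, 2, 3), rep("a", 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sd, 1)
  gs1 <- group_summary(5, "a")
  expect_equal(gs1$mean, 5)
  expect_true(is.na(gs1$sd))
  gs2 <- group_summary(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gs2$mean[1], gs2$mean[2])
  expect_equal(gs2$sd[1], gs2$sd[2])
  expect_warning(
    gs3 <- group_summary(c(1, 2), factor(c("a", "a"), levels = c("a", "b"))),
    "empty")
  expect_equal(gs3$group, "a")
})

test_that("Mann-Whitney U matches the enumeration oracle and handles ties", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  # identical samples: U at its center, p = 1 under the approximation
  res2 <- mann_whitney_u(c(1, 2, 5, 9), c(1, 2, 5, 9))
  expect_equal(res2$p, 1)

  # midrank ties put U at n_a * n_b / 2
  res3 <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(res3$U, 2)

  # all observations identical: degenerate variance, p = 1
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 9))$p, 1)
})

test_that("exact p equals full enumeration for all tie-free sizes up to 6", {
  set.seed(33)
  for (na in 1:6) for (nb in 1:6) {
    for (rep_i in 1:3) {
      v <- sample(1000, na + nb)  # distinct values, no ties
      a <- v[seq_len(na)]; b <- v[-seq_len(na)]
      expect_identical(mann_whitney_u(a, b)$p, mw_enum_p(a, b))
    }
  }
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(34)
  # exact branch
  a <- rnorm(6); b <- rnorm(8) + 1
  expect_equal(mann_whitney_u(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
  # normal approximation with ties and continuity correction
  a2 <- round(rnorm(15, sd = 2)); b2 <- round(rnorm(12, sd = 2) + 1)
  expect_equal(mann_whitney_u(a2, b2)$p,
               suppressWarnings(
                 wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-12)
})

test_that("Pearson correlation and its t-based p behave", {
  expect_equal(pearson_r(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_r(1:4, c(2, 4, 6, 8))$p, 0)
  expect_equal(pearson_r(1:4, c(8, 6, 4, 2))$r, -1)
  set.seed(35)
  x <- rnorm(20); y <- rnorm(20)
  res <- pearson_r(x, y)
  ref <- cor.test(x, y)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p, ref$p.value)
  # affine invariance
  res2 <- pearson_r(3 * x + 7, 0.5 * y - 2)
  expect_equal(res2$r, res$r)
  expect_equal(res2$p, res$p)
  # independent permutations average near zero
  rs <- replicate(200, pearson_r(x, sample(y))$r)
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(pearson_r(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Spearman rho is rank-based and monotone-invariant", {
  skill <- c(1, 2, 2, 3, 3, 3)
  y_up <- c(0.1, 0.5, 0.7, 1.2, 1.9, 2.4)
  # any strictly increasing y over ordered untied ranks gives rho = 1
  expect_equal(spearman_rho(1:6, y_up)$r, 1, tolerance = 1e-12)
  expect_equal(spearman_rho(1:6, rev(y_up))$r, -1, tolerance = 1e-12)
  # with tied skill groups rho comes from midranks, bounded away from 1
  expect_lt(spearman_rho(skill, y_up)$r, 1)
  expect_equal(spearman_rho(skill, y_up)$r,
               cor(rank(skill), rank(y_up)), tolerance = 1e-12)
  set.seed(36)
  x <- sample(rep(1:3, each = 5)); y <- rnorm(15)
  expect_equal(spearman_rho(x, y)$r,
               unname(cor(rank(x), rank(y))), tolerance = 1e-12)
  expect_equal(spearman_rho(x, y)$r, cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), y^3 - 2 * y * 0)$r,
               spearman_rho(x, y)$r, tolerance = 1e-12)
})

test_that("correlation strength bands use strict thresholds on |r|", {
  expect_equal(classify_correlation(0.55), "moderate")
  expect_equal(classify_correlation(-0.34), "weak")
  expect_equal(classify_correlation(0.70), "moderate")
  expect_equal(classify_correlation(0.71), "strong")
  expect_equal(classify_correlation(0.3), "negligible")
  expect_equal(classify_correlation(-0.95), "strong")
  expect_error(classify_correlation(1.2), "exceed")
  # order-preserving on |r|
  r <- seq(0, 1, by = 0.01)
  lev <- match(classify_correlation(r),
               c("negligible", "weak", "moderate", "strong"))
  expect_true(all(diff(lev) >= 0))
})

test_that("linear trend equals the closed-form normal equations", {
  tr <- linear_trend(1:10, 2 * (1:10) + 1)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 1)
  expect_equal(linear_trend(1:10, rep(4, 10))$slope, 0)
  set.seed(37)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    tr <- linear_trend(x, y)
    slope_o <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
    expect_equal(tr$slope, slope_o, tolerance = 1e-9)
    expect_equal(tr$intercept, mean(y) - slope_o * mean(x), tolerance = 1e-9)
  }
  expect_error(linear_trend(rep(1, 5), 1:5), "zero variance")
})

test_that("skill comparison table joins, tests and correlates correctly", {
  fc <- fake_cohort_frames()
  tab <- skill_comparison_table(fc$metrics, fc$records)
  cmp <- tab$comparisons
  expect_setequal(unique(cmp$parameter),
                  c("time", "left_path_length", "left_movements",
                    "right_path_length", "right_movements", "grs"))
  trow <- cmp[cmp$parameter == "time", ]
  # large constructed separation: novice/expert difference is significant
  expect_true(trow$sig_novice_expert)
  expect_true(all(cmp$p_novice_expert >= 0 & cmp$p_novice_expert <= 1,
                  na.rm = TRUE))
  # flags are exactly p < alpha
  expect_equal(cmp$sig_novice_intermediate,
               !is.na(cmp$p_novice_intermediate) &
                 cmp$p_novice_intermediate < 0.05)

  # Pearson column equals a direct call on the joined data
  key <- function(d) paste(d$exercise, d$participant, d$repetition)
  grs <- fc$records$grs_total[match(key(fc$metrics), key(fc$records))]
  direct <- pearson_r(fc$metrics$time_s, grs)
  expect_equal(trow$pearson_r_grs, direct$r)
  expect_equal(trow$pearson_p_grs, direct$p)
  # GRS row carries no self-correlation
  expect_true(is.na(cmp$pearson_r_grs[cmp$parameter == "grs"]))

  # Spearman uses the ordinal skill coding
  sk <- fc$records$skill_level[match(key(fc$metrics), key(fc$records))]
  direct_sp <- spearman_rho(skill_ordinal(sk), grs)
  expect_equal(tab$spearman$spearman_r, direct_sp$r)
  expect_equal(tab$spearman$spearman_p, direct_sp$p)

  # a missing group yields NA p-values, not an error
  fc2 <- fake_cohort_frames(n_per_group = c(novice = 6, intermediate = 0,
                                            expert = 6))
  tab2 <- suppressWarnings(skill_comparison_table(fc2$metrics, fc2$records))
  expect_true(all(is.na(tab2$comparisons$p_novice_intermediate)))
  expect_false(any(is.na(tab2$comparisons$p_novice_expert)))

  # unmatched metric rows are an error
  bad <- fc$metrics; bad$participant[1] <- "Z"
  expect_error(skill_comparison_table(bad, fc$records), "without a matching")
})

test_that("Holm flagging is more conservative than raw flagging", {
  fc <- fake_cohort_frames(time_means = c(novice = 100, intermediate = 95,
                                          expert = 90), seed = 4)
  raw <- skill_comparison_table(fc$metrics, fc$records)$comparisons
  holm <- skill_comparison_table(fc$metrics, fc$records,
                                 holm = TRUE)$comparisons
  sig_cols <- c("sig_novice_intermediate", "sig_intermediate_expert",
                "sig_novice_expert")
  expect_true(all(unlist(holm[sig_cols]) <= unlist(raw[sig_cols])))
  # raw p-values are reported unchanged
  expect_equal(holm$p_novice_expert, raw$p_novice_expert)
})
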