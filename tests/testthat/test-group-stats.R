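test_that("Shapiro-Wilk screen behaves across regular and degenerate samples", {
  set.seed(42)
  ok <- 0L
  for (s in 1:100) {
    x <- rnorm(26)
    if (cc_shapiro(x)$p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 88L)    # nominal non-rejection rate is 95%
  bimodal <- c(rep(0, 13), rep(10, 13)) + rnorm(26, sd = 0.05)
  expect_lt(cc_shapiro(bimodal)$p, 0.01)
  expect_error(cc_shapiro(c(1, 2)), class = "ccmorph_too_few")
  expect_error(cc_shapiro(rep(3, 10)), class = "ccmorph_degenerate")
  # cross-check against the reference implementation
  x <- rnorm(40)
  expect_equal(cc_shapiro(x)$W, unname(shapiro.test(x)$statistic))
})

test_that("paired t matches the hand-computed formula and handles degenerate differences", {
  # differences (2,0,2,0,2,0): mean 1, sd sqrt(6/5), t = sqrt(5), p from t5
  r <- paired_t(c(3, 1, 3, 1, 3, 1), c(1, 1, 1, 1, 1, 1))
  expect_equal(r$t, sqrt(5), tolerance = 1e-12)
  expect_equal(r$t, 2.2360679, tolerance = 1e-6)
  expect_equal(r$p, 2 * pt(-sqrt(5), 5), tolerance = 1e-12)
  expect_equal(r$p, 0.075589, tolerance = 1e-4)
  # agrees with stats::t.test on non-degenerate data
  set.seed(1); a <- rnorm(13, 1); b <- rnorm(13)
  tt <- t.test(a, b, paired = TRUE)
  r2 <- paired_t(a, b)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p, tt$p.value)
  expect_equal(r2$ci, unname(tt$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)

  ident <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ident$t, 0); expect_identical(ident$p, 1)
  expect_warning(deg <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 class = "ccmorph_zero_variance")
  expect_identical(deg$p, 0)
})

test_that("per-centile comparison flags only real differences and locates the maximum", {
  set.seed(9)
  X <- matrix(rnorm(26 * 99, mean = 8, sd = 0.1), 26)
  co <- cc_cohort(X, rep(c("case", "control"), each = 13),
                  pairing = c(1:13, 1:13))
  same <- compare_centiles(co)
  expect_identical(nrow(same), 99L)
  expect_false(any(same$sig_bonferroni))

  X2 <- X
  X2[1:13, 50] <- X2[1:13, 50] + 10
  co2 <- cc_cohort(X2, co$group, pairing = co$pairing)
  cmp <- compare_centiles(co2)
  expect_identical(which(cmp$sig_bonferroni), 50L)
  expect_identical(attr(cmp, "summary")$at_centile, 50L)
  expect_equal(attr(cmp, "summary")$max_abs_diff_mm, 10, tolerance = 0.15)
  # CI of each group mean contains that mean
  expect_true(all(cmp$ci_lo_case <= cmp$mean_case &
                    cmp$mean_case <= cmp$ci_hi_case))
})

test_that("Bonferroni flags are a subset of unadjusted flags at any alpha", {
  set.seed(77)
  for (alpha in c(0.01, 0.05, 0.2)) {
    X <- matrix(rnorm(20 * 99, 8), 20) +
      cbind(matrix(0, 20, 49), matrix(rep(c(0.8, 0), c(10, 10)), 20, 50))
    co <- cc_cohort(X, rep(c("case", "control"), each = 10))
    cmp <- compare_centiles(co, alpha = alpha)
    expect_true(all(cmp$sig_unadjusted[cmp$sig_bonferroni]))
  }
})

test_that("one-way ANOVA matches the hand computation and the t-squared identity", {
  an <- anova_factor_scores(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                            rep(c("case", "control"), each = 3))
  expect_equal(an$F, 13.5, tolerance = 1e-12)
  expect_identical(an$df2, 4L)
  expect_equal(an$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(an$critical_F, qf(0.95, 1, 4), tolerance = 1e-12)

  # identical sets in both groups: F = 0
  an0 <- anova_factor_scores(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1),
                             rep(c("case", "control"), each = 3))
  expect_equal(an0$F, 0, tolerance = 1e-12)

  # F equals the square of the pooled-variance two-sample t
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(13); y <- rnorm(13, 0.5)
    an2 <- anova_factor_scores(matrix(c(x, y), ncol = 1),
                               rep(c("case", "control"), each = 13))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an2$p, tt$p.value, tolerance = 1e-10)
  }
  # cross-check against aov on multi-column scores
  S <- matrix(rnorm(26 * 3), 26)
  g <- rep(c("case", "control"), each = 13)
  an3 <- anova_factor_scores(S, g)
  for (j in 1:3) {
    ref <- summary(aov(S[, j] ~ factor(g)))[[1]]
    expect_equal(an3$F[j], ref[["F value"]][1], tolerance = 1e-10)
  }
})

test_that("global comparisons run the paired chain per measure", {
  set.seed(3)
  glob <- data.frame(area = c(rnorm(13, 600, 40), rnorm(13, 600, 40)),
                     perimeter = rnorm(26, 200, 10),
                     centreline_length = rnorm(26, 80, 5))
  g <- rep(c("case", "control"), each = 13)
  out <- compare_globals(glob, g, pairing = c(1:13, 1:13))
  expect_identical(out$measure, c("area", "perimeter", "centreline_length"))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(out$ci_lo <= out$mean_diff & out$mean_diff <= out$ci_hi))
})

test_that("power is concentrated on the affected factor", {
  # under the default effect generator, the factor covering centiles 61-70
  # rejects more often than any factor covering unaffected centiles
  nrep <- 60
  hit <- matrix(NA, nrep, 2)
  for (i in seq_len(nrep)) {
    cfg <- generator_config(seed = 7000 + i)
    co <- suppressWarnings(generate_cohort(cfg))
    r <- suppressWarnings(regionalize(co))
    ov <- vapply(seq_len(r$retained_k), function(j)
      sum(which(r$region_of_centile == j) %in% 61:70), numeric(1))
    j4 <- which.max(ov)
    # an unaffected comparator: the factor owning most of centiles 38-55
    ov3 <- vapply(seq_len(r$retained_k), function(j)
      sum(which(r$region_of_centile == j) %in% 38:55), numeric(1))
    j3 <- which.max(ov3)
    an <- suppressWarnings(anova_factor_scores(
      r$scores[, c(j4, j3), drop = FALSE], co$group))
    hit[i, ] <- an$p < 0.05
  }
  expect_gt(mean(hit[, 1]), mean(hit[, 2]))
  expect_lt(mean(hit[, 2]), 0.2)
})
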