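test_that("PCA explained fractions behave on constructed covariance structures", {
  set.seed(101)
  # rank-1: all centiles share one subject-level value plus tiny jitter
  v <- rnorm(30)
  X1 <- outer(v, rep(1, 99)) + matrix(rnorm(30 * 99, sd = 1e-3), 30)
  p1 <- cc_pca(X1)
  expect_gt(p1$explained_fraction[1], 0.99)

  # two independent latent factors on disjoint halves, 10% noise
  a <- rnorm(200); b <- rnorm(200)
  X2 <- cbind(outer(a, rep(1, 50)), outer(b, rep(1, 49))) +
    matrix(rnorm(200 * 99, sd = 0.1), 200)
  p2 <- cc_pca(X2)
  expect_true(all(p2$explained_fraction[1:2] > 0.45 &
                    p2$explained_fraction[1:2] < 0.52))
  expect_true(all(p2$explained_fraction[-(1:2)] < 0.02))

  expect_equal(sum(p2$explained_fraction), 1, tolerance = 1e-10)
  expect_error(cc_pca(cbind(X2[, 1:98], 5)), class = "ccmorph_constant_centile")
  expect_error(cc_pca(X2[1:2, ]), class = "ccmorph_too_few")
})

test_that("retention counts components strictly above the threshold", {
  expect_identical(retain_components(c(0.60, 0.20, 0.011, 0.009, 0.002)), 3L)
  expect_identical(retain_components(c(0.5, 0.5)), 2L)
  expect_identical(retain_components(c(0.99, 0.01)), 1L)  # 0.01 not > 0.01
  expect_error(retain_components(c(0.009, 0.005), threshold = 0.01),
               class = "ccmorph_nothing_retained")
})

test_that("varimax leaves k = 1 and perfect simple structure unchanged, and undoes a 45-degree mix", {
  L1 <- matrix(seq(0.1, 1, length.out = 99), ncol = 1)
  expect_equal(rotate_varimax(L1)$loadings, L1)

  # block simple structure is already optimal
  B <- matrix(0, 99, 2)
  B[1:50, 1] <- 0.9; B[51:99, 2] <- 0.8
  rb <- rotate_varimax(B)$loadings
  perm <- if (which.max(abs(rb[1, ])) == 1L) 1:2 else 2:1
  expect_equal(abs(rb[, perm]), abs(B), tolerance = 1e-6)

  # rotate the block structure by 45 degrees; varimax must recover it
  th <- pi / 4
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mixed <- B %*% Rm
  rec <- rotate_varimax(mixed)$loadings
  perm <- if (which.max(abs(rec[1, ])) == 1L) 1:2 else 2:1
  expect_equal(abs(rec[, perm]), abs(B), tolerance = 1e-4)
  crit <- function(L) { x <- L^2; sum(apply(x, 2, var)) }
  expect_gt(crit(rec), crit(mixed))
})

test_that("rotation preserves communalities and total explained variance", {
  set.seed(7)
  co <- suppressWarnings(generate_cohort(generator_config(n_case = 60L, n_control = 60L, seed = 7)))
  p <- cc_pca(co)
  k <- retain_components(p$explained_fraction)
  A <- p$eigenvectors[, 1:k] %*% diag(sqrt(p$eigenvalues[1:k]))
  rot <- rotate_varimax(A)$loadings
  expect_equal(rowSums(rot^2), rowSums(A^2), tolerance = 1e-10)
  expect_equal(sum(rot^2), sum(p$eigenvalues[1:k]), tolerance = 1e-8)
})

test_that("region assignment follows the largest |loading| with tie-break and runs report", {
  B <- matrix(0, 99, 3)
  B[1:33, 1] <- 0.9; B[34:66, 2] <- -0.8; B[67:99, 3] <- 0.7
  asg <- assign_regions(B)
  expect_identical(asg$region_of_centile, rep(1:3, each = 33))
  expect_identical(nrow(asg$runs), 3L)

  B[1, ] <- c(0.5, 0.5, 0.1)
  expect_warning(asg2 <- assign_regions(B), class = "ccmorph_loading_tie")
  expect_identical(asg2$region_of_centile[1], 1L)
})

test_that("region assignment is invariant to column sign flips and permutations", {
  co <- suppressWarnings(generate_cohort(generator_config(n_case = 50L, n_control = 50L, seed = 13)))
  r <- suppressWarnings(regionalize(co))
  L <- r$loadings
  flip <- L %*% diag(c(-1, 1, -1, 1, 1, -1, 1)[seq_len(ncol(L))])
  perm <- sample(ncol(L))
  a0 <- assign_regions(L)$region_of_centile
  a1 <- assign_regions(flip)$region_of_centile
  a2 <- assign_regions(L[, perm])$region_of_centile
  expect_equal(region_agreement(a1, a0, centiles = 1:99), 1)
  expect_equal(region_agreement(a2, a0, centiles = 1:99), 1)
})

test_that("factor scores have zero mean, rank thickened subjects first, and duplicate consistently", {
  co <- suppressWarnings(generate_cohort(generator_config(n_case = 40L, n_control = 40L, seed = 23)))
  r <- suppressWarnings(regionalize(co))
  expect_true(all(abs(colMeans(r$scores)) < 1e-10))

  # thicken one subject across a designed region; it must top that factor
  cfg <- generator_config(seed = 23)
  part <- designed_partition(cfg)
  co2 <- co
  co2$widths[5, part == 2] <- co2$widths[5, part == 2] + 6
  r2 <- suppressWarnings(regionalize(co2))
  j <- which.max(vapply(seq_len(r2$retained_k), function(j)
    sum(part[r2$region_of_centile == j] == 2), numeric(1)))
  sgn <- sign(sum(r2$loadings[part == 2, j]))
  expect_identical(unname(which.max(sgn * r2$scores[, j])), 5L)

  # duplicated cohort: identical scores duplicated
  co3 <- cc_cohort(rbind(co$widths, co$widths), c(as.character(co$group),
                                                  as.character(co$group)))
  L3 <- suppressWarnings(regionalize(co))$loadings
  s3 <- suppressWarnings(factor_scores(co3, L3))
  expect_equal(unname(s3[1:80, ]), unname(s3[81:160, ]), tolerance = 1e-8)
})

test_that("the default generator's regions are recovered across seeds", {
  agr <- vapply(1:20, function(s) {
    cfg <- generator_config(n_case = 100L, n_control = 100L, seed = 100 + s)
    co <- suppressWarnings(generate_cohort(cfg))
    r <- suppressWarnings(regionalize(co))
    region_agreement(r$region_of_centile, designed_partition(cfg))
  }, numeric(1))
  expect_true(all(agr >= 0.8))
})

test_that("end-taper factors are flagged and excluded from comparison by default", {
  co <- suppressWarnings(generate_cohort(generator_config(n_case = 80L, n_control = 80L, seed = 31)))
  r <- suppressWarnings(regionalize(co))
  expect_identical(sum(r$end_taper), 1L)
  own <- which(r$region_of_centile == which(r$end_taper))
  expect_gt(mean(own %in% c(1:4, 96:99)), 0.5)
})
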