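#' Shapiro-Wilk normality screen
#'
#' Standard Shapiro-Wilk test (delegates to [stats::shapiro.test()]),
#' with explicit errors for the degenerate inputs the pipeline can produce.
#'
#' @param values numeric sample, 3 to 5000 observations.
#' @return List with `W` and `p`.
#' @export
cc_shapiro <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) cc_stop("too-few", "Shapiro-Wilk needs n >= 3")
  if (length(values) > 5000L) cc_stop("too-many", "Shapiro-Wilk needs n <= 5000")
  if (stats::sd(values) == 0)
    cc_stop("degenerate", "all values identical; W undefined")
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Paired Student's t-test of a global measure
#'
#' Classical paired t: `t = mean(d) / (sd(d) / sqrt(n))` on the case-minus-
#' control differences, two-sided p on n-1 degrees of freedom, and the 95%
#' t-interval of the mean difference. Degenerate inputs are handled
#' explicitly: identical pairs give `t = 0, p = 1`; constant nonzero
#' differences give `p = 0` with a warning.
#'
#' @param case,control equal-length paired values (already matched; use
#'   `pairing` to align them first if needed).
#' @param pairing optional integer match index for each vector; when given,
#'   both vectors are reordered so matching indices align.
#' @param conf_level confidence level of the interval.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci` (length 2), `n`.
#' @export
paired_t <- function(case, control, pairing = NULL, conf_level = 0.95) {
  if (!is.null(pairing)) {
    stopifnot(length(pairing) == 2L)
    case <- case[order(pairing[[1L]])]
    control <- control[order(pairing[[2L]])]
  }
  if (length(case) != length(control))
    cc_stop("unpaired", "paired test needs equal-length samples")
  n <- length(case)
  if (n < 2L) cc_stop("too-few", "paired t needs n >= 2")
  d <- case - control
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                            ci = c(0, 0), n = n))
    cc_warn("zero-variance",
            "constant nonzero paired differences; p reported as 0")
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean_diff = m,
                ci = c(m, m), n = n))
  }
  se <- s / sqrt(n)
  tt <- m / se
  q <- stats::qt(1 - (1 - conf_level) / 2, n - 1L)
  list(t = tt, df = n - 1L, p = 2 * stats::pt(-abs(tt), n - 1L),
       mean_diff = m, ci = c(m - q * se, m + q * se), n = n)
}

#' Compare global callosal measures between groups
#'
#' Paired t-tests of area, perimeter and centreline length (or whichever of
#' these are available) between the case and control groups.
#'
#' @param globals data frame of per-subject global measures.
#' @param group case/control factor, one entry per row of `globals`.
#' @param pairing integer match index per subject (paired design).
#' @param measures which columns of `globals` to compare.
#' @return Data frame: measure, t, df, p, mean_diff, ci_lo, ci_hi.
#' @export
compare_globals <- function(globals, group,
                            pairing = NULL,
                            measures = intersect(c("area", "perimeter",
                                                   "centreline_length"),
                                                 names(globals))) {
  ic <- group == "case"; ik <- group == "control"
  out <- lapply(measures, function(m) {
    pr <- if (!is.null(pairing)) list(pairing[ic], pairing[ik])
    r <- paired_t(globals[[m]][ic], globals[[m]][ik], pairing = pr)
    data.frame(measure = m, t = r$t, df = r$df, p = r$p,
               mean_diff = r$mean_diff, ci_lo = r$ci[1L], ci_hi = r$ci[2L])
  })
  do.call(rbind, out)
}

#' Per-centile group comparison with Bonferroni correction
#'
#' At each of the 99 centiles: the case-minus-control mean width difference,
#' the 95% t-interval of each group mean, the per-centile p-value (paired t
#' when the cohort carries a pairing, Welch otherwise), and significance
#' flags before and after Bonferroni correction over the 99 tests
#' (two-sided, threshold `alpha / m`).
#'
#' @param cohort a [cc_cohort()] with both groups present.
#' @param alpha family significance level.
#' @param m number of tests for the Bonferroni correction.
#' @return Data frame with 99 rows (class `cc_centile_comparison`); the
#'   location and value of the maximum absolute mean difference are attached
#'   as the `summary` attribute.
#' @export
compare_centiles <- function(cohort, alpha = 0.05, m = 99L) {
  stopifnot(inherits(cohort, "cc_cohort"))
  Xc <- cohort$widths[cohort$group == "case", , drop = FALSE]
  Xk <- cohort$widths[cohort$group == "control", , drop = FALSE]
  if (nrow(Xc) < 2L || nrow(Xk) < 2L)
    cc_stop("too-few", "both groups need at least 2 subjects")
  paired <- !is.null(cohort$pairing) && nrow(Xc) == nrow(Xk)
  nc <- nrow(Xc); nk <- nrow(Xk)
  mc <- colMeans(Xc); mk <- colMeans(Xk)
  vc <- apply(Xc, 2L, stats::var); vk <- apply(Xk, 2L, stats::var)
  if (paired) {
    Xc <- Xc[order(cohort$pairing[cohort$group == "case"]), , drop = FALSE]
    Xk <- Xk[order(cohort$pairing[cohort$group == "control"]), , drop = FALSE]
    D <- Xc - Xk
    md <- colMeans(D)
    se <- sqrt(apply(D, 2L, stats::var) / nc)
    df <- rep(nc - 1, 99L)
  } else {
    md <- mc - mk
    se <- sqrt(vc / nc + vk / nk)
    df <- se^4 / ((vc / nc)^2 / (nc - 1) + (vk / nk)^2 / (nk - 1))  # Welch
  }
  tt <- ifelse(se == 0, ifelse(md == 0, 0, sign(md) * Inf), md / se)
  p <- ifelse(is.infinite(tt), 0, 2 * stats::pt(-abs(tt), df))
  p[tt == 0 & se == 0] <- 1
  qc <- stats::qt(0.975, nc - 1); qk <- stats::qt(0.975, nk - 1)
  out <- data.frame(
    centile = 1:99,
    mean_case = mc, ci_lo_case = mc - qc * sqrt(vc / nc),
    ci_hi_case = mc + qc * sqrt(vc / nc),
    mean_control = mk, ci_lo_control = mk - qk * sqrt(vk / nk),
    ci_hi_control = mk + qk * sqrt(vk / nk),
    mean_diff = md, t = tt, df = df, p = p,
    sig_unadjusted = p < alpha,
    sig_bonferroni = p < alpha / m)
  attr(out, "summary") <- list(max_abs_diff_mm = unname(max(abs(md))),
                               at_centile = unname(which.max(abs(md))),
                               test = if (paired) "paired-t" else "welch-t")
  class(out) <- c("cc_centile_comparison", "data.frame")
  out
}

#' One-way ANOVA of factor scores between groups
#'
#' For each retained factor: `F = MS_between / MS_within` with 1 and n-2
#' degrees of freedom for the two-group design, the p-value, the critical F
#' at `1 - alpha`, and the group score means. For two groups F equals the
#' square of the pooled-variance t statistic.
#'
#' @param scores subjects x k factor score matrix.
#' @param group case/control factor.
#' @param alpha significance level (the critical value is the upper-alpha
#'   F quantile at the realized degrees of freedom).
#' @return Data frame: factor, F, df1, df2, p, critical_F, mean_case,
#'   mean_control, significant.
#' @export
anova_factor_scores <- function(scores, group, alpha = 0.05) {
  S <- as.matrix(scores)
  group <- factor(as.character(group))
  lev <- levels(group)
  if (length(lev) != 2L) cc_stop("bad-groups", "exactly two groups required")
  n1 <- sum(group == lev[1L]); n2 <- sum(group == lev[2L])
  if (n1 < 2L || n2 < 2L) cc_stop("too-few", "each group needs n >= 2")
  n <- n1 + n2
  m1 <- colMeans(S[group == lev[1L], , drop = FALSE])
  m2 <- colMeans(S[group == lev[2L], , drop = FALSE])
  gm <- colMeans(S)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((S[group == lev[1L], , drop = FALSE] -
                    matrix(m1, n1, ncol(S), byrow = TRUE))^2) +
         colSums((S[group == lev[2L], , drop = FALSE] -
                    matrix(m2, n2, ncol(S), byrow = TRUE))^2)
  msw <- ssw / (n - 2)
  if (any(msw == 0))
    cc_warn("zero-variance", "zero within-group variance; F reported as Inf")
  F <- ifelse(msw == 0, Inf, ssb / msw)
  p <- ifelse(is.infinite(F), 0, stats::pf(F, 1, n - 2, lower.tail = FALSE))
  p[F == 0 & ssb == 0] <- 1
  data.frame(factor = colnames(S) %||% paste0("factor", seq_len(ncol(S))),
             F = F, df1 = 1L, df2 = n - 2L, p = p,
             critical_F = stats::qf(1 - alpha, 1, n - 2),
             mean_case = if ("case" %in% lev) m1[] else m2[],
             mean_control = if ("case" %in% lev) m2[] else m1[],
             significant = p < alpha,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
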