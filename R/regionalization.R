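#' Principal component analysis of the centile widths
#'
#' PCA of the column-standardized width matrix, i.e. an eigendecomposition
#' of the 99 x 99 correlation matrix. Working on correlations rather than
#' covariances keeps the components from being dominated by the absolute
#' variance of the thick splenium and genu, matching the interpretation of
#' the factors as size-normalized regional shape; set `use_correlation =
#' FALSE` for covariance-matrix PCA.
#'
#' @param x a [cc_cohort()] or a subjects x 99 numeric matrix.
#' @param use_correlation standardize columns first (default).
#' @return List with `eigenvectors` (99 x 99), `eigenvalues`, and
#'   `explained_fraction` (`eigenvalues / 99`, summing to 1).
#' @export
cc_pca <- function(x, use_correlation = TRUE) {
  X <- if (inherits(x, "cc_cohort")) x$widths else as.matrix(x)
  if (nrow(X) < 3L) cc_stop("too-few", "PCA needs at least 3 subjects")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    cc_stop("constant-centile",
            paste("zero-variance centile(s):",
                  paste(which(sds == 0), collapse = ", ")))
  S <- if (use_correlation) stats::cor(X) else stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  list(eigenvectors = e$vectors, eigenvalues = vals,
       explained_fraction = vals / sum(diag(S)))
}

#' Number of components explaining more than the retention threshold
#'
#' @param explained_fraction non-increasing fractions of total variance.
#' @param threshold retention threshold (default 1% of total variance).
#' @return Integer count of components with fraction strictly above the
#'   threshold.
#' @export
retain_components <- function(explained_fraction, threshold = 0.01) {
  stopifnot(!is.unsorted(rev(explained_fraction)))
  k <- sum(explained_fraction > threshold)
  if (k == 0L) cc_stop("nothing-retained",
                       "no component explains more than the threshold")
  k
}

#' Varimax rotation of retained component loadings
#'
#' Orthogonal rotation maximizing the varimax criterion (variance of squared
#' normalized loadings per factor), so that each factor loads heavily on few
#' centiles ("simple structure"). Kaiser row normalization is on by default,
#' the convention in the callosal factor-analysis literature. Each rotated
#' column is sign-flipped so its largest-magnitude loading is positive.
#'
#' @param loadings 99 x k loading matrix (eigenvectors scaled by the square
#'   root of their eigenvalues).
#' @param kaiser use Kaiser row normalization.
#' @param eps relative convergence tolerance of the rotation.
#' @return List with `loadings` (rotated, sign-fixed) and `rotmat`.
#' @export
rotate_varimax <- function(loadings, kaiser = TRUE, eps = 1e-8) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k == 1L) return(list(loadings = fix_signs(L), rotmat = matrix(1, 1, 1)))
  v <- stats::varimax(L, normalize = kaiser, eps = eps)
  list(loadings = fix_signs(unclass(v$loadings)), rotmat = v$rotmat)
}

fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Assign each centile to the factor with the highest loading
#'
#' The assignment uses the largest absolute rotated loading, so that
#' anticorrelated tapering is not misassigned; exact ties go to the lower
#' factor index with a warning. Contiguity is reported, not enforced: the
#' maximal runs of consecutive centiles per factor are returned alongside.
#'
#' @param loadings rotated 99 x k loadings.
#' @return List with `region_of_centile` (integer 1..k per centile) and
#'   `runs` (data frame of maximal runs: region, start, end, length).
#' @export
assign_regions <- function(loadings) {
  L <- abs(as.matrix(loadings))
  reg <- integer(nrow(L))
  tied <- FALSE
  for (c in seq_len(nrow(L))) {
    m <- max(L[c, ])
    hits <- which(L[c, ] == m)
    if (length(hits) > 1L) tied <- TRUE
    reg[c] <- hits[1L]
  }
  if (tied) cc_warn("loading-tie",
                    "exact loading tie(s); assigned to the lower factor index")
  r <- rle(reg)
  runs <- data.frame(region = r$values,
                     start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
                     length = r$lengths)
  runs$end <- runs$start + runs$length - 1L
  list(region_of_centile = reg,
       runs = runs[, c("region", "start", "end", "length")])
}

#' Regression-method factor scores
#'
#' Scores are the standardized widths projected through the inverse
#' correlation matrix onto the rotated loadings (Thurstone regression
#' estimator). Each score column has exactly zero sample mean because the
#' standardized widths do. A near-singular correlation matrix (inevitable
#' when subjects are fewer than centiles) is ridge-stabilized with a 1e-8
#' diagonal, with a warning.
#'
#' @param x a [cc_cohort()] or subjects x 99 matrix (the same data the
#'   loadings came from).
#' @param loadings rotated 99 x k loadings.
#' @return Subjects x k score matrix.
#' @export
factor_scores <- function(x, loadings) {
  X <- if (inherits(x, "cc_cohort")) x$widths else as.matrix(x)
  Z <- scale(X)
  R <- stats::cor(X)
  if (rcond(R) < 1e-10) {
    cc_warn("singular-correlation",
            "correlation matrix is near-singular; using a ridge-stabilized inverse")
    R <- R + diag(1e-8, nrow(R))
  }
  S <- Z %*% solve(R, as.matrix(loadings))
  colnames(S) <- colnames(loadings)
  rownames(S) <- rownames(X)
  S
}

#' Regionalize a cohort of width profiles
#'
#' The full reduction chain: correlation-matrix PCA, retention of components
#' explaining more than `threshold` of total variance, varimax rotation,
#' centile-to-region assignment, end-taper flagging, and regression factor
#' scores. A factor is flagged `end_taper` when more than half of its
#' assigned centiles lie in the extreme tails (centiles 1-4 or 96-99); such
#' factors reflect the tapering tips rather than an anatomical region and
#' are excluded from group comparison by default downstream.
#'
#' @param cohort a [cc_cohort()] (or plain width matrix).
#' @param threshold retention threshold on the explained variance fraction.
#' @param kaiser Kaiser normalization during varimax.
#' @param use_correlation correlation-matrix (vs covariance-matrix) PCA.
#' @return An object of class `cc_regional_factors`: rotated `loadings`,
#'   `explained_fraction` of the retained components, `retained_k`,
#'   `region_of_centile`, contiguity `runs`, subject `scores`, `end_taper`
#'   flags, and the full `eigenvalues`.
#' @export
regionalize <- function(cohort, threshold = 0.01, kaiser = TRUE,
                        use_correlation = TRUE) {
  p <- cc_pca(cohort, use_correlation = use_correlation)
  k <- retain_components(p$explained_fraction, threshold)
  A <- p$eigenvectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(p$eigenvalues[seq_len(k)]), k)
  rot <- rotate_varimax(A, kaiser = kaiser)
  colnames(rot$loadings) <- paste0("factor", seq_len(k))
  asg <- assign_regions(rot$loadings)
  tail_cent <- c(1:4, 96:99)
  end_taper <- vapply(seq_len(k), function(j) {
    own <- which(asg$region_of_centile == j)
    length(own) > 0L && mean(own %in% tail_cent) > 0.5
  }, logical(1))
  scores <- factor_scores(cohort, rot$loadings)
  structure(list(loadings = rot$loadings,
                 explained_fraction = p$explained_fraction[seq_len(k)],
                 retained_k = k,
                 region_of_centile = asg$region_of_centile,
                 runs = asg$runs,
                 scores = scores,
                 end_taper = end_taper,
                 eigenvalues = p$eigenvalues),
            class = "cc_regional_factors")
}

#' @export
print.cc_regional_factors <- function(x, ...) {
  cat(sprintf("<cc_regional_factors> %d retained factor(s) (%.1f%% of variance)\n",
              x$retained_k, 100 * sum(x$explained_fraction)))
  for (j in seq_len(x$retained_k)) {
    own <- which(x$region_of_centile == j)
    cat(sprintf("  factor%d: %.1f%% variance, %s%s\n", j,
                100 * x$explained_fraction[j],
                if (length(own)) sprintf("centiles %d-%d (%d assigned)",
                                         min(own), max(own), length(own))
                else "no centiles assigned",
                if (x$end_taper[j]) " [end-taper]" else ""))
  }
  invisible(x)
}

#' Agreement between a centile partition and a reference partition
#'
#' Greedily matches factor labels to reference labels by maximal centile
#' overlap, then reports the fraction of the evaluated centiles whose
#' matched label agrees with the reference. Used to score recovery of the
#' generator's designed partition (the end-taper zones are excluded by
#' default). The score is invariant to label permutation.
#'
#' @param assignment integer per-centile factor labels (length 99).
#' @param reference integer per-centile reference labels (length 99).
#' @param centiles which centiles to evaluate; defaults to those with a
#'   positive reference label.
#' @return Fraction in `[0, 1]`.
#' @export
region_agreement <- function(assignment, reference,
                             centiles = which(reference > 0L)) {
  a <- assignment[centiles]; r <- reference[centiles]
  tab <- table(a, r)
  match_a <- character(0); match_r <- character(0); hit <- 0L
  while (nrow(tab) && ncol(tab) && max(tab) > 0L) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    hit <- hit + tab[ij[1L], ij[2L]]
    tab <- tab[-ij[1L], -ij[2L], drop = FALSE]
  }
  as.numeric(hit) / length(centiles)
}
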