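#' Default configuration for the synthetic cohort generator
#'
#' Encodes the study conditions the generator emulates: two age-matched
#' groups of 13 children, corpus-callosum-like width profiles with regional
#' between-subject covariance, and a focal thinning effect in the genu
#' (centiles 8-15) and the mid-posterior body (centiles 61-70) peaking at
#' 1.47 mm at centile 63. Noise magnitudes are the package's calibrated
#' defaults (see the methods vignette): wide enough that single centiles
#' rarely survive Bonferroni correction, narrow enough that the multivariate
#' profile remains separable.
#'
#' @param n_case,n_control group sizes.
#' @param baseline list of baseline width-curve parameters (mm): `genu`,
#'   `body`, `splenium` thicknesses, `end` taper thickness, bump centres and
#'   width, taper scale.
#' @param boundaries seven region boundaries (half-centile positions)
#'   delimiting the end-taper zone, the six anatomical regions, and the
#'   posterior end-taper zone.
#' @param overlap crossfade half-width (centiles) of the factor loading
#'   windows across region boundaries.
#' @param footprints fibre-bundle footprint windows: for the listed regions,
#'   the factor loading follows a raised-cosine bundle profile (`support`,
#'   `peak` in centiles) instead of a flat regional window. The defaults tie
#'   the genu factor to the anterior bundle (centiles 8-15, peak 11) and the
#'   mid-posterior-body factor to the paracentral commissural bundle
#'   (centiles 61-70, peak 63) — between-subject variability of a bundle has
#'   the same spatial footprint as its injury-related thinning.
#' @param footprint_floor loading floor of footprint windows across their
#'   zone, keeping every centile covered by between-subject variance.
#' @param bundle_cor correlation between the amplitudes of the two bundle
#'   footprint factors (anterior vs paracentral). The negative default
#'   encodes a between-subject allocation trade-off: at a given overall
#'   callosal size, children with a relatively thick genu bundle tend to
#'   have a relatively thin paracentral bundle. This is the covariance
#'   structure under which single-centile comparisons stay inconclusive
#'   (high marginal variance) while the joint width profile remains highly
#'   separable, the combination the emulated study reports.
#' @param regional_sd between-subject sd (mm) of the six regional factors.
#' @param end_factor_sd between-subject sd (mm) of the end-taper factor.
#' @param global_scale_sd sd of the log of the per-subject global scale.
#' @param noise_sd independent per-centile noise sd (mm).
#' @param effect list of focal thinning components, each
#'   `list(range = c(lo, hi), peak = mm, at = centile)`.
#' @param effect_jitter relative between-subject sd of the effect magnitude.
#' @param age_range case age range (years), sampled uniformly; controls copy
#'   their matched case's age within +/- 0.5 year.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `cc_generator_config`.
#' @export
generator_config <- function(n_case = 13L, n_control = 13L,
                             baseline = list(genu = 11, body = 6, splenium = 10,
                                             end = 2, genu_center = 0.1,
                                             splenium_center = 0.9,
                                             bump_sd = 0.085, taper_tau = 0.04),
                             boundaries = c(4.5, 16.5, 37.5, 60.5, 70.5, 83.5, 95.5),
                             overlap = 2,
                             footprints = list(
                               list(region = 1L, support = c(8L, 15L), peak = 11L),
                               list(region = 4L, support = c(61L, 70L), peak = 63L)),
                             footprint_floor = 0.35,
                             bundle_cor = -0.98,
                             regional_sd = 1.1,
                             end_factor_sd = 0.6,
                             global_scale_sd = 0.01,
                             noise_sd = 0.15,
                             effect = list(
                               list(range = c(8L, 15L), peak = 1.45, at = 11L),
                               list(range = c(61L, 70L), peak = 1.47, at = 63L)),
                             effect_jitter = 0.2,
                             age_range = c(1, 15),
                             seed = NULL) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              baseline = baseline, boundaries = boundaries, overlap = overlap,
              footprints = footprints, footprint_floor = footprint_floor,
              bundle_cor = bundle_cor,
              regional_sd = regional_sd, end_factor_sd = end_factor_sd,
              global_scale_sd = global_scale_sd, noise_sd = noise_sd,
              effect = effect, effect_jitter = effect_jitter,
              age_range = age_range, seed = seed)
  if (cfg$n_case < 2L || cfg$n_control < 2L)
    cc_stop("bad-config", "need at least 2 subjects per group")
  if (any(c(regional_sd, end_factor_sd, global_scale_sd, noise_sd) < 0))
    cc_stop("bad-config", "all sd parameters must be non-negative")
  if (length(boundaries) != 7L || is.unsorted(boundaries))
    cc_stop("bad-config", "boundaries must be 7 increasing positions")
  for (e in cfg$effect)
    if (e$range[1L] < 1L || e$range[2L] > 99L)
      cc_stop("bad-config", "effect ranges must lie within centiles 1..99")
  class(cfg) <- "cc_generator_config"
  cfg
}

#' Baseline corpus callosum width curve
#'
#' Smooth positive template of callosal thickness along the normalized axis:
#' a thick genu plateau near the anterior end, a thin mid-body, a thick
#' splenium, and short tapers at both tips. The shape is a qualitative
#' stand-in for a typical paediatric mid-sagittal profile; all parameters
#' are exposed through [generator_config()].
#'
#' @param t position(s) along the axis in `[0, 1]` (0 = anterior tip).
#' @param baseline parameter list, as in [generator_config()].
#' @return Width(s) in mm.
#' @examples
#' baseline_width_curve(0.5)   # mid-body thickness, 6 mm by default
#' @export
baseline_width_curve <- function(t, baseline = generator_config()$baseline) {
  stopifnot(all(t >= 0 & t <= 1))
  b <- baseline
  core <- b$body +
    (b$genu - b$body) * exp(-(t - b$genu_center)^2 / (2 * b$bump_sd^2)) +
    (b$splenium - b$body) * exp(-(t - b$splenium_center)^2 / (2 * b$bump_sd^2))
  ramp <- tanh(t / b$taper_tau) * tanh((1 - t) / b$taper_tau)
  b$end + (core - b$end) * ramp
}

#' Expected case-minus-control width difference profile
#'
#' Evaluates the configured focal thinning as a 99-vector of expected mean
#' width differences (mm): raised-cosine dips over each configured centile
#' range, peaking (in magnitude) at the configured peak centile, zero
#' elsewhere. Negative values mean the case group is thinner.
#'
#' @param config a [generator_config()].
#' @return Numeric length-99 `delta`, case minus control, in mm.
#' @examples
#' d <- effect_profile(generator_config())
#' which.max(abs(d))   # 63
#' max(abs(d))         # 1.47
#' @export
effect_profile <- function(config = generator_config()) {
  delta <- numeric(99L)
  for (e in config$effect) {
    lo <- e$range[1L]; hi <- e$range[2L]; at <- e$at
    if (at < lo || at > hi)
      cc_stop("bad-effect", "peak centile must lie inside its range")
    cc <- lo:hi
    up <- cc <= at
    val <- numeric(length(cc))
    val[up] <- if (at == lo) 1 else
      0.5 * (1 - cos(pi * (cc[up] - lo) / (at - lo)))
    val[!up] <- if (at == hi) 1 else
      0.5 * (1 - cos(pi * (hi - cc[!up]) / (hi - at)))
    delta[cc] <- delta[cc] - e$peak * val
  }
  delta
}

## Factor loading windows: a 99 x 7 matrix whose columns are the six regional
## windows plus the end-taper window. Regions without a bundle footprint
## (and the end zones) use flat windows that crossfade as cos/sin over
## `overlap` centiles around each boundary (squared loadings sum to 1 there,
## keeping between-subject variance uniform). Footprint regions instead
## carry a raised-cosine bundle profile over the configured support, floored
## at `footprint_floor` so the whole zone stays covered by between-subject
## variance.
factor_windows <- function(config = generator_config()) {
  b <- config$boundaries; o <- config$overlap
  fp_regions <- vapply(config$footprints, `[[`, integer(1), "region")
  cent <- 1:99
  # zone index per centile: 0 = anterior end, 1..6 regions, 7 = posterior end
  zone <- findInterval(cent, b)
  L <- matrix(0, 99L, 7L)
  colf <- function(z) if (z == 0L || z == 7L) 7L else z   # factor column of a zone
  for (c in cent) {
    z <- zone[c]
    db <- c - b                                  # signed distance to boundaries
    nearest <- which.min(abs(db))
    if (abs(db[nearest]) < o) {
      s <- (db[nearest] + o) / (2 * o)           # 0 before boundary, 1 after
      z_lo <- nearest - 1L; z_hi <- nearest      # zones on each side
      if (!(colf(z_lo) %in% fp_regions))
        L[c, colf(z_lo)] <- L[c, colf(z_lo)] + cos(pi / 2 * s)
      if (!(colf(z_hi) %in% fp_regions))
        L[c, colf(z_hi)] <- L[c, colf(z_hi)] + sin(pi / 2 * s)
    } else if (!(z %in% fp_regions)) {
      L[c, colf(z)] <- 1
    }
  }
  for (fp in config$footprints) {
    r <- fp$region
    zlo <- ceiling(b[r]); zhi <- floor(b[r + 1L])         # region zone
    lo <- fp$support[1L]; hi <- fp$support[2L]; pk <- fp$peak
    cc <- zlo:zhi
    w <- numeric(length(cc))
    inb <- cc >= lo & cc <= hi
    up <- inb & cc <= pk
    dn <- inb & cc > pk
    w[up] <- if (pk == lo) 1 else
      0.5 * (1 - cos(pi * (cc[up] - lo + 1) / (pk - lo + 1)))
    w[dn] <- if (pk == hi) 1 else
      0.5 * (1 - cos(pi * (hi + 1 - cc[dn]) / (hi + 1 - pk)))
    L[cc, r] <- pmax(w, config$footprint_floor)
  }
  colnames(L) <- c(paste0("region", 1:6), "end_taper")
  L
}

#' Designed region partition of the synthetic generator
#'
#' The partition a perfect regionalization would recover: each centile is
#' assigned to the designed factor with the largest loading window value
#' (0 for the end-taper zones).
#'
#' @param config a [generator_config()].
#' @return Integer length-99 vector: 1..6 for the six designed regions, 0 for
#'   the anterior/posterior end-taper zones.
#' @export
designed_partition <- function(config = generator_config()) {
  z <- apply(factor_windows(config), 1L, which.max)
  z[z == 7L] <- 0L
  z
}

#' Generate a synthetic width-profile cohort
#'
#' Each subject's profile is `scale * (baseline + sum_r a_r * L_r) + noise`,
#' where `scale` is a per-subject lognormal global size factor, `a_r` are
#' normal regional factor amplitudes with smooth loading windows `L_r`
#' ([factor_windows()]), and the noise is independent per centile. Case
#' subjects additionally receive the focal thinning [effect_profile()],
#' scaled per subject by `1 + jitter` to emulate biological heterogeneity of
#' the injury. Widths are floored at 0.5 mm (with a warning; an error if
#' more than 5% of values are clipped). Ages are sampled for cases and
#' mirrored to the matched controls within half a year.
#'
#' @param config a [generator_config()]; `config$seed` makes the cohort
#'   fully reproducible.
#' @return A [cc_cohort()] (cases first, then controls).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "cc_generator_config"))
  with_seed(config$seed, {
    nc <- config$n_case; nk <- config$n_control
    n <- nc + nk
    t99 <- (1:99) / 100
    base <- baseline_width_curve(t99, config$baseline)
    L <- factor_windows(config)
    sds <- c(rep(config$regional_sd, 6L), config$end_factor_sd)
    Ca <- diag(7)
    fp <- vapply(config$footprints, `[[`, integer(1), "region")
    if (length(fp) == 2L && !is.null(config$bundle_cor))
      Ca[fp[1L], fp[2L]] <- Ca[fp[2L], fp[1L]] <- config$bundle_cor
    a <- matrix(stats::rnorm(n * 7L), n, 7L) %*% chol(Ca) %*% diag(sds)
    sc <- exp(stats::rnorm(n, 0, config$global_scale_sd))
    eps <- matrix(stats::rnorm(n * 99L, 0, config$noise_sd), n, 99L)
    w <- sc * (matrix(base, n, 99L, byrow = TRUE) + a %*% t(L)) + eps
    delta <- effect_profile(config)
    jit <- 1 + stats::rnorm(nc, 0, config$effect_jitter)
    w[seq_len(nc), ] <- w[seq_len(nc), ] + outer(jit, delta)
    clipped <- w < 0.5
    if (mean(clipped) > 0.05)
      cc_stop("noise-too-large",
              sprintf("%.1f%% of widths below the 0.5 mm floor", 100 * mean(clipped)))
    if (any(clipped)) {
      w[clipped] <- 0.5
      cc_warn("widths-clipped",
              sprintf("%d width value(s) clipped at 0.5 mm", sum(clipped)))
    }
    age_case <- stats::runif(nc, config$age_range[1L], config$age_range[2L])
    if (nc == nk) {
      age_ctrl <- age_case + stats::runif(nk, -0.5, 0.5)
      pairing <- c(seq_len(nc), seq_len(nk))
    } else {
      age_ctrl <- stats::runif(nk, config$age_range[1L], config$age_range[2L])
      pairing <- NULL
    }
    cc_cohort(w, rep(c("case", "control"), c(nc, nk)),
              age = c(age_case, age_ctrl), pairing = pairing,
              subject_id = c(sprintf("case%02d", seq_len(nc)),
                             sprintf("ctrl%02d", seq_len(nk))),
              config = config)
  })
}

#' Render a width profile as a mid-sagittal mask
#'
#' Sweeps the 99-centile width profile perpendicular to a corpus-callosum
#' like arch (a circular arc opening downward) and rasterizes the swept
#' region: a pixel is foreground when its radial distance from the arch
#' falls within half the locally interpolated width. Widths taper linearly
#' to zero over the outermost centile at each tip, closing the shape. With
#' `radius_mm = Inf` the arch degenerates to a straight axis of length
#' `length_mm`.
#'
#' @param widths numeric length-99, widths in mm at centiles 1..99.
#' @param spacing pixel size in mm (isotropic); values above 0.5 mm degrade
#'   the geometric fidelity of re-extraction.
#' @param radius_mm arch radius (mm); `Inf` for a straight axis.
#' @param span_deg angular span of the arch in degrees.
#' @param length_mm axis length, used only when `radius_mm = Inf`.
#' @param pad_mm background margin around the shape.
#' @param tip_taper_deg half-angle of the wedge that closes each tip: the
#'   local half-width is additionally capped by `tan(tip_taper_deg)` times
#'   the arc distance to the nearer tip, so the shape comes to a point at
#'   the axis endpoints. The default 75 degrees confines the taper to well
#'   under the first/last centile for callosum-like profiles.
#' @return A [cc_mask()].
#' @export
render_mask <- function(widths, spacing = 0.25, radius_mm = 30,
                        span_deg = 150, length_mm = NULL, pad_mm = 2,
                        tip_taper_deg = 75) {
  stopifnot(length(widths) == 99L, all(widths > 0))
  if (spacing > 0.5)
    cc_warn("coarse-spacing", "spacing above 0.5 mm; widths will be inaccurate")
  if (is.finite(radius_mm) && any(widths >= 2 * radius_mm))
    cc_stop("sweep-fold",
            "width exceeds twice the arch radius of curvature; sweep folds over")
  if (!is.finite(radius_mm) && is.null(length_mm))
    cc_stop("bad-config", "length_mm is required for a straight axis")
  wfun0 <- stats::approxfun(c(0, (1:99) / 100, 1),
                            c(widths[1L], widths, widths[99L]), rule = 2)
  slope <- tan(tip_taper_deg * pi / 180)
  axis_len <- if (is.finite(radius_mm)) radius_mm * span_deg * pi / 180
              else length_mm
  wfun <- function(t) {
    s_tip <- pmin(t, 1 - t) * axis_len          # arc distance to nearer tip
    pmin(wfun0(t), 2 * slope * pmax(s_tip, 0))
  }
  wmax <- max(widths)
  if (is.finite(radius_mm)) {
    phi1 <- (90 + span_deg / 2) * pi / 180
    phi2 <- (90 - span_deg / 2) * pi / 180
    xr <- range(radius_mm * cos(c(phi1, phi2)), radius_mm * cos(pi / 2))
    yr <- range(radius_mm * sin(c(phi1, phi2)), radius_mm)
    xr <- xr + c(-1, 1) * (wmax / 2 + pad_mm)
    yr <- yr + c(-1, 1) * (wmax / 2 + pad_mm)
    C <- ceiling(diff(xr) / spacing); R <- ceiling(diff(yr) / spacing)
    xw <- xr[1L] + (seq_len(C) - 0.5) * spacing
    yw <- yr[1L] + (R - seq_len(R) + 0.5) * spacing      # row 1 = top
    X <- matrix(xw, R, C, byrow = TRUE)
    Y <- matrix(yw, R, C)
    rho <- sqrt(X^2 + Y^2)
    phi <- atan2(Y, X)
    tt <- (phi1 - phi) / (phi1 - phi2)
    inside <- tt >= 0 & tt <= 1 & abs(rho - radius_mm) <= wfun(pmin(pmax(tt, 0), 1)) / 2
  } else {
    if (is.null(length_mm))
      cc_stop("bad-config", "length_mm is required for a straight axis")
    xr <- c(-pad_mm, length_mm + pad_mm)
    yr <- c(-1, 1) * (wmax / 2 + pad_mm)
    C <- ceiling(diff(xr) / spacing); R <- ceiling(diff(yr) / spacing)
    xw <- xr[1L] + (seq_len(C) - 0.5) * spacing
    yw <- yr[1L] + (R - seq_len(R) + 0.5) * spacing
    X <- matrix(xw, R, C, byrow = TRUE)
    Y <- matrix(yw, R, C)
    tt <- X / length_mm
    inside <- tt >= 0 & tt <= 1 & abs(Y) <= wfun(pmin(pmax(tt, 0), 1)) / 2
  }
  cc_mask(inside, spacing)
}
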