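#' @keywords internal
"_PACKAGE"

## Classed error conditions: every documented failure mode has a stable code
## (e.g. "empty-mask") surfaced as condition class "ccmorph_empty_mask".
cc_stop <- function(code, msg, call. = FALSE) {
  cls <- paste0("ccmorph_", gsub("-", "_", code, fixed = TRUE))
  stop(errorCondition(paste0("[", code, "] ", msg), class = c(cls, "ccmorph_error")))
}

cc_warn <- function(code, msg) {
  cls <- paste0("ccmorph_", gsub("-", "_", code, fixed = TRUE))
  warning(warningCondition(paste0("[", code, "] ", msg),
                           class = c(cls, "ccmorph_warning")))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG stream afterwards. All stochastic entry points funnel
## through this so that a run is reproducible from its seed alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## ---- polygon / polyline primitives ----------------------------------------

## Signed area of a closed polygon (shoelace). Positive = counter-clockwise.
polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

## Perimeter of a closed polygon / length of an open polyline.
polyline_length <- function(p, closed = FALSE) {
  if (closed) p <- rbind(p, p[1L, , drop = FALSE])
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

## Cumulative arc length along a polyline, starting at 0.
arc_length <- function(p) {
  d <- diff(p)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

## Resample an open polyline at arc-length fractions `fr` (in [0,1]).
## Returns a length(fr) x 2 matrix. Duplicate vertices are dropped first so
## the arc-length parameterization is strictly increasing.
resample_polyline <- function(p, fr) {
  s <- arc_length(p)
  keep <- c(TRUE, diff(s) > 0)
  p <- p[keep, , drop = FALSE]
  s <- s[keep]
  total <- s[length(s)]
  at <- fr * total
  cbind(stats::approx(s, p[, 1L], xout = at)$y,
        stats::approx(s, p[, 2L], xout = at)$y)
}

## Intersections of the infinite line {p + t*u} (u unit vector) with an open
## polyline. Returns the signed offsets t of all crossings, ordered as found.
line_polyline_intersections <- function(p, u, poly) {
  w <- c(-u[2L], u[1L])                       # normal to the slice line
  rel_x <- poly[, 1L] - p[1L]
  rel_y <- poly[, 2L] - p[2L]
  cs <- rel_x * w[1L] + rel_y * w[2L]         # signed distance from the line
  n <- length(cs)
  a <- cs[-n]; b <- cs[-1L]
  hit <- (a <= 0 & b > 0) | (a >= 0 & b < 0) | (a == 0 & b == 0)
  hit[a == 0 & b == 0] <- FALSE               # degenerate co-linear segment
  idx <- which(hit)
  if (!length(idx)) return(numeric(0))
  al <- a[idx] / (a[idx] - b[idx])
  px <- rel_x[idx] + al * (rel_x[idx + 1L] - rel_x[idx])
  py <- rel_y[idx] + al * (rel_y[idx + 1L] - rel_y[idx])
  px * u[1L] + py * u[2L]
}
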