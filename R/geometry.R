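#' Locate the anterior and posterior tips of the callosal contour
#'
#' By default the two tips are found from the shape's morphological skeleton:
#' the contour points hit by extending the two ends of the skeleton's longest
#' geodesic path. The anterior tip is the endpoint with the smaller x
#' (image left, genu side). A manual `hint` overrides the automatic search,
#' which is the escape hatch for shapes whose skeleton is ambiguous.
#'
#' @param contour a [extract_contour()] result.
#' @param hint optional 2 x 2 matrix (or list of two length-2 vectors) of
#'   approximate tip coordinates in mm; the nearest contour vertices are used.
#' @param mask the originating [cc_mask()]; if omitted, the contour polygon
#'   is rasterized at its own spacing to recover a grid for skeletonization.
#' @return List with integer vertex indices `anterior` and `posterior`.
#' @export
find_endpoints <- function(contour, hint = NULL, mask = NULL) {
  stopifnot(inherits(contour, "cc_contour"))
  pts <- contour$points
  if (!is.null(hint)) {
    if (is.list(hint)) hint <- do.call(rbind, hint)
    hint <- matrix(as.numeric(hint), ncol = 2L)
    stopifnot(nrow(hint) == 2L)
    i1 <- nearest_vertex(pts, hint[1L, ])
    i2 <- nearest_vertex(pts, hint[2L, ])
    if (i1 == i2) cc_stop("degenerate-cut", "hinted endpoints coincide")
    ends <- c(i1, i2)
  } else {
    grid <- if (!is.null(mask)) mask$grid else
      rasterize_polygon(pts, contour$spacing)$grid
    sk <- skeletonize(grid)
    lp <- skeleton_longest_path(sk, contour$spacing)
    area <- abs(polygon_signed_area(pts))
    if (lp$length^2 < 2.5 * area)
      cc_stop("no-elongation",
              "shape has no clear long axis; supply endpoint hints")
    ends <- c(project_terminal(lp$points, forward = FALSE, pts, grid,
                               contour$spacing),
              project_terminal(lp$points, forward = TRUE, pts, grid,
                               contour$spacing))
    if (ends[1L] == ends[2L])
      cc_stop("no-elongation", "skeleton endpoints project to a single vertex")
  }
  ant <- ends[order(pts[ends, 1L])]
  list(anterior = ant[1L], posterior = ant[2L])
}

nearest_vertex <- function(pts, p) {
  which.min((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2)
}

## Continue the medial axis beyond the skeleton and return the contour vertex
## nearest to where the continuation exits the shape. The skeleton's longest
## path is unreliable over roughly the last half-width (it bends into corner
## spurs at blunt or curved tips), so a circle is fitted to a generous end
## window of the path, excluding its last couple of millimetres, and the
## axis is marched along that circle (or straight line, when the window is
## near-collinear) until it leaves the mask.
project_terminal <- function(path, forward, contour_pts, grid, spacing,
                             skip_mm = 2.5) {
  if (!forward) path <- path[nrow(path):1L, , drop = FALSE]
  s <- arc_length(path)
  total <- s[length(s)]
  skip <- min(skip_mm, total / 5)
  win <- min(max(12, 0.3 * total), 0.45 * total)
  sel <- s >= total - skip - win & s <= total - skip
  if (sum(sel) < 3L) { sel <- s >= total / 2 ; skip <- 0 }
  w <- path[sel, , drop = FALSE]
  start <- w[nrow(w), ]
  fit <- fit_circle(w)
  step <- min(spacing) / 2
  inside <- function(p) {
    R <- nrow(grid)
    r <- round(R - p[2L] / spacing[1L] + 0.5)
    c <- round(p[1L] / spacing[2L] + 0.5)
    r >= 1L && r <= R && c >= 1L && c <= ncol(grid) && grid[r, c]
  }
  max_travel <- 0.6 * total
  if (is.null(fit)) {                         # straight continuation
    u <- start - w[1L, ]
    u <- u / sqrt(sum(u^2))
    move <- function(d) start + d * u
  } else {
    v0 <- start - fit$centre
    th0 <- atan2(v0[2L], v0[1L])
    dirv <- start - w[max(1L, nrow(w) - 3L), ]
    sgn <- sign(v0[1L] * dirv[2L] - v0[2L] * dirv[1L])
    if (sgn == 0) sgn <- 1
    move <- function(d) fit$centre + fit$r *
      c(cos(th0 + sgn * d / fit$r), sin(th0 + sgn * d / fit$r))
  }
  last_in <- start
  d <- 0
  while (d < max_travel) {
    d <- d + step
    p <- move(d)
    if (!inside(p)) break
    last_in <- p
  }
  nearest_vertex(contour_pts, last_in)
}

## Algebraic (Kasa) circle fit; NULL when the points are nearly collinear,
## degenerate, or the radius is implausibly large relative to the span.
fit_circle <- function(p) {
  A <- cbind(2 * p[, 1L], 2 * p[, 2L], 1)
  b <- p[, 1L]^2 + p[, 2L]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  r <- sqrt(r2)
  span <- max(dist(rbind(p[1L, ], p[nrow(p), ])))
  if (r > 20 * max(span, 1)) return(NULL)
  list(centre = sol[1:2], r = r)
}

#' Split a closed contour into dorsal and ventral arcs
#'
#' Cuts the contour at the two tips into two open polylines sharing their
#' endpoints. The arc with the higher mean y (upper in anatomical
#' orientation) is labelled dorsal; both are oriented anterior to posterior.
#' The labelling and orientation are independent of the winding direction of
#' the input contour.
#'
#' @param contour a [extract_contour()] result.
#' @param endpoints a [find_endpoints()] result.
#' @return An object of class `cc_arcs`: list with `dorsal`, `ventral`
#'   (polyline matrices, mm), `anterior` and `posterior` tip coordinates.
#' @export
split_arcs <- function(contour, endpoints) {
  stopifnot(inherits(contour, "cc_contour"))
  pts <- contour$points
  n <- nrow(pts)
  i <- endpoints$anterior; j <- endpoints$posterior
  stopifnot(i >= 1L, i <= n, j >= 1L, j <= n)
  if (i == j || abs(i - j) == 1L || abs(i - j) == n - 1L)
    cc_stop("degenerate-cut", "endpoints identical or adjacent on the contour")
  fwd <- if (i < j) i:j else c(i:n, 1L:j)                  # follow vertex order
  bwd <- if (i < j) c(i:1L, n:j) else i:j                  # against vertex order
  a1 <- pts[fwd, , drop = FALSE]                           # both anterior -> posterior
  a2 <- pts[bwd, , drop = FALSE]
  m1 <- mean(a1[-c(1L, nrow(a1)), 2L])
  m2 <- mean(a2[-c(1L, nrow(a2)), 2L])
  dorsal <- if (m1 >= m2) a1 else a2
  ventral <- if (m1 >= m2) a2 else a1
  structure(list(dorsal = dorsal, ventral = ventral,
                 anterior = pts[i, ], posterior = pts[j, ],
                 spacing = contour$spacing),
            class = "cc_arcs")
}

#' Fit the 99 centile widths by iterative percentile-slice relaxation
#'
#' Divides the corpus callosum into `n_segments` radial segments by placing
#' `n_segments - 1` percentile slices along its axis. The centreline is
#' initialized as the pointwise mean of the dorsal and ventral arcs resampled
#' at matched arc-length fractions, then relaxed to a fixed point: at each
#' interior equal-arc-length fraction the slice is the line normal to the
#' local centreline tangent, the width is the distance between its nearest
#' intersections with the two arcs, and the centreline interior points are
#' replaced by the slice midpoints (tips held fixed) until the maximum
#' midpoint displacement falls below `tol_mm`.
#'
#' @param arcs a [split_arcs()] result.
#' @param n_segments number of radial segments (99 slices when 100).
#' @param tol_mm convergence tolerance on the maximum midpoint displacement.
#' @param max_iter iteration cap; non-convergence is reported via the
#'   `convergence` field and a warning, not an error.
#' @param contour optional originating contour; supplies area and perimeter.
#' @return List with `profile` (class `cc_width_profile`: `widths` in mm
#'   anterior to posterior, `area`, `perimeter`, `centreline_length`,
#'   `n_segments`, `convergence`, `slices`) and `centreline` (points plus
#'   cumulative `arc_length`).
#' @export
fit_centile_widths <- function(arcs, n_segments = 100L, tol_mm = 0.01,
                               max_iter = 100L, contour = NULL,
                               damping = 0.5) {
  stopifnot(inherits(arcs, "cc_arcs"), n_segments >= 2L)
  n <- as.integer(n_segments)
  fr <- (0:n) / n
  interior <- 2:n                                # row indices of interior points
  d0 <- resample_polyline(arcs$dorsal, fr)
  v0 <- resample_polyline(arcs$ventral, fr)
  centre <- (d0 + v0) / 2
  centre[1L, ] <- arcs$anterior
  centre[n + 1L, ] <- arcs$posterior

  # displacements below a fraction of a pixel are rasterization noise, not a
  # meaningful centreline change; the effective tolerance is floored there
  eff_tol <- if (!is.null(arcs$spacing))
    max(tol_mm, 0.2 * min(arcs$spacing)) else tol_mm
  widths <- numeric(n - 1L)
  sd_pts <- matrix(NA_real_, n - 1L, 2L)
  sv_pts <- matrix(NA_real_, n - 1L, 2L)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  best <- list(disp = Inf)
  while (iter < max_iter) {
    iter <- iter + 1L
    pts <- resample_polyline(centre, fr)
    pts[1L, ] <- arcs$anterior; pts[n + 1L, ] <- arcs$posterior
    tang <- chain_tangents(pts)
    mids <- matrix(0, n - 1L, 2L)
    missed <- integer(0)
    for (k in seq_len(n - 1L)) {
      p <- pts[k + 1L, ]
      tg <- tang[k, ]
      u <- c(-tg[2L], tg[1L])
      u <- u / sqrt(sum(u^2))
      # orient the normal toward the dorsal arc so that the dorsal crossing
      # is sought at positive offsets and the ventral at negative offsets;
      # this pins each slice to opposite boundary branches near the tips
      if (sum(u * (d0[k + 1L, ] - v0[k + 1L, ])) < 0) u <- -u
      td <- pick_nearest(line_polyline_intersections(p, u, arcs$dorsal),
                         p, u, sd_pts[k, ], side = 1)
      tv <- pick_nearest(line_polyline_intersections(p, u, arcs$ventral),
                         p, u, sv_pts[k, ], side = -1)
      if (is.na(td) || is.na(tv)) {
        # transient miss while the centreline is still settling: leave the
        # station in place this round; fatal only if it persists (below)
        missed <- c(missed, k)
        mids[k, ] <- p
        next
      }
      sd_pts[k, ] <- p + td * u
      sv_pts[k, ] <- p + tv * u
      widths[k] <- abs(td - tv)
      mids[k, ] <- p + (td + tv) / 2 * u
    }
    # damped update: full midpoint steps overshoot and can lock into a
    # period-2 oscillation near strongly curved tips
    mids <- pts[interior, , drop = FALSE] +
      damping * (mids - pts[interior, , drop = FALSE])
    mids <- repair_backtracking(arcs$anterior, mids, arcs$posterior)
    mids <- smooth_chain(arcs$anterior, mids, arcs$posterior)
    disp <- max(sqrt(rowSums((mids - pts[interior, , drop = FALSE])^2)))
    history <- c(history, disp)
    centre <- rbind(arcs$anterior, mids, arcs$posterior)
    if (disp < best$disp) {
      best <- list(disp = disp, widths = widths, sd = sd_pts, sv = sv_pts,
                   centre = centre, iter = iter, missed = missed)
    }
    if (disp < eff_tol) {
      if (length(missed))
        cc_stop("slice-miss",
                sprintf("slice(s) %s never intersect both arcs (re-entrant shape?)",
                        paste(missed, collapse = ", ")))
      converged <- TRUE
      break
    }
    if (iter - best$iter >= 12L) break      # stagnated: keep the best iterate
  }
  if (!converged) {
    widths <- best$widths; sd_pts <- best$sd; sv_pts <- best$sv
    centre <- best$centre
    if (length(best$missed))
      cc_stop("slice-miss",
              sprintf("slice(s) %s never intersect both arcs (re-entrant shape?)",
                      paste(best$missed, collapse = ", ")))
    cc_warn("no-convergence",
            sprintf("midpoint relaxation did not reach tol %.3g mm (best disp %.4g mm at iteration %d)",
                    eff_tol, best$disp, best$iter))
  }

  if (is.null(contour)) {
    closed <- rbind(arcs$dorsal, arcs$ventral[(nrow(arcs$ventral) - 1L):2L, ,
                                              drop = FALSE])
    area <- abs(polygon_signed_area(closed))
    perim <- polyline_length(closed, closed = TRUE)
  } else {
    s <- shape_summary(contour)
    area <- s$area_mm2; perim <- s$perimeter_mm
  }
  profile <- structure(
    list(widths = widths, area = area, perimeter = perim,
         centreline_length = polyline_length(centre),
         n_segments = n,
         convergence = list(iterations = iter,
                            final_displacement_mm = if (converged)
                              history[length(history)] else best$disp,
                            converged = converged, history = history),
         slices = list(dorsal = sd_pts, ventral = sv_pts)),
    class = "cc_width_profile")
  stopifnot(length(profile$widths) == n - 1L, all(profile$widths > 0))
  list(profile = profile,
       centreline = list(points = centre, arc_length = arc_length(centre)))
}

## Keep the midpoint chain simple: a valid centreline progresses monotonically
## from tip to tip, so any vertex where consecutive segments reverse direction
## (negative dot product) is a relaxation artefact; it is replaced by its
## neighbours' mean until no reversals remain. Genuine callosal curvature
## turns a few degrees per slice and is untouched by this repair.
repair_backtracking <- function(tip_a, mids, tip_p, max_sweeps = 25L) {
  for (s in seq_len(max_sweeps)) {
    chain <- rbind(tip_a, mids, tip_p)
    seg <- diff(chain)
    n <- nrow(seg)
    dots <- rowSums(seg[-n, , drop = FALSE] * seg[-1L, , drop = FALSE])
    bad <- which(dots < 0)                  # vertex indices into mids
    if (!length(bad)) break
    for (k in bad) {
      lo <- if (k == 1L) tip_a else mids[k - 1L, ]
      hi <- if (k == nrow(mids)) tip_p else mids[k + 1L, ]
      mids[k, ] <- (lo + hi) / 2
    }
  }
  mids
}

## Tangent at each interior station from the principal direction of a local
## window of stations (half-width 4), sign-aligned with the chain direction.
## A two-point difference is far too noisy near blunt tips, where the slice
## midpoint amplifies tangent error by tan^2 of the tip wedge angle.
chain_tangents <- function(pts, halfw = 4L) {
  n <- nrow(pts)
  out <- matrix(0, n - 2L, 2L)
  for (k in 2:(n - 1L)) {
    lo <- max(1L, k - halfw); hi <- min(n, k + halfw)
    w <- pts[lo:hi, , drop = FALSE]
    w <- sweep(w, 2L, colMeans(w))
    v <- eigen(crossprod(w), symmetric = TRUE)$vectors[, 1L]
    ref <- pts[min(n, k + 1L), ] - pts[max(1L, k - 1L), ]
    if (sum(v * ref) < 0) v <- -v
    out[k - 1L, ] <- v
  }
  out
}

## One pass of 1/4-1/2-1/4 smoothing on the interior midpoints (tips fixed).
## Suppresses pixel-scale kinks that destabilize the tangent estimates; the
## induced bias for a smooth axis is of order (station spacing)^2 times the
## curvature, far below the rasterization scale.
smooth_chain <- function(tip_a, mids, tip_p) {
  chain <- rbind(tip_a, mids, tip_p)
  n <- nrow(chain)
  0.25 * chain[1:(n - 2L), , drop = FALSE] +
    0.50 * chain[2:(n - 1L), , drop = FALSE] +
    0.25 * chain[3:n, , drop = FALSE]
}

## Nearest intersection by unsigned offset, optionally restricted to one
## side of the station (`side` = sign of admissible offsets); near-ties
## (< 1 nm) broken toward the intersection closest to the previous
## iteration's slice endpoint.
pick_nearest <- function(ts, p, u, prev, side = 0) {
  if (side != 0) ts <- ts[sign(ts) == side]
  if (!length(ts)) return(NA_real_)
  a <- abs(ts)
  near <- which(a <= min(a) + 1e-9)
  if (length(near) > 1L && !any(is.na(prev))) {
    px <- p[1L] + ts[near] * u[1L]
    py <- p[2L] + ts[near] * u[2L]
    near <- near[which.min((px - prev[1L])^2 + (py - prev[2L])^2)]
  } else near <- near[1L]
  ts[near]
}

#' @export
print.cc_width_profile <- function(x, ...) {
  cat(sprintf(paste0("<cc_width_profile> %d widths (%.2f-%.2f mm), area %.1f mm^2,\n",
                     "  perimeter %.1f mm, centreline %.1f mm, %s in %d iteration(s)\n"),
              length(x$widths), min(x$widths), max(x$widths), x$area,
              x$perimeter, x$centreline_length,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}

#' Full width-profile extraction from a mask
#'
#' Convenience wrapper running [extract_contour()], [find_endpoints()],
#' [split_arcs()] and [fit_centile_widths()] in sequence.
#'
#' @inheritParams find_endpoints
#' @inheritParams fit_centile_widths
#' @param mask a [cc_mask()].
#' @return A `cc_width_profile` (the `centreline`, `contour` and `arcs` are
#'   attached as attributes).
#' @examples
#' m <- matrix(FALSE, 48, 328)
#' m[20:29, 5:324] <- TRUE   # 80 x 2.5 mm bar at 0.25 mm spacing
#' p <- extract_widths(cc_mask(m, 0.25))
#' range(p$widths)           # all close to 2.5 mm
#' @export
extract_widths <- function(mask, hint = NULL, n_segments = 100L,
                           tol_mm = 0.01, max_iter = 100L) {
  contour <- extract_contour(mask)
  ends <- find_endpoints(contour, hint = hint, mask = mask)
  arcs <- split_arcs(contour, ends)
  fit <- fit_centile_widths(arcs, n_segments = n_segments, tol_mm = tol_mm,
                            max_iter = max_iter, contour = contour)
  out <- fit$profile
  attr(out, "centreline") <- fit$centreline
  attr(out, "contour") <- contour
  attr(out, "arcs") <- arcs
  out
}

## Scanline rasterization of a simple polygon onto a pixel grid at the given
## spacing (used when a contour arrives without its source mask).
rasterize_polygon <- function(pts, spacing, pad = 2L) {
  sy <- spacing[1L]; sx <- spacing[2L]
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  C <- ceiling((xr[2L]) / sx) + pad
  R <- ceiling((yr[2L]) / sy) + pad
  grid <- matrix(FALSE, R, C)
  closed <- rbind(pts, pts[1L, ])
  x1 <- closed[-nrow(closed), 1L]; y1 <- closed[-nrow(closed), 2L]
  x2 <- closed[-1L, 1L];          y2 <- closed[-1L, 2L]
  for (r in seq_len(R)) {
    y <- (R - r + 0.5) * sy
    cross <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (y - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (m in seq(1L, length(xs) - 1L, by = 2L)) {
      c1 <- ceiling(xs[m] / sx + 0.5); c2 <- floor(xs[m + 1L] / sx + 0.5)
      if (c2 >= c1) grid[r, max(1L, c1):min(C, c2)] <- TRUE
    }
  }
  list(grid = grid, spacing = c(sy, sx))
}
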