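#' Extract the outer contour of the corpus callosum mask
#'
#' Traces the boundary of the largest 8-connected foreground component as a
#' simple closed polygon in physical (mm) coordinates. The boundary is the
#' marching-squares level set at 0.5 between pixel centres, so a bar that is
#' w pixels wide has geometric width `w * spacing` (corners are chamfered by
#' half a pixel). Interior holes are filled and smaller components dropped,
#' each with a warning.
#'
#' @param mask a [cc_mask()].
#' @return An object of class `cc_contour`: a list with `points` (n x 2
#'   matrix of x, y vertices in mm, counter-clockwise, first vertex not
#'   repeated) and `spacing`.
#' @export
extract_contour <- function(mask) {
  stopifnot(inherits(mask, "cc_mask"))
  g <- mask$grid
  if (!any(g)) cc_stop("empty-mask", "mask has no foreground pixels")
  if (any(g[1L, ]) || any(g[nrow(g), ]) || any(g[, 1L]) || any(g[, ncol(g)]))
    cc_stop("mask-truncated", "foreground touches the image border")

  lab <- EBImage::bwlabel(g * 1L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L)
    cc_warn("components-dropped",
            sprintf("%d smaller component(s) dropped (largest kept: %d px)",
                    length(sizes) - 1L, max(sizes)))
  keep <- which.max(sizes)
  comp <- lab == keep
  filled <- EBImage::fillHull(comp * 1L) > 0
  if (sum(filled) > sum(comp))
    cc_warn("holes-filled",
            sprintf("%d interior hole pixel(s) filled", sum(filled) - sum(comp)))

  sy <- mask$spacing[1L]; sx <- mask$spacing[2L]
  R <- nrow(filled); C <- ncol(filled)
  xs <- (seq_len(C) - 0.5) * sx                 # pixel-centre x
  ys <- (seq_len(R) - 0.5) * sy                 # pixel-centre y (bottom row = min)
  z <- t(filled[R:1, , drop = FALSE]) * 1.0     # z[i, j] at (xs[i], ys[j])
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (!length(cl)) cc_stop("empty-mask", "no contour found at level 0.5")
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  pts <- cbind(cc$x, cc$y)
  if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
  structure(list(points = pts, spacing = mask$spacing), class = "cc_contour")
}

#' @export
print.cc_contour <- function(x, ...) {
  s <- shape_summary(x)
  cat(sprintf("<cc_contour> %d vertices, area %.2f mm^2, perimeter %.2f mm\n",
              nrow(x$points), s$area_mm2, s$perimeter_mm))
  invisible(x)
}

#' Area and perimeter of a closed contour
#'
#' Shoelace area and summed edge length of a simple closed polygon.
#'
#' @param contour a `cc_contour` or an n x 2 matrix of vertices (closed
#'   implicitly; the first vertex should not be repeated).
#' @return List with `area_mm2` and `perimeter_mm`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' shape_summary(sq)   # area 1, perimeter 4
#' @export
shape_summary <- function(contour) {
  p <- if (inherits(contour, "cc_contour")) contour$points else as.matrix(contour)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
  list(area_mm2 = abs(polygon_signed_area(p)),
       perimeter_mm = polyline_length(p, closed = TRUE))
}
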