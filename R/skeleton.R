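## Zhang-Suen morphological thinning and skeleton longest-path extraction.
## Used to locate the anterior/posterior tips of the callosal contour: the
## skeleton of an elongated shape is (close to) its medial axis, and the two
## ends of its longest geodesic path sit near the shape's terminal points.

shift_mat <- function(m, dr, dc) {
  R <- nrow(m); C <- ncol(m)
  out <- matrix(0L, R, C)
  rs <- seq_len(R) + dr; cs <- seq_len(C) + dc
  ok_r <- rs >= 1L & rs <= R; ok_c <- cs >= 1L & cs <= C
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  out
}

## Thin a logical matrix to a 1-px-wide skeleton (Zhang & Suen's two-pass
## deletion scheme, vectorized over the whole image).
skeletonize <- function(grid) {
  m <- (grid != 0) * 1L
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north; row 1 is the image top
      p2 <- shift_mat(m,  1L,  0L); p3 <- shift_mat(m,  1L, -1L)
      p4 <- shift_mat(m,  0L, -1L); p5 <- shift_mat(m, -1L, -1L)
      p6 <- shift_mat(m, -1L,  0L); p7 <- shift_mat(m, -1L,  1L)
      p8 <- shift_mat(m,  0L,  1L); p9 <- shift_mat(m,  1L,  1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1L) {
        cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

## Longest geodesic path through the skeleton pixel graph (8-connectivity,
## edges weighted by physical step length). Two sweeps of single-source
## shortest paths give the graph diameter endpoints (exact on trees, which a
## pruned skeleton nearly is). Returns the path as physical coordinates.
skeleton_longest_path <- function(skel, spacing) {
  idx <- which(skel)
  if (length(idx) < 2L)
    cc_stop("no-elongation", "skeleton too small to define an axis")
  R <- nrow(skel)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[idx] <- seq_along(idx)
  edges <- NULL; weights <- NULL
  sy <- spacing[1L]; sx <- spacing[2L]
  steps <- list(c(1L, 0L, sy), c(0L, 1L, sx),
                c(1L, 1L, sqrt(sx^2 + sy^2)), c(1L, -1L, sqrt(sx^2 + sy^2)))
  for (st in steps) {
    nb <- shift_mat(id, -st[1L], -st[2L])   # neighbour at (+dr, +dc)
    both <- id > 0L & nb > 0L
    if (any(both)) {
      edges <- c(edges, rbind(id[both], nb[both]))
      weights <- c(weights, rep(st[3L], sum(both)))
    }
  }
  if (is.null(edges))
    cc_stop("no-elongation", "skeleton pixels are not connected")
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  d1 <- igraph::distances(g, v = 1L)[1L, ]
  d1[!is.finite(d1)] <- -1
  v1 <- which.max(d1)
  d2 <- igraph::distances(g, v = v1)[1L, ]
  d2[!is.finite(d2)] <- -1
  v2 <- which.max(d2)
  path <- igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1L]]
  path <- as.integer(path)
  rows <- ((idx[path] - 1L) %% R) + 1L
  cols <- ((idx[path] - 1L) %/% R) + 1L
  pts <- cbind((cols - 0.5) * sx, (R - rows + 0.5) * sy)
  list(points = pts, length = d2[v2])
}
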