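# Analytic raster fixtures, built in code at test time.

# Solid axis-aligned bar: width_mm x height_mm at `spacing`, with a margin.
make_rect_mask <- function(width_mm = 80, height_mm = 10, spacing = 0.25,
                           margin_px = 10L) {
  w <- round(width_mm / spacing); h <- round(height_mm / spacing)
  g <- matrix(FALSE, h + 2L * margin_px, w + 2L * margin_px)
  g[margin_px + seq_len(h), margin_px + seq_len(w)] <- TRUE
  cc_mask(g, spacing)
}

# Constant-width half annulus (180 degrees, opening downward).
make_half_annulus_mask <- function(r_outer = 50, r_inner = 40, spacing = 0.25,
                                   margin_mm = 2) {
  half_w <- r_outer + margin_mm
  C <- ceiling(2 * half_w / spacing)
  R <- ceiling((r_outer + 2 * margin_mm) / spacing)
  xw <- -half_w + (seq_len(C) - 0.5) * spacing
  yw <- (R:1 - 0.5) * spacing - margin_mm
  X <- matrix(xw, R, C, byrow = TRUE)
  Y <- matrix(yw, R, C)
  rho <- sqrt(X^2 + Y^2)
  cc_mask(rho >= r_inner & rho <= r_outer & Y > 0, spacing)
}

make_disk_mask <- function(radius_mm = 20, spacing = 0.5, margin_mm = 2) {
  n <- ceiling(2 * (radius_mm + margin_mm) / spacing)
  ctr <- (radius_mm + margin_mm)
  xw <- (seq_len(n) - 0.5) * spacing - ctr
  X <- matrix(xw, n, n, byrow = TRUE)
  Y <- matrix(rev(xw), n, n)
  cc_mask(X^2 + Y^2 <= radius_mm^2, spacing)
}

# Brute-force AUC oracle: fraction of positive-negative pairs ranked
# correctly, ties counting one half.
auc_pair_count <- function(y_true, scores, positive) {
  sp <- scores[y_true == positive]
  sn <- scores[y_true != positive]
  cmp <- outer(sp, sn, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
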