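# Independent oracle implementations used to cross-check the package.
# These deliberately take different routes than the implementation:
# median polish via stats::medpolish driven to a fixed point, perimeters
# via EBImage contour walking, appositions via a double loop.

# Median polish residuals at the fixed point (eps = 0 forces the full
# iteration budget; 2000 sweeps converge on 16 x 24 plates).
oracle_medpolish <- function(m, iters = 2000) {
  suppressWarnings(stats::medpolish(m, eps = 0, maxiter = iters,
                                    trace.iter = FALSE, na.rm = TRUE))$residuals
}

oracle_bscore <- function(m, iters = 2000) {
  res <- oracle_medpolish(m, iters)
  s <- 1.4826 * stats::median(abs(res), na.rm = TRUE)
  if (s == 0) res * 0 else res / s
}

# Boundary-walk perimeter: EBImage's oriented contour walked as a chain
# code with Vossepoel-Smeulders corner-corrected weights (0.980 per
# orthogonal step, 1.406 per diagonal step, -0.091 per direction change),
# the standard low-bias chain estimator for digital perimeters.
oracle_boundary_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  diag_step <- rowSums(abs(d)) == 2
  turns <- sum(rowSums(abs(d - rbind(d[nrow(d), ], d[-nrow(d), ]))) > 0)
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * turns
}

# All-pairs O(n*m) apposition count.
oracle_appositions <- function(psd, syn, radius_px) {
  n <- 0L
  for (j in seq_len(nrow(psd))) {
    hit <- FALSE
    for (i in seq_len(nrow(syn))) {
      if ((psd$row[j] - syn$row[i])^2 + (psd$col[j] - syn$col[i])^2 <=
          radius_px^2) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

# Rasterize a filled axis-ratio q ellipse of given pixel area, for
# morphometry fixtures.
make_ellipse_mask <- function(area_px, q, theta = 0, pad = 6) {
  s <- sqrt(area_px / pi); a <- s * sqrt(q); b <- s / q^0.5
  ext <- ceiling(a) + pad
  n <- 2 * ext + 1
  d <- seq.int(-ext, ext)
  dr <- matrix(d, n, n); dc <- t(dr)
  x <- dc * cos(theta) + dr * sin(theta)
  y <- -dc * sin(theta) + dr * cos(theta)
  (x / a)^2 + (y / b)^2 <= 1
}

make_disk_mask <- function(radius, pad = 6) {
  make_ellipse_mask(pi * radius^2, 1, pad = pad)
}
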