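# Synthetic multi-channel field rendering with per-neuron ground truth.
#
# Geometry conventions: 0-based concepts are avoided at the R surface; all
# coordinates here are 1-based (row, col) matrix indices. Chain lengths use
# the 8-connected metric (1 per orthogonal step, sqrt(2) per diagonal step),
# which is the same metric the tracing stage uses, so generator bookkeeping
# and measurement share one definition of "length".

# Solve for the ellipse axis ratio whose continuous roundness 4*pi*A/P^2
# (Ramanujan perimeter) equals the target. Scale-invariant.
ellipse_axis_ratio <- function(roundness) {
  if (roundness >= 1) return(1)
  ram <- function(a, b) {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  }
  f <- function(q) 4 * pi * pi / ram(sqrt(q), 1 / sqrt(q))^2 - roundness
  stats::uniroot(f, c(1 + 1e-9, 50), tol = 1e-10)$root
}

# Pixel (row, col) offsets of a filled rotated ellipse centred at origin.
rasterize_ellipse <- function(a, b, theta, r0, c0) {
  ext <- ceiling(a) + 1L
  d <- seq.int(-ext, ext)
  dr <- rep(d, times = length(d))
  dc <- rep(d, each = length(d))
  x <- dc * cos(theta) + dr * sin(theta)
  y <- -dc * sin(theta) + dr * cos(theta)
  keep <- (x / a)^2 + (y / b)^2 <= 1
  cbind(r = round(r0) + dr[keep], c = round(c0) + dc[keep])
}

# 8-compass step table: direction k in 1..8, angle (k-1)*45 degrees.
.DIR_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.DIR_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.DIR_W  <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# Grow one neurite branch as a persistent 8-direction walk. Returns pixels
# and the chain length actually drawn.
grow_branch <- function(r, c, dir, len_budget, nr, nc, turn_prob = 0.25) {
  px_r <- integer(0); px_c <- integer(0); len <- 0; stuck <- 0L
  while (len < len_budget && stuck < 4L) {
    run <- stats::rgeom(1, turn_prob) + 1L
    w <- .DIR_W[dir]
    run <- min(run, max(1L, ceiling((len_budget - len) / w)))
    rr <- r + .DIR_DR[dir] * seq_len(run)
    cc <- c + .DIR_DC[dir] * seq_len(run)
    ok <- rr >= 2L & rr <= nr - 1L & cc >= 2L & cc <= nc - 1L
    n_ok <- if (all(ok)) run else which(!ok)[1] - 1L
    if (n_ok > 0L) {
      px_r <- c(px_r, rr[seq_len(n_ok)]); px_c <- c(px_c, cc[seq_len(n_ok)])
      r <- rr[n_ok]; c <- cc[n_ok]
      len <- len + n_ok * w
      stuck <- 0L
    } else stuck <- stuck + 1L
    dir <- if (n_ok < run) {
      ((dir - 1L + sample(c(2L, -2L), 1)) %% 8L) + 1L   # bounced off border
    } else ((dir - 1L + sample(c(-1L, 0L, 1L), 1)) %% 8L) + 1L
  }
  list(r = px_r, c = px_c, len = len, end_r = r, end_c = c, dir = dir)
}

add_gaussian_spot <- function(img, r0, c0, amplitude, sigma) {
  ext <- 3L
  rs <- max(1L, round(r0) - ext):min(nrow(img), round(r0) + ext)
  cs <- max(1L, round(c0) - ext):min(ncol(img), round(c0) + ext)
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  img[rs, cs] <- img[rs, cs] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a synthetic multi-channel fluorescence field
#'
#' Draws a deterministic (seeded) field of neurons from a [field_spec()]:
#' DAPI nuclei as filled rotated ellipses calibrated so the roundness index
#' recovers the spec target; MAP2 neurites as branched 1-px walks whose
#' chain length per neuron matches the spec mean; FOS/EGR-1 channels filled
#' within nuclear masks at responder or non-responder intensity; and, when
#' puncta densities are given, SYN1/PSD95 channels of Gaussian puncta with a
#' controlled fraction of apposed pairs. Gaussian read noise is added to
#' every channel and intensities are clipped to the 16-bit range.
#'
#' @param spec A [field_spec()].
#' @return An `image_field`: list with `channels` (named matrices, AFU),
#'   `pixel_size`, `condition`, `spec`, and `ground_truth` (tables `nuclei`,
#'   `neurites`, `puncta_syn1`, `puncta_psd95`).
#' @export
render_field <- function(spec) {
  spec <- validate_field_spec(spec)
  with_seed(spec$seed, render_field_impl(spec))
}

render_field_impl <- function(spec) {
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  ps <- spec$pixel_size
  blank <- function() matrix(0, nr, nc)
  dapi <- blank(); map2 <- blank(); fos <- blank(); egr1 <- blank()
  with_puncta <- !is.na(spec$puncta_density_syn1) &&
    !is.na(spec$puncta_density_psd95)
  syn1 <- if (with_puncta) blank() else NULL
  psd95 <- if (with_puncta) blank() else NULL

  n <- spec$n_neurons
  area_px_mean <- spec$nucleus_area_mean / ps^2
  mean_radius <- sqrt(area_px_mean / pi)
  q <- ellipse_axis_ratio(spec$roundness_mean)
  min_sep <- 2.4 * mean_radius * sqrt(q)
  margin <- ceiling(mean_radius * sqrt(q)) + 3L

  # -- nuclei placement (rejection sampling with a retry budget) -----------
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      r0 <- stats::runif(1, margin, nr - margin)
      c0 <- stats::runif(1, margin, nc - margin)
      if (nrow(centers) == 0 ||
          min((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) >= min_sep^2) {
        centers <- rbind(centers, c(r0, c0)); placed <- TRUE; break
      }
    }
    if (!placed)
      stop_fmt("field %dx%d too small to place %d non-overlapping nuclei",
               nr, nc, n)
  }

  frac_pos <- if (spec$condition == "stimulated")
    spec$ieg_pos_fraction_stim else spec$ieg_pos_fraction_unstim
  responder <- stats::runif(n) < frac_pos

  nuc_rows <- vector("list", n)
  gt_nuclei <- data.frame(neuron = integer(0), row = numeric(0),
                          col = numeric(0), area_px = integer(0),
                          area_um2 = numeric(0), roundness = numeric(0),
                          responder = logical(0))
  for (i in seq_len(n)) {
    area_i <- max(0.3 * area_px_mean,
                  stats::rnorm(1, area_px_mean,
                               spec$nucleus_area_cv * area_px_mean))
    round_i <- min(0.995, max(0.5, stats::rnorm(1, spec$roundness_mean, 0.008)))
    qi <- ellipse_axis_ratio(round_i)
    s <- sqrt(area_i / pi)
    a <- s * sqrt(qi); b <- s / sqrt(qi)
    px <- rasterize_ellipse(a, b, stats::runif(1, 0, pi),
                            centers[i, 1], centers[i, 2])
    px <- px[px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc, ,
             drop = FALSE]
    nuc_rows[[i]] <- px
    ii <- cbind(px[, 1], px[, 2])
    dapi_int <- 15000 * stats::runif(1, 0.9, 1.1)
    dapi[ii] <- dapi_int
    fos[ii] <- if (responder[i]) spec$fos_pos_intensity else spec$fos_neg_intensity
    egr1[ii] <- if (responder[i]) spec$egr1_pos_intensity else spec$egr1_neg_intensity
    gt_nuclei <- rbind(gt_nuclei, data.frame(
      neuron = i, row = centers[i, 1], col = centers[i, 2],
      area_px = nrow(px), area_um2 = nrow(px) * ps^2,
      roundness = round_i, responder = responder[i]))
  }

  # -- neurites ------------------------------------------------------------
  gt_neurites <- data.frame(neuron = integer(0), length_um = numeric(0),
                            n_segments = integer(0))
  neurite_px <- list()
  for (i in seq_len(n)) {
    target_px <- spec$neurite_length_mean / ps * exp(stats::rnorm(1, 0, 0.08))
    n_seg_target <- max(1L, round(spec$branches_per_neuron *
                                    stats::runif(1, 0.8, 1.2)))
    seg_mean <- target_px / n_seg_target
    n_primary <- min(n_seg_target, sample(2:4, 1))
    phis <- stats::runif(1, 0, 2 * pi) +
      2 * pi * seq_len(n_primary) / n_primary
    srad <- sqrt(gt_nuclei$area_px[i] / pi) + 1.5
    tips <- lapply(phis, function(phi) {
      dir <- (round(phi / (pi / 4)) %% 8) + 1
      list(r = round(centers[i, 1] + srad * sin(phi)),
           c = round(centers[i, 2] + srad * cos(phi)), dir = dir)
    })
    drawn <- 0; n_seg <- 0L
    px_r <- integer(0); px_c <- integer(0)
    while (length(tips) > 0 && drawn < target_px) {
      tip <- tips[[1]]; tips <- tips[-1]
      budget <- min(target_px - drawn, seg_mean * stats::runif(1, 0.5, 1.5))
      br <- grow_branch(tip$r, tip$c, tip$dir, budget, nr, nc)
      if (br$len <= 0) next
      px_r <- c(px_r, br$r); px_c <- c(px_c, br$c)
      drawn <- drawn + br$len; n_seg <- n_seg + 1L
      want_more <- n_seg + length(tips) < n_seg_target && drawn < target_px
      if (want_more)
        tips <- c(tips, list(
          list(r = br$end_r, c = br$end_c, dir = ((br$dir) %% 8) + 1),
          list(r = br$end_r, c = br$end_c, dir = ((br$dir - 2) %% 8) + 1)))
      if (length(tips) == 0 && drawn < target_px) {
        phi <- stats::runif(1, 0, 2 * pi)
        tips <- list(list(r = round(centers[i, 1] + srad * sin(phi)),
                          c = round(centers[i, 2] + srad * cos(phi)),
                          dir = (round(phi / (pi / 4)) %% 8) + 1))
      }
    }
    if (length(px_r) > 0) {
      map2[cbind(px_r, px_c)] <- 12000 * stats::runif(1, 0.9, 1.1)
      neurite_px[[length(neurite_px) + 1L]] <- cbind(px_r, px_c)
    }
    gt_neurites <- rbind(gt_neurites, data.frame(
      neuron = i, length_um = drawn * ps, n_segments = n_seg))
  }

  # -- synaptic puncta -----------------------------------------------------
  gt_syn1 <- data.frame(row = numeric(0), col = numeric(0))
  gt_psd95 <- data.frame(row = numeric(0), col = numeric(0),
                         apposed = logical(0))
  if (with_puncta && length(neurite_px) > 0) {
    all_px <- do.call(rbind, neurite_px)
    total_um <- sum(gt_neurites$length_um)
    cfg <- threshold_config()
    radius_px <- cfg$apposition_radius / ps
    n_syn <- round(total_um / 100 * spec$puncta_density_syn1)
    n_psd <- round(total_um / 100 * spec$puncta_density_psd95)
    if (n_syn > 0) {
      pick <- all_px[sample.int(nrow(all_px), n_syn, replace = TRUE), ,
                     drop = FALSE]
      gt_syn1 <- data.frame(row = pick[, 1] + stats::runif(n_syn, -0.5, 0.5),
                            col = pick[, 2] + stats::runif(n_syn, -0.5, 0.5))
    }
    if (n_psd > 0 && n_syn > 0) {
      n_app <- round(spec$apposed_fraction * n_psd)
      rows <- numeric(n_psd); cols <- numeric(n_psd)
      for (j in seq_len(n_psd)) {
        if (j <= n_app) {
          k <- sample.int(n_syn, 1)
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.7 * radius_px)
          rows[j] <- gt_syn1$row[k] + rad * sin(ang)
          cols[j] <- gt_syn1$col[k] + rad * cos(ang)
        } else {
          for (try in seq_len(60L)) {
            cand <- all_px[sample.int(nrow(all_px), 1), ]
            rj <- cand[1] + stats::runif(1, -0.5, 0.5)
            cj <- cand[2] + stats::runif(1, -0.5, 0.5)
            d2 <- min((gt_syn1$row - rj)^2 + (gt_syn1$col - cj)^2)
            if (d2 > (2 * radius_px)^2 || try == 60L) break
          }
          rows[j] <- rj; cols[j] <- cj
        }
      }
      # truth label from geometry, not construction
      app <- vapply(seq_len(n_psd), function(j) {
        min((gt_syn1$row - rows[j])^2 + (gt_syn1$col - cols[j])^2) <=
          radius_px^2
      }, logical(1))
      gt_psd95 <- data.frame(row = rows, col = cols, apposed = app)
    }
    for (j in seq_len(nrow(gt_syn1)))
      syn1 <- add_gaussian_spot(syn1, gt_syn1$row[j], gt_syn1$col[j],
                                4000, 1.2)
    for (j in seq_len(nrow(gt_psd95)))
      psd95 <- add_gaussian_spot(psd95, gt_psd95$row[j], gt_psd95$col[j],
                                 4000, 1.2)
  }

  finish <- function(x) {
    x <- x + spec$background + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd),
                                      nr, nc)
    pmin(pmax(x, 0), 65535)
  }
  channels <- list(DAPI = finish(dapi), MAP2 = finish(map2),
                   FOS = finish(fos), EGR1 = finish(egr1))
  if (with_puncta) {
    channels$SYN1 <- finish(syn1)
    channels$PSD95 <- finish(psd95)
  }

  structure(list(channels = channels, pixel_size = ps,
                 condition = spec$condition, spec = spec,
                 ground_truth = list(nuclei = gt_nuclei,
                                     neurites = gt_neurites,
                                     puncta_syn1 = gt_syn1,
                                     puncta_psd95 = gt_psd95)),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field '%s'> %s, %dx%d px @ %.2f um/px, channels: %s\n",
              x$spec$preset_name, x$condition, nrow(x$channels[[1]]),
              ncol(x$channels[[1]]), x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  ground truth: %d nuclei, %.0f um neurite total\n",
              nrow(x$ground_truth$nuclei), sum(x$ground_truth$neurites$length_um)))
  invisible(x)
}
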