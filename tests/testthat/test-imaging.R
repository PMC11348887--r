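# Imaging operators: segmentation, morphometry, tracing, IEG scoring,
# puncta and appositions, field measurement.

test_that("nucleus segmentation handles blank rasters and separated disks", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(segment_nuclei(blank)$records), 0)

  img <- matrix(100, 300, 300)
  centers <- expand.grid(r = c(60, 150, 240), c = c(60, 150, 240))
  disk <- make_disk_mask(8, pad = 2)
  for (i in seq_len(9)) {
    rr <- centers$r[i] + (seq_len(nrow(disk)) - ceiling(nrow(disk) / 2))
    cc <- centers$c[i] + (seq_len(ncol(disk)) - ceiling(ncol(disk) / 2))
    img[rr, cc][disk] <- 15000
  }
  seg <- segment_nuclei(img, threshold_config(dapi_min_area = 10))
  expect_equal(nrow(seg$records), 9)
  # disk r=8 px at 0.65 um/px: area ~ pi*(8*0.65)^2 = 84.9 um^2
  expect_lt(max(abs(seg$records$area_um2 - pi * (8 * 0.65)^2)) /
              (pi * (8 * 0.65)^2), 0.1)
})

test_that("morphometry: circles score ~1 and matches the analytic disk area", {
  disk <- make_disk_mask(20)
  m <- nucleus_morphometry(disk, pixel_size = 0.65)
  expect_gte(m$roundness, 0.95)
  expect_lte(m$roundness, 1.0)
  expect_lt(abs(m$area - pi * (20 * 0.65)^2) / (pi * (20 * 0.65)^2), 0.05)
  expect_error(nucleus_morphometry(matrix(FALSE, 5, 5)), "at least one")
})

test_that("roundness agrees with a boundary-walk oracle on smooth shapes", {
  for (q in c(1.2, 1.6, 2.0, 3.0)) {
    mask <- make_ellipse_mask(3000, q, theta = 0.4)
    m <- nucleus_morphometry(mask, pixel_size = 1)
    p_oracle <- oracle_boundary_perimeter(mask)
    r_oracle <- min(1, 4 * pi * sum(mask) / p_oracle^2)
    expect_lt(abs(m$roundness - r_oracle) / r_oracle, 0.05)
  }
  # 4:1 axis-aligned rectangle, the polygon worst case for Crofton
  rect <- matrix(FALSE, 40, 100); rect[11:30, 11:90] <- TRUE
  m <- nucleus_morphometry(rect, pixel_size = 1)
  p_oracle <- oracle_boundary_perimeter(rect)
  r_oracle <- 4 * pi * sum(rect) / p_oracle^2
  expect_lt(abs(m$roundness - r_oracle) / r_oracle, 0.05)
})

test_that("roundness decreases monotonically with ellipse elongation", {
  rs <- vapply(c(1, 1.5, 2, 3, 4), function(q)
    nucleus_morphometry(make_ellipse_mask(1500, q))$roundness, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("neurite tracing measures lines, trees and rotations correctly", {
  # horizontal 100-px line: 99 unit steps x 0.65 um
  img <- matrix(100, 60, 120)
  img[30, 11:110] <- 12000
  gr <- trace_neurites(img, pixel_size = 0.65)
  expect_equal(gr$total_length, 99 * 0.65, tolerance = 0.02)
  expect_equal(gr$n_segments, 1)

  # Y-tree: one junction, three tips -> 3 segments
  y <- matrix(100, 80, 80)
  y[40, 10:40] <- 12000                      # stem
  for (k in 1:25) { y[40 - k, 40 + k] <- 12000; y[40 + k, 40 + k] <- 12000 }
  gy <- trace_neurites(y, pixel_size = 1)
  expect_equal(gy$n_segments, 3)
  expect_equal(gy$total_length, 30 + 2 * 25 * sqrt(2), tolerance = 0.1)

  # 90-degree rotation leaves total length within 1%
  spec <- field_preset("hpsc_day21", n_neurons = 8,
                       field_shape = c(320, 320), seed = 31)
  fld <- render_field(spec)
  g1 <- trace_neurites(fld$channels$MAP2)
  rot <- t(fld$channels$MAP2)[ncol(fld$channels$MAP2):1, ]
  g2 <- trace_neurites(rot)
  expect_lt(abs(g1$total_length - g2$total_length) / g1$total_length, 0.01)
})

test_that("IEG scoring applies strict thresholds within nuclear masks", {
  img <- matrix(100, 200, 200)
  centers <- expand.grid(r = c(30, 100, 170), c = c(30, 100, 170))
  disk <- make_disk_mask(8, pad = 2)
  for (i in seq_len(9)) {
    rr <- centers$r[i] + (seq_len(nrow(disk)) - ceiling(nrow(disk) / 2))
    cc <- centers$c[i] + (seq_len(ncol(disk)) - ceiling(ncol(disk) / 2))
    img[rr, cc][disk] <- 15000
  }
  seg <- segment_nuclei(img, threshold_config(dapi_min_area = 10))
  n <- nrow(seg$records)
  fos <- matrix(0, 200, 200); egr <- matrix(0, 200, 200)
  # first 3 nuclei FOS-bright (900), rest dim (100); EGR exactly at 1000
  for (lab in seq_len(n)) {
    px <- seg$labels == lab
    fos[px] <- if (lab <= 3) 900 else 100
    egr[px] <- 1000
  }
  sc <- score_ieg(seg, fos, egr)
  expect_equal(unname(sc$fractions["frac_fos"]), 3 / n)
  expect_equal(unname(sc$fractions["frac_egr1"]), 0)   # ties are negative
  expect_equal(unname(sc$fractions["frac_double"]), 0)
  expect_true(all(sc$records$double_pos == (sc$records$fos_pos &
                                              sc$records$egr1_pos)))
  # adding a constant below the threshold gap changes nothing
  sc2 <- score_ieg(seg, fos + 500, egr)   # 100+500=600 < 800, 900+500 > 800
  expect_equal(sc2$fractions, sc$fractions)
  # all-zero channel scores zero positives
  sc0 <- score_ieg(seg, matrix(0, 200, 200), matrix(0, 200, 200))
  expect_equal(unname(sc0$fractions["frac_fos"]), 0)
})

test_that("puncta detection finds planted spots on neurites and respects the mask", {
  set.seed(77)
  img <- matrix(0, 200, 200)
  mask <- matrix(FALSE, 200, 200)
  mask[100, 20:180] <- TRUE                # a horizontal neurite
  spots <- data.frame(row = c(100, 100, 99, 101, 100),
                      col = c(40, 70, 100, 130, 160))
  add_spot <- function(img, r0, c0) {
    for (dr in -3:3) for (dc in -3:3)
      img[r0 + dr, c0 + dc] <- img[r0 + dr, c0 + dc] +
        4000 * exp(-(dr^2 + dc^2) / (2 * 1.2^2))
    img
  }
  for (i in 1:5) img <- add_spot(img, spots$row[i], spots$col[i])
  img_off <- add_spot(img, 30, 30)          # off-neurite spot
  noisy <- img_off + matrix(rnorm(200 * 200, 100, 40), 200, 200)

  det <- detect_puncta(noisy, neurite_mask = mask, pixel_size = 0.65)
  expect_equal(nrow(det), 5)
  for (i in 1:5) {
    d <- sqrt((det$row - spots$row[i])^2 + (det$col - spots$col[i])^2)
    expect_lt(min(d), 2)
  }
  det_all <- detect_puncta(noisy, pixel_size = 0.65)   # no mask: 6 spots
  expect_equal(nrow(det_all), 6)
  blank <- detect_puncta(matrix(0, 64, 64))
  expect_equal(nrow(blank), 0)
})

test_that("apposition counting equals the all-pairs oracle", {
  cfg <- threshold_config()
  rad_px <- cfg$apposition_radius / 0.65
  # hand-built: 3 of 5 PSD95 within radius of some SYN1
  syn <- data.frame(row = c(10, 50, 90), col = c(10, 50, 90))
  psd <- data.frame(row = c(10.5, 50, 89, 30, 70),
                    col = c(10.5, 51, 90.8, 30, 10))
  app <- count_appositions(syn, psd, cfg, total_length = 200,
                           pixel_size = 0.65)
  expect_equal(app$apposed_count, 3L)
  expect_equal(app$apposed_per_100um, 3 / 2)
  expect_equal(count_appositions(syn, psd[0, ], cfg, 200)$apposed_count, 0L)

  set.seed(123)
  for (i in 1:20) {
    syn <- data.frame(row = runif(60, 0, 100), col = runif(60, 0, 100))
    psd <- data.frame(row = runif(40, 0, 100), col = runif(40, 0, 100))
    got <- count_appositions(syn, psd, cfg, pixel_size = 0.65)$apposed_count
    expect_equal(got, oracle_appositions(psd, syn, rad_px))
  }
})

test_that("field measurement composes the pipeline and tolerates missing channels", {
  spec <- field_preset("hpsc_treated", n_neurons = 8,
                       field_shape = c(384, 384), seed = 41)
  fld <- render_field(spec)
  ff <- measure_field(fld)
  expect_equal(ff$n_nuclei, 8)
  expect_false(is.na(ff$apposed_per_100um))
  expect_true(ff$frac_fos >= 0 && ff$frac_fos <= 1)

  # drop the synaptic channels: morphology still measured, puncta missing
  fld2 <- fld; fld2$channels$SYN1 <- NULL; fld2$channels$PSD95 <- NULL
  ff2 <- measure_field(fld2)
  expect_true(is.na(ff2$syn1_count))
  expect_equal(ff2$n_nuclei, ff$n_nuclei)

  # an empty field reports missing per-nucleus features, not errors
  ff0 <- measure_field(render_field(field_spec(n_neurons = 0,
                                               field_shape = c(128, 128),
                                               seed = 1)))
  expect_equal(ff0$n_nuclei, 0)
  expect_true(is.na(ff0$neurite_length_per_nucleus))

  fld3 <- fld; fld3$channels$MAP2 <- NULL
  expect_error(measure_field(fld3), "MAP2")
})

test_that("apposition fraction fixtures recover the planted fraction", {
  spec <- field_preset("hpsc_day21", n_neurons = 10, apposed_fraction = 0.5,
                       field_shape = c(512, 512), seed = 55)
  fld <- render_field(spec)
  gt <- fld$ground_truth$puncta_psd95
  n <- nrow(gt)
  # binomial tolerance around the constructed fraction
  expect_gt(n, 20)
  expect_lt(abs(mean(gt$apposed) - 0.5), 3 * sqrt(0.25 / n) + 0.05)
})
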