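# Synthetic-data generators: presets, determinism, ground-truth
# bookkeeping and planted-truth completeness.

test_that("presets encode the benchmark culture states", {
  rat <- field_preset("rat_day14")
  expect_equal(rat$nucleus_area_mean, 130)
  expect_equal(rat$roundness_mean, 0.93)
  expect_gt(rat$neurite_length_mean, 2500)
  expect_gt(rat$ieg_pos_fraction_stim, 0.95)

  hpsc <- field_preset("hpsc_day21")
  expect_lt(hpsc$nucleus_area_mean, rat$nucleus_area_mean)
  expect_lt(hpsc$roundness_mean, rat$roundness_mean)
  expect_lt(hpsc$neurite_length_mean, rat$neurite_length_mean)
  expect_lt(hpsc$ieg_pos_fraction_stim, rat$ieg_pos_fraction_stim)

  expect_error(field_preset("unknown"), "valid presets")
})

test_that("generators are deterministic given spec and seed", {
  spec <- field_preset("hpsc_day21", n_neurons = 6,
                       field_shape = c(256, 256), seed = 21)
  f1 <- render_field(spec); f2 <- render_field(spec)
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$ground_truth, f2$ground_truth)

  lib <- library_spec(n_compounds = 100, n_toxic = 5, n_hits = 5, seed = 3)
  expect_identical(simulate_screen_features(lib),
                   simulate_screen_features(lib))

  ms <- mea_sim_spec(n_channels = 64, duration = 10, trace_channels = 1:2,
                     seed = 5)
  r1 <- simulate_mea(ms); r2 <- simulate_mea(ms)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$traces, r2$traces)

  cs <- calcium_sim_spec(n_rois = 4, seed = 6)
  expect_identical(simulate_calcium(cs)$traces, simulate_calcium(cs)$traces)
})

test_that("empty field renders pure noise with empty ground truth", {
  spec <- field_spec(n_neurons = 0, field_shape = c(128, 128), seed = 1)
  fld <- render_field(spec)
  expect_equal(nrow(fld$ground_truth$nuclei), 0)
  expect_equal(nrow(fld$ground_truth$neurites), 0)
  # nothing but background + noise in any channel
  expect_lt(max(fld$channels$DAPI), spec$background + 6 * spec$noise_sd)
})

test_that("nucleus bookkeeping matches connected components of a noiseless render", {
  spec <- field_preset("hpsc_day21", n_neurons = 10, noise_sd = 0,
                       field_shape = c(512, 512), seed = 14)
  fld <- render_field(spec)
  expect_equal(nrow(fld$ground_truth$nuclei), 10)
  comp <- EBImage::bwlabel(EBImage::Image((fld$channels$DAPI > 5000) * 1))
  expect_equal(max(comp), 10)
})

test_that("placement fails loudly when the field cannot hold the nuclei", {
  expect_error(render_field(field_spec(n_neurons = 50,
                                       field_shape = c(64, 64), seed = 1)),
               "too small")
})

test_that("noiseless ground truth recovers spec means within sampling error", {
  spec <- field_preset("rat_day14", n_neurons = 200, noise_sd = 0,
                       field_shape = c(2048, 2048), seed = 2)
  fld <- render_field(spec)
  gt <- fld$ground_truth
  expect_equal(nrow(gt$nuclei), 200)
  expect_lt(abs(mean(gt$nuclei$area_um2) - 130) / 130, 0.1)
  expect_lt(abs(mean(gt$neurites$length_um) - 2800) / 2800, 0.1)
})

test_that("screen simulation plants every compound exactly once with labelled truth", {
  lib <- library_spec(n_compounds = 200, n_toxic = 12, n_hits = 7,
                      plate_shape = c(8, 12), controls_per_plate = 16,
                      seed = 8)
  feats <- simulate_screen_features(lib)
  truth <- attr(feats, "truth")
  expect_equal(nrow(truth), 200)
  expect_equal(anyDuplicated(truth$compound_id), 0)
  expect_equal(sum(truth$class == "toxic"), 12)
  expect_equal(sum(truth$class == "hit"), 7)
  # every compound appears once per plate instance (2 reps x 2 conditions)
  counts <- table(feats$compound_id[feats$compound_id != "DMSO"])
  expect_true(all(counts == lib$n_replicates * 2))
  # DMSO on every plate instance
  dmso <- unique(feats[feats$compound_id == "DMSO",
                       c("plate", "replicate", "condition")])
  expect_equal(nrow(dmso), lib$n_plates * lib$n_replicates * 2)
})

test_that("effect-free libraries make compound wells exchangeable with controls", {
  lib <- library_spec(n_compounds = 300, n_toxic = 0, n_hits = 0,
                      row_effect_sd = 0, col_effect_sd = 0, seed = 10)
  feats <- simulate_screen_features(lib)
  cmp <- feats$nuclei_count[feats$compound_id != "DMSO"]
  ctl <- feats$nuclei_count[feats$compound_id == "DMSO"]
  expect_lt(abs(mean(cmp) - mean(ctl)), 3 * 120 / sqrt(length(ctl)))
})

test_that("MEA simulation plants the requested spikes and bursts", {
  quiet <- simulate_mea(mea_sim_spec(n_channels = 32, duration = 5,
                                     baseline_rate = 0, burst_rate = 0,
                                     trace_channels = 1, seed = 1))
  expect_equal(nrow(quiet$spikes), 0)
  expect_equal(nrow(quiet$truth$bursts), 0)

  rec <- simulate_mea(mea_sim_spec(duration = 60, burst_rate = 0.7,
                                   baseline_rate = 0.05, seed = 2))
  expect_equal(nrow(rec$truth$bursts), 42)  # 0.7 Hz x 60 s
  expect_true(all(rec$spikes$time >= 0 & rec$spikes$time <= 60))
  # planted 12-sigma spikes all exceed the 9-sigma threshold by construction
  tr <- simulate_mea(mea_sim_spec(n_channels = 16, duration = 20,
                                  baseline_rate = 0.5, spike_amplitude = 12,
                                  trace_channels = 3, seed = 4))
  sigma <- robust_sigma(tr$traces[, 1])
  expect_true(min(tr$traces[, 1]) < -9 * sigma)
})

test_that("calcium simulation follows the acquisition schedule and plants events", {
  ca <- simulate_calcium(calcium_sim_spec(n_rois = 3, seed = 3))
  expect_equal(ncol(ca$traces), 240)  # 20 min at one frame per 5 s
  flat <- simulate_calcium(calcium_sim_spec(n_rois = 3, events_per_roi = 0,
                                            seed = 3))
  expect_equal(nrow(flat$truth), 0)
  ev <- simulate_calcium(calcium_sim_spec(n_rois = 5, events_per_roi = 7,
                                          seed = 9))
  expect_equal(as.vector(table(ev$truth$roi)), rep(7L, 5))
  expect_error(calcium_sim_spec(duration = 1197),
               "not a multiple")
})
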