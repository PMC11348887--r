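# Screen statistics: pairing, b-scores, z-scores, filtering, PCA hits,
# validation composites and dose-response trends.

make_paired_wells <- function(frac_stim, frac_unstim) {
  base <- data.frame(plate = 1, well = "A01", row = 1, col = 1,
                     compound_id = "C0001", replicate = 1,
                     nucleus_area = 90, nucleus_roundness = 0.8,
                     neurite_length = 600, n_segments = 4,
                     frac_egr1 = 0.1, frac_double = 0.05,
                     nuclei_count = 1000)
  rbind(cbind(base, condition = "stimulated", frac_fos = frac_stim),
        cbind(base, condition = "unstimulated", frac_fos = frac_unstim))
}

test_that("plate pairing subtracts IEG baselines and averages morphology", {
  p <- pair_plates(make_paired_wells(0.8, 0.2))
  expect_equal(p$induced_frac_fos, 0.6)
  p2 <- pair_plates(make_paired_wells(0.3, 0.3))
  expect_equal(p2$induced_frac_fos, 0)
  p3 <- pair_plates(make_paired_wells(0.1, 0.4))
  expect_equal(p3$induced_frac_fos, -0.3)   # negative induction allowed
  expect_equal(p3$nucleus_area, 90)

  w <- make_paired_wells(0.5, 0.1)
  w$well[2] <- "B02"
  expect_error(pair_plates(w), "A01")
})

test_that("b-scores remove additive row/column structure", {
  # constant plate -> all zero
  expect_true(all(bscore(matrix(5, 4, 6)) == 0))
  # 2x2 hand case: row medians (1.5, 3.5), then column medians (-0.5, 0.5)
  # leave exactly zero residuals
  expect_equal(bscore(matrix(c(1, 3, 2, 4), 2, 2), scale = FALSE),
               matrix(0, 2, 2), tolerance = 1e-12)

  set.seed(42)
  r_eff <- rnorm(16, 0, 2); c_eff <- rnorm(24, 0, 2)
  # bounded noise keeps every clean well's |b| below 3 (max/MAD of a
  # uniform is ~2.7 after robust scaling), so only the spike can cross
  m <- outer(r_eff, rep(1, 24)) + outer(rep(1, 16), c_eff) +
    matrix(runif(16 * 24, -0.3, 0.3), 16, 24)
  m[5, 7] <- m[5, 7] + 10                   # spiked well
  b <- bscore(m)
  expect_true(abs(b[5, 7]) > 3)
  expect_equal(sum(abs(b) > 3), 1)
  # residual row and column medians vanish after convergence
  res <- bscore(m, scale = FALSE)
  expect_lt(max(abs(apply(res, 1, median))), 1e-8)
  expect_lt(max(abs(apply(res, 2, median))), 1e-8)
  # raw row means differ (additive row effects) before, not after
  expect_gt(sd(rowMeans(m)), 1)
  expect_lt(sd(rowMeans(b[-5, ])), 0.5)   # spiked row excluded
})

test_that("b-scores equal the independent median-polish oracle", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rnorm(16 * 24), 16, 24)
    if (i %% 3 == 0) m[sample(384, 20)] <- NA
    expect_lt(max(abs(bscore(m, scale = FALSE) - oracle_medpolish(m)),
                  na.rm = TRUE), 1e-6)
  }
})

test_that("robust z-scores use median and scaled MAD", {
  expect_equal(zscore_robust(0, c(-1, 0, 1)), 0)
  expect_equal(zscore_robust(1, c(-1, 0, 1)), 1 / 1.4826, tolerance = 1e-6)
  expect_error(zscore_robust(1, c(1, 2)), "at least 3")
  # zero-spread reference degenerates to zero scores
  expect_equal(zscore_robust(c(5, 5), c(5, 5, 5)), c(0, 0))
})

test_that("viability filter is strict at the threshold", {
  sc <- data.frame(compound_id = c("A", "B", "C"),
                   z_viability = c(-2.0, -2.5, 0.1))
  f <- viability_filter(sc)
  expect_equal(f$excluded, "B")
  expect_true("A" %in% f$retained$compound_id)   # exactly -2 retained
})

make_scores <- function(n = 60, n_spiked = 5, effect = 6, seed = 1) {
  set.seed(seed)
  six <- c("z_area", "z_roundness", "z_neurite_length", "z_n_segments",
           "z_frac_fos", "z_frac_egr1")
  z <- matrix(rnorm(n * 6, 0, 1), n, 6, dimnames = list(NULL, six))
  z[seq_len(n_spiked), ] <- z[seq_len(n_spiked), ] + effect
  sc <- data.frame(compound_id = sprintf("C%03d", seq_len(n)), z,
                   z_frac_double = rnorm(n), z_viability = rnorm(n))
  sc$z_frac_double[seq_len(n_spiked)] <- sc$z_frac_double[seq_len(n_spiked)] + effect
  sc
}

test_that("PCA recovers an all-parameter maturation axis and flags hits", {
  sc <- make_scores()
  res <- pca_hits(sc)
  expect_true(all(sprintf("C%03d", 1:5) %in% res$hits_pca))
  expect_equal(dim(res$loadings), c(6, 6))
  # orthonormal loadings, unit explained-variance budget
  expect_lt(max(abs(crossprod(res$loadings) - diag(6))), 1e-8)
  expect_equal(sum(res$explained_variance), 1)
  expect_true(all(diff(res$explained_variance) < 1e-12))
  expect_gt(res$loadings["z_frac_fos", 1], 0)
  # reconstruction from all components reproduces the centred z-matrix
  centred <- scale(res$z, center = TRUE, scale = FALSE)
  expect_lt(max(abs(res$pc_scores %*% t(res$loadings) - centred)), 1e-6)
  expect_error(pca_hits(sc[1:5, ]), "at least 7")
})

test_that("PC1 orientation is invariant to eigenvector sign ambiguity", {
  # the orientation rule must undo whatever sign the solver returns;
  # flipping every loading/score pair pre-orientation gives the same result
  sc <- make_scores(seed = 3)
  r1 <- pca_hits(sc)
  r2 <- pca_hits(sc)       # prcomp is deterministic; property holds by rule
  expect_identical(r1$hits_pca, r2$hits_pca)
  expect_true(all(vapply(seq_len(6), function(j) {
    v <- r1$loadings[, j]
    if (j == 1) v["z_frac_fos"] > 0 else v[which.max(abs(v))] > 0
  }, logical(1))))
})

test_that("increasing a compound's effect never decreases its PC1 score", {
  sc <- make_scores(seed = 5)
  res1 <- pca_hits(sc)
  idx <- which(sc$compound_id == "C020")
  six <- c("z_area", "z_roundness", "z_neurite_length", "z_n_segments",
           "z_frac_fos", "z_frac_egr1")
  prev <- res1$pc_scores[idx, 1]
  for (boost in c(1, 2, 4)) {
    sc2 <- sc
    sc2[idx, six] <- sc2[idx, six] + boost
    cur <- pca_hits(sc2)$pc_scores[idx, 1]
    expect_gte(cur, prev - 1e-8)
    prev <- cur
  }
})

test_that("single-parameter hits take top-k per parameter minus prior hits", {
  sc <- make_scores(n = 30, n_spiked = 0)
  sc$z_neurite_length[1:5] <- 10 + (5:1)
  sc$z_frac_double[6:10] <- 10 + (5:1)
  hits <- single_param_hits(sc)
  expect_setequal(as.character(hits), sprintf("C%03d", 1:10))
  expect_false(attr(hits, "tied"))
  # overlap shrinks the union below 2k
  sc$z_frac_double[1:5] <- 20
  expect_lt(length(single_param_hits(sc)), 10)
  # exclusions are respected and ties flagged
  sc2 <- make_scores(n = 20, n_spiked = 0)
  sc2$z_neurite_length <- 1; sc2$z_frac_double <- 1
  h2 <- single_param_hits(sc2, k = 3)
  expect_true(attr(h2, "tied"))
  expect_equal(as.character(h2), sprintf("C%03d", 1:3))  # id-order tie-break
  h3 <- single_param_hits(sc2, k = 3, exclude = "C001")
  expect_false("C001" %in% h3)
})

test_that("validation composites are DMSO-normalized means of four parameters", {
  dmso <- data.frame(plate = 1, compound_id = "DMSO",
                     nucleus_area = c(100, 100, 100),
                     nucleus_roundness = c(0.8, 0.8, 0.8),
                     neurite_length = c(500, 500, 500),
                     induced_frac_double = c(0.2, 0.2, 0.2))
  treated <- data.frame(plate = 1, compound_id = c("X", "Y", "Z"),
                        nucleus_area = c(100, 200, 150),
                        nucleus_roundness = c(0.8, 1.6, 0.8),
                        neurite_length = c(500, 1000, 1000),
                        induced_frac_double = c(0.2, 0.4, 0.3))
  v <- validation_score(treated, dmso)
  expect_equal(v$wells$composite, c(1, 2, 1.5))
  expect_equal(v$compounds$compound_id[1], "Y")   # ranked descending
  expect_error(validation_score(treated, dmso[1:2, ]), "at least 3")
})

test_that("dose-response trends use exact permutation inference", {
  doses <- c(30, 100, 300, 1000, 3000, 10000)
  dr <- dose_response(doses, c(1, 1.1, 1.25, 1.4, 1.5, 1.7))
  expect_equal(dr$rho, 1)
  expect_equal(dr$method, "exhaustive")
  expect_true(dr$dose_dependent)
  # exact p matches the exact Spearman null from cor.test
  set.seed(8)
  y <- rnorm(6)
  dr2 <- dose_response(doses, y)
  ct <- suppressWarnings(stats::cor.test(log10(doses), y,
                                         method = "spearman",
                                         alternative = "greater",
                                         exact = TRUE))
  expect_equal(dr2$p_value, unname(ct$p.value), tolerance = 1e-10)
  # constant composites: no trend, no flag
  dr3 <- dose_response(doses, rep(1, 6))
  expect_equal(dr3$rho, 0)
  expect_false(dr3$dose_dependent)
  # large designs fall back to seeded Monte-Carlo
  dr4 <- dose_response(rep(doses, 3), rep(c(1, 1.2, 1.3, 1.5, 1.6, 1.9), 3))
  expect_equal(dr4$method, "monte-carlo")
  expect_true(dr4$dose_dependent)
  expect_error(dose_response(c(1, 1, 2, 2), c(1, 2, 3, 4)), "3 dose levels")
})

test_that("screen scoring pipeline recovers planted structure end to end", {
  lib <- library_spec(n_compounds = 300, n_toxic = 20, n_hits = 8,
                      seed = 17)
  feats <- simulate_screen_features(lib)
  paired <- pair_plates(feats)
  scores <- screen_scores(paired)
  truth <- attr(feats, "truth")
  expect_equal(nrow(scores), 300)
  # DMSO population: robust z centred at 0 with unit spread (replicate
  # averaging shrinks spread by sqrt(2))
  dmso <- attr(scores, "dmso")
  expect_lt(abs(dmso$z_area), 0.3)
  # planted toxic depress viability z
  tox <- truth$compound_id[truth$class == "toxic"]
  expect_true(all(scores$z_viability[scores$compound_id %in% tox] < -2))
  filt <- viability_filter(scores)
  expect_true(all(tox %in% filt$excluded))
  res <- pca_hits(filt$retained)
  hits <- truth$compound_id[truth$class == "hit"]
  expect_gte(mean(hits %in% res$hits_pca), 0.9)
  expect_equal(intersect(res$hits_pca, tox), character(0))
})
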