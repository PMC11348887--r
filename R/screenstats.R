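# Screen analytics: plate pairing, b-score and robust z-score
# normalization, viability filtering, PCA hit selection, single-parameter
# hits, validation composites and dose-response trends.

#' Pair stimulated and unstimulated plates
#'
#' Matches wells across the two plate types of each replicate by (plate,
#' well, replicate). IEG fractions are baseline-subtracted (stimulated
#' minus unstimulated, so the induced response isolates depolarization);
#' morphology parameters and the nuclei count are averaged across the pair.
#'
#' @param wells A `plate_features` data frame containing both conditions.
#' @return Data frame of per-well paired scores: morphology averages,
#'   `induced_frac_fos`, `induced_frac_egr1`, `induced_frac_double`, and
#'   `nuclei_count`.
#' @export
pair_plates <- function(wells) {
  stim <- wells[wells$condition == "stimulated", ]
  unstim <- wells[wells$condition == "unstimulated", ]
  key <- function(d) paste(d$plate, d$well, d$replicate, sep = "/")
  ks <- key(stim); ku <- key(unstim)
  orphan <- c(setdiff(ks, ku), setdiff(ku, ks))
  if (length(orphan) > 0)
    stop_fmt("unmatched well address(es) across plate pair: %s",
             paste(utils::head(orphan, 5), collapse = ", "))
  u <- unstim[match(ks, ku), ]
  avg <- function(f) (stim[[f]] + u[[f]]) / 2
  data.frame(
    plate = stim$plate, well = stim$well, row = stim$row, col = stim$col,
    replicate = stim$replicate, compound_id = stim$compound_id,
    nucleus_area = avg("nucleus_area"),
    nucleus_roundness = avg("nucleus_roundness"),
    neurite_length = avg("neurite_length"),
    n_segments = avg("n_segments"),
    induced_frac_fos = stim$frac_fos - u$frac_fos,
    induced_frac_egr1 = stim$frac_egr1 - u$frac_egr1,
    induced_frac_double = stim$frac_double - u$frac_double,
    nuclei_count = avg("nuclei_count"),
    stringsAsFactors = FALSE)
}

#' B-score normalization of one plate
#'
#' Two-way median polish (Tukey) removes additive row and column effects:
#' row and column medians are swept alternately until the largest absolute
#' sweep falls below `tol` or `max_iter` is reached. Residuals are then
#' scaled by 1.4826 times the median absolute residual so a unit b-score
#' corresponds to one robust SD of the plate. A plate with zero residual
#' MAD returns all-zero b-scores. The sweep loop is implemented directly
#' because the stopping rule is on the largest sweep, which
#' [stats::medpolish()]'s sum-based criterion cannot express (it can halt
#' on a sum plateau while residuals still move); `medpolish` driven to a
#' fixed point serves as the independent cross-check in the test suite.
#'
#' @param plate_matrix Numeric rows x columns matrix of one parameter;
#'   missing wells may be `NA`.
#' @param max_iter,tol Iteration cap and max-absolute-sweep tolerance.
#' @param scale Divide residuals by 1.4826 x MAD (the b-score proper);
#'   `FALSE` returns the raw median-polish residuals.
#' @return Matrix of b-scores, same shape as the input.
#' @export
bscore <- function(plate_matrix, max_iter = 1000, tol = 1e-9, scale = TRUE) {
  if (nrow(plate_matrix) < 2 || ncol(plate_matrix) < 2)
    stop_fmt("plate matrix must be at least 2 x 2")
  res <- cpp_medpolish(plate_matrix, tol, as.integer(max_iter))
  dimnames(res) <- dimnames(plate_matrix)
  if (!scale) return(res)
  s <- 1.4826 * stats::median(abs(res), na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    res[] <- ifelse(is.na(res), NA, 0)
    return(res)
  }
  res / s
}

#' Robust z-score against a reference distribution
#'
#' z = (x - median(ref)) / (1.4826 * MAD(ref)). The robust location/scale
#' pair resists the heavy outlier tail typical of screens.
#'
#' @param x Values to score.
#' @param reference Reference (library) distribution; defaults to `x`.
#' @return Numeric vector of z-scores.
#' @export
zscore_robust <- function(x, reference = x) {
  if (sum(is.finite(reference)) < 3)
    stop_fmt("need at least 3 finite reference values")
  s <- stats::mad(reference, na.rm = TRUE)  # constant 1.4826 built in
  if (s == 0) return(ifelse(is.na(x), NA, 0))
  (x - stats::median(reference, na.rm = TRUE)) / s
}

.score_params <- c(nucleus_area = "z_area", nucleus_roundness = "z_roundness",
                   neurite_length = "z_neurite_length",
                   n_segments = "z_n_segments",
                   induced_frac_fos = "z_frac_fos",
                   induced_frac_egr1 = "z_frac_egr1",
                   induced_frac_double = "z_frac_double",
                   nuclei_count = "z_viability")

#' Normalize a paired screen into per-compound z-scores
#'
#' Sequential normalization: per plate and parameter, b-scores remove
#' additive row/column artifacts; per replicate and parameter, robust
#' z-scores place every compound on the library distribution; replicate
#' z-vectors are then averaged per compound. DMSO control wells participate
#' in the plate-level median polish but the z reference is the library
#' itself.
#'
#' @param paired Output of [pair_plates()].
#' @return A `compound_scores` data frame: `compound_id`, the six maturity
#'   z-scores, `z_frac_double` and `z_viability`, averaged over replicates.
#'   DMSO wells are summarized in attribute `dmso`.
#' @export
screen_scores <- function(paired) {
  params <- names(.score_params)
  for (z in .score_params) paired[[z]] <- NA_real_
  for (rep_i in unique(paired$replicate)) {
    for (p in unique(paired$plate)) {
      sel <- paired$replicate == rep_i & paired$plate == p
      sub <- paired[sel, ]
      nrow_p <- max(sub$row); ncol_p <- max(sub$col)
      for (f in params) {
        m <- matrix(NA_real_, nrow_p, ncol_p)
        m[cbind(sub$row, sub$col)] <- sub[[f]]
        b <- bscore(m)
        paired[[.score_params[[f]]]][sel] <- b[cbind(sub$row, sub$col)]
      }
    }
    sel_rep <- paired$replicate == rep_i
    lib_ref <- sel_rep & paired$compound_id != "DMSO"
    for (f in params) {
      z <- .score_params[[f]]
      paired[[z]][sel_rep] <- zscore_robust(paired[[z]][sel_rep],
                                            paired[[z]][lib_ref])
    }
  }
  agg <- stats::aggregate(paired[, .score_params],
                          by = list(compound_id = paired$compound_id), mean)
  dmso <- agg[agg$compound_id == "DMSO", ]
  agg <- agg[agg$compound_id != "DMSO", ]
  agg <- agg[order(agg$compound_id), ]
  rownames(agg) <- NULL
  attr(agg, "dmso") <- dmso
  class(agg) <- c("compound_scores", "data.frame")
  agg
}

#' Exclude toxic compounds by viability z-score
#'
#' A compound is excluded iff its viability z-score (from the viable-nuclei
#' count) is strictly below the threshold; a score exactly at the threshold
#' is retained.
#'
#' @param scores A `compound_scores` data frame.
#' @param threshold Exclusion threshold on the viability z (default -2).
#' @return List with `retained` (data frame) and `excluded` (compound ids).
#' @export
viability_filter <- function(scores, threshold = -2) {
  excl <- scores$z_viability < threshold
  list(retained = scores[!excl, , drop = FALSE],
       excluded = scores$compound_id[excl])
}

#' PCA hit selection on the six-parameter z-matrix
#'
#' Principal components of the compound x 6 z-score matrix (covariance PCA;
#' the z-scores are already on a common robust scale, so no further column
#' scaling is applied). The first component is oriented so the FOS-fraction
#' loading is positive ("more mature" scores positive); remaining
#' components are oriented so their largest-magnitude loading is positive,
#' which removes the eigenvector sign ambiguity. Hits are compounds with
#' PC1 strictly above the threshold. Cluster labels operationalize the
#' screen's phenotypic classes: `maturation_enhancing` (PC1 > threshold),
#' `maturation_inhibiting` (PC1 < -threshold), `non_neuronal_proliferation`
#' (viability z > 2 with neurite z < 0), otherwise `other`.
#'
#' @param scores Retained `compound_scores` (at least 7 compounds).
#' @param pc1_threshold Hit threshold on PC1 (default 4).
#' @return A `screen_result`: list with `compound_id`, `z` (matrix),
#'   `pc_scores`, `loadings`, `explained_variance`,
#'   `low_variance_components`, `cluster_labels`, `hits_pca`,
#'   `pc1_threshold`, `excluded_toxic`, `hits_single_param`.
#' @export
pca_hits <- function(scores, pc1_threshold = 4) {
  six <- c("z_area", "z_roundness", "z_neurite_length", "z_n_segments",
           "z_frac_fos", "z_frac_egr1")
  if (nrow(scores) < 7)
    stop_fmt("PCA hit selection needs at least 7 compounds")
  X <- as.matrix(scores[, six])
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation; sc <- pr$x
  for (j in seq_len(ncol(rot))) {
    flip <- if (j == 1) rot["z_frac_fos", 1] < 0
    else rot[which.max(abs(rot[, j])), j] < 0
    if (flip) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  pc1 <- sc[, 1]
  labels <- rep("other", nrow(scores))
  labels[scores$z_viability > 2 & scores$z_neurite_length < 0] <-
    "non_neuronal_proliferation"
  labels[pc1 < -pc1_threshold] <- "maturation_inhibiting"
  labels[pc1 > pc1_threshold] <- "maturation_enhancing"
  structure(list(
    compound_id = scores$compound_id, z = X, pc_scores = sc, loadings = rot,
    explained_variance = ev,
    low_variance_components = which(pr$sdev < 1e-10),
    cluster_labels = labels,
    hits_pca = scores$compound_id[pc1 > pc1_threshold],
    pc1_threshold = pc1_threshold,
    excluded_toxic = character(0), hits_single_param = character(0)),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d compounds, %d PCA hits (PC1 > %g), %d excluded toxic\n",
              length(x$compound_id), length(x$hits_pca), x$pc1_threshold,
              length(x$excluded_toxic)))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.2f", x$explained_variance), collapse = " ")))
  invisible(x)
}

#' Top-k single-parameter hits
#'
#' For each named z-score column, the top-k compounds by descending score
#' after removing already-selected ids; the union is returned. Ties are
#' broken by ascending compound id and flagged via the `tied` attribute.
#'
#' @param scores A `compound_scores` data frame.
#' @param params Score columns (default total neurite length and the
#'   double-IEG induced fraction).
#' @param k Number of compounds per parameter.
#' @param exclude Compound ids already selected (e.g. PCA hits).
#' @return Character vector (union of per-parameter top-k), with attribute
#'   `tied` marking whether a tie at any selection boundary occurred.
#' @export
single_param_hits <- function(scores,
                              params = c("z_neurite_length", "z_frac_double"),
                              k = 5, exclude = character()) {
  cand <- scores[!scores$compound_id %in% exclude, ]
  if (k > nrow(cand)) stop_fmt("k = %d exceeds the %d retained candidates",
                               k, nrow(cand))
  tied <- FALSE
  sel <- character(0)
  for (p in params) {
    ord <- cand[order(-cand[[p]], cand$compound_id), ]
    top <- ord[seq_len(k), ]
    if (nrow(ord) > k && ord[[p]][k + 1] == ord[[p]][k]) tied <- TRUE
    sel <- c(sel, top$compound_id)
  }
  structure(sort(unique(sel)), tied = tied)
}

#' DMSO-normalized validation composite
#'
#' Each of four maturity parameters (nucleus area, nucleus roundness,
#' neurite length, KCl-induced double-IEG fraction) is divided by its
#' same-plate DMSO mean, shielding the composite from plate effects; the
#' composite is the mean of the four ratios, so a DMSO-like well scores 1.
#'
#' @param treated Data frame of treated wells with columns `plate`,
#'   `compound_id` and the four parameters (`nucleus_area`,
#'   `nucleus_roundness`, `neurite_length`, `induced_frac_double`).
#' @param dmso Data frame of DMSO wells with the same columns (at least 3
#'   per plate).
#' @return List with `wells` (per-well ratios and `composite`) and
#'   `compounds` (per-compound mean composite, ranked descending).
#' @export
validation_score <- function(treated, dmso) {
  params <- c("nucleus_area", "nucleus_roundness", "neurite_length",
              "induced_frac_double")
  counts <- table(dmso$plate)
  if (any(counts < 3))
    stop_fmt("each plate needs at least 3 DMSO wells")
  ref <- stats::aggregate(dmso[, params], by = list(plate = dmso$plate), mean)
  m <- match(treated$plate, ref$plate)
  if (any(is.na(m))) stop_fmt("treated wells reference plates without DMSO")
  wells <- treated
  for (p in params) wells[[paste0("ratio_", p)]] <- treated[[p]] / ref[[p]][m]
  wells$composite <- rowMeans(wells[, paste0("ratio_", params)])
  comp <- stats::aggregate(list(composite = wells$composite),
                           by = list(compound_id = wells$compound_id), mean)
  comp <- comp[order(-comp$composite), ]
  comp$rank <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  list(wells = wells, compounds = comp)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Dose-response trend on validation composites
#'
#' Summarizes per-dose mean composites and tests for a monotone trend with
#' the Spearman rank correlation of the composite against log10(dose).
#' Significance uses a one-sided permutation test: exhaustive over all
#' composite permutations when there are at most 10^5 of them, otherwise
#' 10^4 Monte-Carlo draws under a fixed seed. The `dose_dependent` flag
#' requires a positive correlation with permutation p < 0.05.
#'
#' @param dose Dose per well, nM (at least 3 distinct levels).
#' @param composite Validation composite per well.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List with `per_dose` (mean composite per dose), `rho`,
#'   `p_value`, `dose_dependent` and `method`.
#' @export
dose_response <- function(dose, composite, seed = 1L) {
  if (length(dose) != length(composite))
    stop_fmt("dose and composite lengths differ")
  if (length(unique(dose)) < 3) stop_fmt("need at least 3 dose levels")
  per_dose <- stats::aggregate(list(mean_composite = composite),
                               by = list(dose = dose), mean)
  per_dose <- per_dose[order(per_dose$dose), ]
  rx <- rank(log10(dose)); ry <- rank(composite)
  n <- length(dose)
  rx_c <- rx - mean(rx); ry_c <- ry - mean(ry)
  denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  if (denom == 0)  # a constant composite carries no trend
    return(list(per_dose = per_dose, rho = 0, p_value = 1,
                dose_dependent = FALSE, method = "degenerate"))
  rho <- sum(rx_c * ry_c) / denom
  if (factorial(n) <= 1e5) {
    perms <- all_permutations(n)
    stat <- (matrix(ry_c[perms], nrow(perms), n) %*% rx_c) / denom
    p <- mean(stat >= rho - 1e-12)
    method <- "exhaustive"
  } else {
    stat <- with_seed(seed, vapply(seq_len(1e4), function(i)
      sum(rx_c * sample(ry_c)) / denom, numeric(1)))
    p <- (1 + sum(stat >= rho - 1e-12)) / (1 + length(stat))
    method <- "monte-carlo"
  }
  list(per_dose = per_dose, rho = rho, p_value = p,
       dose_dependent = rho > 0 && p < 0.05, method = method)
}
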