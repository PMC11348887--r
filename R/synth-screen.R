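# Feature-level simulation of a whole compound screen: per-well maturity
# feature vectors for paired stimulated/unstimulated 384-well plates in
# duplicate, with planted hits, planted toxic compounds and additive
# row/column plate artifacts.

#' Specification of a synthetic compound library screen
#'
#' @param n_compounds Library size (default 2,688).
#' @param n_replicates Independent screen replicates (default 2).
#' @param plate_shape Rows x columns per plate (default 16 x 24, i.e.
#'   384-well).
#' @param n_toxic Number of strongly toxic compounds planted.
#' @param toxic_effect_sd Depression of the viable-nuclei count for toxic
#'   compounds, in multiples of the well-to-well noise SD.
#' @param n_hits Number of maturation-enhancing hits planted.
#' @param hit_effect_sd Elevation of every maturity parameter for hits, in
#'   multiples of each feature's well-to-well noise SD.
#' @param row_effect_sd,col_effect_sd Additive plate-artifact scale, in
#'   multiples of each feature's noise SD.
#' @param controls_per_plate DMSO control wells per plate, placed in the
#'   outermost usable columns.
#' @param seed Integer seed.
#' @return A `library_spec`.
#' @export
library_spec <- function(n_compounds = 2688, n_replicates = 2,
                         plate_shape = c(16L, 24L),
                         n_toxic = 325, toxic_effect_sd = 6,
                         n_hits = 40, hit_effect_sd = 6,
                         row_effect_sd = 1, col_effect_sd = 1,
                         controls_per_plate = 2 * plate_shape[1],
                         seed = 1L) {
  spec <- list(n_compounds = as.integer(n_compounds),
               n_replicates = as.integer(n_replicates),
               plate_shape = as.integer(plate_shape),
               n_toxic = as.integer(n_toxic),
               toxic_effect_sd = toxic_effect_sd,
               n_hits = as.integer(n_hits), hit_effect_sd = hit_effect_sd,
               row_effect_sd = row_effect_sd, col_effect_sd = col_effect_sd,
               controls_per_plate = as.integer(controls_per_plate),
               seed = as.integer(seed))
  if (spec$n_toxic + spec$n_hits > spec$n_compounds)
    stop_fmt("n_toxic + n_hits exceeds the library size")
  wells <- prod(spec$plate_shape)
  if (spec$controls_per_plate >= wells)
    stop_fmt("controls_per_plate leaves no compound wells")
  spec$compound_wells_per_plate <- wells - spec$controls_per_plate
  spec$n_plates <- ceiling(spec$n_compounds / spec$compound_wells_per_plate)
  class(spec) <- "library_spec"
  spec
}

# Per-feature generative baselines: stimulated / unstimulated means and the
# well-to-well noise SD. Morphology is condition-independent; IEG fractions
# rise under depolarization. Values model an immature hPSC-derived culture.
.screen_baselines <- function() {
  data.frame(
    feature = c("nucleus_area", "nucleus_roundness", "neurite_length",
                "n_segments", "frac_fos", "frac_egr1", "frac_double",
                "nuclei_count"),
    stim   = c(90, 0.82, 600, 4, 0.25, 0.22, 0.15, 1600),
    unstim = c(90, 0.82, 600, 4, 0.05, 0.05, 0.02, 1600),
    sd     = c(3, 0.015, 30, 0.3, 0.03, 0.03, 0.02, 120),
    hit_affected  = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stim_only     = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    bounded01     = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

well_address <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Simulate per-well screen features with planted ground truth
#'
#' Lays the library out across plates (controls in the outermost usable
#' columns, compounds row-major elsewhere) and generates, for every
#' replicate and for paired stimulated/unstimulated plates, a per-well
#' feature vector: the six maturity parameters, the double-IEG fraction and
#' the viable-nuclei count. Planted effects: hits elevate every maturity
#' feature (IEG fractions only under stimulation); toxic compounds depress
#' the nuclei count; additive row and column artifacts are drawn per plate
#' and per feature.
#'
#' @param lib A [library_spec()].
#' @return A `plate_features` data frame (plate, well, row, col, condition,
#'   compound_id, replicate, features, nuclei_count) with attributes
#'   `truth` (compound_id, class in inert/hit/toxic) and `lib`.
#' @export
simulate_screen_features <- function(lib) {
  stopifnot(inherits(lib, "library_spec"))
  with_seed(lib$seed, simulate_screen_impl(lib))
}

simulate_screen_impl <- function(lib) {
  nrow_p <- lib$plate_shape[1]; ncol_p <- lib$plate_shape[2]
  n_ctrl_cols <- ceiling(lib$controls_per_plate / nrow_p)
  ctrl_cols <- c(seq_len(ceiling(n_ctrl_cols / 2)),
                 ncol_p - seq_len(floor(n_ctrl_cols / 2)) + 1L)
  base <- .screen_baselines()

  ids <- sprintf("C%04d", seq_len(lib$n_compounds))
  cls <- rep("inert", lib$n_compounds)
  special <- sample.int(lib$n_compounds, lib$n_toxic + lib$n_hits)
  cls[special[seq_len(lib$n_toxic)]] <- "toxic"
  if (lib$n_hits > 0)
    cls[special[lib$n_toxic + seq_len(lib$n_hits)]] <- "hit"
  truth <- data.frame(compound_id = ids, class = cls,
                      stringsAsFactors = FALSE)

  # static layout shared by every plate instance
  layout <- do.call(rbind, lapply(seq_len(lib$n_plates), function(p) {
    grid <- expand.grid(row = seq_len(nrow_p), col = seq_len(ncol_p))
    grid <- grid[order(grid$row, grid$col), ]
    is_ctrl <- grid$col %in% ctrl_cols
    cmp <- rep(NA_character_, nrow(grid))
    cmp[is_ctrl] <- "DMSO"
    free <- which(!is_ctrl)
    first <- (p - 1) * lib$compound_wells_per_plate
    take <- min(lib$compound_wells_per_plate, lib$n_compounds - first)
    if (take > 0) cmp[free[seq_len(take)]] <- ids[first + seq_len(take)]
    data.frame(plate = p, row = grid$row, col = grid$col,
               well = well_address(grid$row, grid$col),
               compound_id = cmp, stringsAsFactors = FALSE)
  }))
  layout <- layout[!is.na(layout$compound_id), ]

  effect_of <- function(compound_id, feature_row, condition) {
    eff <- numeric(length(compound_id))
    k <- match(compound_id, ids)
    is_hit <- !is.na(k) & cls[pmax(k, 1)] == "hit"
    is_tox <- !is.na(k) & cls[pmax(k, 1)] == "toxic"
    if (feature_row$feature == "nuclei_count")
      eff[is_tox] <- -lib$toxic_effect_sd * feature_row$sd
    else if (feature_row$hit_affected &&
             (!feature_row$stim_only || condition == "stimulated"))
      eff[is_hit] <- lib$hit_effect_sd * feature_row$sd
    eff
  }

  out <- list()
  for (rep_i in seq_len(lib$n_replicates)) {
    for (cond in c("stimulated", "unstimulated")) {
      for (p in seq_len(lib$n_plates)) {
        lay <- layout[layout$plate == p, ]
        vals <- lay[, c("plate", "row", "col", "well", "compound_id")]
        vals$condition <- cond
        vals$replicate <- rep_i
        for (f in seq_len(nrow(base))) {
          b <- base[f, ]
          mu <- if (cond == "stimulated") b$stim else b$unstim
          row_eff <- stats::rnorm(nrow_p, 0, lib$row_effect_sd * b$sd)
          col_eff <- stats::rnorm(ncol_p, 0, lib$col_effect_sd * b$sd)
          x <- mu + effect_of(lay$compound_id, b, cond) +
            row_eff[lay$row] + col_eff[lay$col] +
            stats::rnorm(nrow(lay), 0, b$sd)
          if (b$bounded01) x <- pmin(pmax(x, 0), 1)
          if (b$feature == "nuclei_count") x <- pmax(round(x), 0)
          vals[[b$feature]] <- x
        }
        out[[length(out) + 1L]] <- vals
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("plate", "well", "row", "col", "condition", "compound_id",
                 "replicate", base$feature)]
  attr(res, "truth") <- truth
  attr(res, "lib") <- lib
  class(res) <- c("plate_features", "data.frame")
  res
}
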