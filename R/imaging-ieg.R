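#' Score immediate-early-gene positivity within nuclear masks
#'
#' Computes the mean FOS and EGR-1 intensity inside each segmented nucleus
#' and calls a nucleus positive when the mean is strictly above the channel
#' threshold (ties at the threshold are negative). Double positivity
#' requires both. Fractions are positives over the total nucleus count.
#'
#' @param nuclei A `nucleus_set` from [segment_nuclei()].
#' @param fos,egr1 Numeric matrices (AFU) with the same shape as the
#'   segmentation.
#' @param cfg A [threshold_config()].
#' @return List with `records` (the nucleus table extended with `mean_fos`,
#'   `mean_egr1`, `fos_pos`, `egr1_pos`, `double_pos`) and `fractions`
#'   (named vector `frac_fos`, `frac_egr1`, `frac_double`).
#' @export
score_ieg <- function(nuclei, fos, egr1, cfg = threshold_config()) {
  if (!identical(dim(nuclei$labels), dim(fos)) ||
      !identical(dim(nuclei$labels), dim(egr1)))
    stop_fmt("IEG rasters and segmentation have different shapes")
  rec <- nuclei$records
  n <- nrow(rec)
  if (n == 0) {
    rec$mean_fos <- rec$mean_egr1 <- numeric(0)
    rec$fos_pos <- rec$egr1_pos <- rec$double_pos <- logical(0)
    return(list(records = rec,
                fractions = c(frac_fos = NA_real_, frac_egr1 = NA_real_,
                              frac_double = NA_real_)))
  }
  idx <- which(nuclei$labels > 0)
  lab <- nuclei$labels[idx]
  mean_by <- function(ch) {
    s <- tapply(ch[idx], lab, mean)
    out <- rep(NA_real_, n)
    out[as.integer(names(s))] <- as.numeric(s)
    out
  }
  rec$mean_fos <- mean_by(fos)
  rec$mean_egr1 <- mean_by(egr1)
  rec$fos_pos <- rec$mean_fos > cfg$fos_afu
  rec$egr1_pos <- rec$mean_egr1 > cfg$egr1_afu
  rec$double_pos <- rec$fos_pos & rec$egr1_pos
  list(records = rec,
       fractions = c(frac_fos = mean(rec$fos_pos),
                     frac_egr1 = mean(rec$egr1_pos),
                     frac_double = mean(rec$double_pos)))
}
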