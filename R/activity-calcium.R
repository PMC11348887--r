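# Calcium-trace analytics: baseline-normalized fluorescence and event
# counting per ROI.

#' Baseline-normalized fluorescence change (dF/F)
#'
#' F0 is a running percentile (default 10th) of the raw trace over a
#' centered window, which tracks slow baseline drift while ignoring the
#' transients themselves; dF/F = (F - F0)/F0 with F0 floored at a small
#' positive constant.
#'
#' @param trace Raw fluorescence series, AFU.
#' @param baseline_percentile Percentile defining F0 (default 10).
#' @param window Window length in frames (default 60).
#' @param floor Minimum F0, AFU.
#' @return Numeric dF/F series of the same length.
#' @export
dff <- function(trace, baseline_percentile = 10, window = 60, floor = 1) {
  n <- length(trace)
  if (n < window) stop_fmt("trace has %d frames; need at least %d", n, window)
  half <- window %/% 2
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::quantile(trace[lo:hi], baseline_percentile / 100, names = FALSE)
  }, numeric(1))
  f0 <- pmax(f0, floor)
  (trace - f0) / f0
}

#' Count calcium transients per ROI
#'
#' An event is an upward crossing of `k` robust noise SDs of the dF/F
#' series that stays supra-threshold for at least `min_frames` frames;
#' crossings within `refractory` frames of the end of an accepted event are
#' merged into it.
#'
#' @param x A `calcium_trace_set`, ROI x frame matrix of raw traces, or a
#'   single dF/F series (when `is_dff = TRUE`).
#' @param k Threshold in noise SDs (default 3).
#' @param min_frames Minimum supra-threshold run length (default 2).
#' @param refractory Merge gap after an event, frames (default 2).
#' @param is_dff Set when `x` is already a dF/F series.
#' @param ... Passed to [dff()].
#' @return Integer vector of event counts (one per ROI), or a single count
#'   for a plain series.
#' @export
count_calcium_spikes <- function(x, k = 3, min_frames = 2, refractory = 2,
                                 is_dff = FALSE, ...) {
  count_one <- function(series, already_dff) {
    d <- if (already_dff) series else dff(series, ...)
    sigma <- stats::mad(d)
    if (sigma == 0) return(0L)
    above <- d > k * sigma
    if (!any(above)) return(0L)
    delta <- diff(c(FALSE, above, FALSE))
    starts <- which(delta == 1); ends <- which(delta == -1) - 1L
    lens <- ends - starts + 1L
    starts <- starts[lens >= min_frames]; ends <- ends[lens >= min_frames]
    if (length(starts) == 0) return(0L)
    count <- 1L; last_end <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] - last_end > refractory) count <- count + 1L
      last_end <- max(last_end, ends[i])
    }
    count
  }
  if (inherits(x, "calcium_trace_set"))
    return(vapply(seq_len(nrow(x$traces)), function(r)
      count_one(x$traces[r, ], FALSE), integer(1)))
  if (is.matrix(x))
    return(vapply(seq_len(nrow(x)), function(r)
      count_one(x[r, ], is_dff), integer(1)))
  count_one(x, is_dff)
}
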