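# MEA analytics: threshold spike detection on raw traces, top-fraction
# firing-rate summaries, and array-wide network-burst detection.

#' Detect spikes on a raw voltage trace
#'
#' The noise scale is estimated robustly (median absolute value / 0.6745,
#' insensitive to the spikes themselves) and events are negative-going
#' threshold crossings at `k` noise SDs. The spike time is the trough of
#' each crossing; events within the refractory period of an accepted spike
#' are dropped. Detection is invariant under amplitude scaling because the
#' threshold is relative to the estimated noise.
#'
#' @param trace Voltage series, uV.
#' @param fs Sampling rate, Hz.
#' @param k Detection threshold in noise SDs (default 9).
#' @param refractory Minimum inter-spike interval, s (default 2 ms).
#' @return A `spike_train` data frame with `time` (s) and `amplitude` (uV,
#'   trough value).
#' @export
detect_spikes <- function(trace, fs, k = 9, refractory = 0.002) {
  if (fs <= 0) stop_fmt("sampling rate must be > 0")
  x <- trace - stats::median(trace)
  sigma <- robust_sigma(x)
  out <- data.frame(time = numeric(0), amplitude = numeric(0))
  if (sigma == 0) return(structure(out, class = c("spike_train", "data.frame")))
  below <- x < -k * sigma
  if (!any(below)) return(structure(out, class = c("spike_train", "data.frame")))
  d <- diff(c(FALSE, below, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  trough_idx <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.min(x[seg])]
  }, integer(1))
  times <- (trough_idx - 1) / fs
  amps <- x[trough_idx]
  keep <- logical(length(times))
  last <- -Inf
  for (i in order(times)) {
    if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
  }
  structure(data.frame(time = times[keep], amplitude = amps[keep]),
            class = c("spike_train", "data.frame"))
}

spike_counts_by_channel <- function(recording, window) {
  sel <- recording$spikes$time <= window
  tabulate(recording$spikes$channel[sel], nbins = recording$n_channels)
}

#' Firing-rate summary of the most active electrodes
#'
#' Ranks channels by spike count in the analysis window and summarizes the
#' top fraction per probe (default 1/64th of the array, i.e. 64 of 4,096
#' electrodes per probe). Ties in the ranking are broken by channel id.
#'
#' @param recordings An `array_recording` or a list of them (one per
#'   probe).
#' @param window Analysis window length, s (default 60).
#' @param top_fraction Fraction of electrodes summarized (default 1/64).
#' @return List with `per_probe` (data frame: probe, n_selected, mean_rate
#'   in spikes/s), `pooled_mean_rate`, and `n_selected_total`.
#' @export
firing_rate_summary <- function(recordings, window = 60, top_fraction = 1 / 64) {
  if (inherits(recordings, "array_recording")) recordings <- list(recordings)
  per <- lapply(seq_along(recordings), function(p) {
    rec <- recordings[[p]]
    counts <- spike_counts_by_channel(rec, window)
    n_sel <- ceiling(top_fraction * rec$n_channels)
    ord <- order(-counts, seq_along(counts))
    sel <- ord[seq_len(n_sel)]
    data.frame(probe = p, n_selected = n_sel,
               mean_rate = mean(counts[sel]) / window)
  })
  per <- do.call(rbind, per)
  list(per_probe = per,
       pooled_mean_rate = sum(per$mean_rate * per$n_selected) /
         sum(per$n_selected),
       n_selected_total = sum(per$n_selected))
}

#' Detect array-wide network bursts
#'
#' Bins spike times across the whole array and thresholds the population
#' firing rate: with `mode = "per_channel"` (default) the rate is total
#' spikes per bin divided by (channels x bin width), i.e. the mean
#' per-channel rate, and a burst is a maximal run of bins at or above
#' `rate_threshold` (default 1 spike/s per channel); `mode = "array"`
#' thresholds the total array rate instead. Bursts separated by less than
#' `merge_gap` are merged. Burst intervals are disjoint and ordered.
#'
#' @param recording An `array_recording`.
#' @param rate_threshold Population-rate threshold, spikes/s (per channel
#'   by default).
#' @param bin Bin width, s.
#' @param merge_gap Bursts closer than this are merged, s.
#' @param mode `"per_channel"` or `"array"`.
#' @return List with `bursts` (data frame: start, end,
#'   participating_channels, peak_rate) and `burst_frequency` (Hz).
#' @export
detect_network_bursts <- function(recording, rate_threshold = 1, bin = 0.1,
                                  merge_gap = 0.2,
                                  mode = c("per_channel", "array")) {
  mode <- match.arg(mode)
  breaks <- seq(0, recording$duration + bin, by = bin)
  counts <- tabulate(findInterval(recording$spikes$time, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  denom <- if (mode == "per_channel") recording$n_channels * bin else bin
  rate <- counts / denom
  above <- rate >= rate_threshold
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      participating_channels = integer(0),
                      peak_rate = numeric(0))
  if (!any(above))
    return(list(bursts = empty, burst_frequency = 0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- (which(d == 1) - 1) * bin
  ends <- (which(d == -1) - 1) * bin
  # merge gaps shorter than merge_gap
  if (length(starts) > 1) {
    keep_s <- c(TRUE, starts[-1] - ends[-length(ends)] >= merge_gap)
    grp <- cumsum(keep_s)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  bursts <- data.frame(start = as.numeric(starts), end = as.numeric(ends))
  bursts$participating_channels <- vapply(seq_len(nrow(bursts)), function(i) {
    sel <- recording$spikes$time >= bursts$start[i] &
      recording$spikes$time < bursts$end[i]
    length(unique(recording$spikes$channel[sel]))
  }, integer(1))
  bursts$peak_rate <- vapply(seq_len(nrow(bursts)), function(i) {
    i0 <- floor(bursts$start[i] / bin) + 1
    i1 <- ceiling(bursts$end[i] / bin)
    max(rate[i0:min(i1, length(rate))])
  }, numeric(1))
  list(bursts = bursts,
       burst_frequency = nrow(bursts) / recording$duration)
}
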