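# Simulation of high-density multielectrode-array recordings: per-channel
# spike times for the full 64 x 64 grid, planted synchronized network
# bursts, and optional raw voltage traces (noise + biphasic spike
# waveforms) for a subset of channels.

#' Specification of a simulated MEA recording
#'
#' @param n_channels Electrode count (default 4,096, a 64 x 64 grid).
#' @param duration Recording length, s.
#' @param sampling_rate Sampling rate for raw traces, Hz.
#' @param noise_sd Voltage noise SD, uV.
#' @param baseline_rate Asynchronous firing rate per channel, spikes/s.
#' @param spike_amplitude Trough amplitude of planted spikes, in multiples
#'   of `noise_sd`.
#' @param burst_rate Planted network-burst rate, Hz (0 disables bursts).
#' @param burst_participation Fraction of channels firing in each burst.
#' @param burst_width Duration of each planted burst window, s.
#' @param trace_channels Channel ids for which raw voltage traces are
#'   synthesized (empty for spike-table-only simulation).
#' @param seed Integer seed.
#' @return An `mea_sim_spec`.
#' @export
mea_sim_spec <- function(n_channels = 4096, duration = 60,
                         sampling_rate = 12500, noise_sd = 5,
                         baseline_rate = 0.1, spike_amplitude = 12,
                         burst_rate = 0, burst_participation = 0.5,
                         burst_width = 0.15,
                         trace_channels = integer(0), seed = 1L) {
  if (burst_rate < 0) stop_fmt("burst_rate must be >= 0")
  if (burst_participation < 0 || burst_participation > 1)
    stop_fmt("burst_participation must be a fraction")
  structure(list(n_channels = as.integer(n_channels), duration = duration,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 baseline_rate = baseline_rate,
                 spike_amplitude = spike_amplitude, burst_rate = burst_rate,
                 burst_participation = burst_participation,
                 burst_width = burst_width,
                 trace_channels = as.integer(trace_channels),
                 seed = as.integer(seed)),
            class = "mea_sim_spec")
}

# Biphasic extracellular spike template: sharp negative trough followed by
# a slower positive rebound. `fs` in Hz; amplitude in uV (trough depth).
spike_template <- function(fs, amplitude) {
  t <- seq(0, 0.002, by = 1 / fs)
  w <- -amplitude * exp(-((t - 0.0005) / 0.00015)^2) +
    0.35 * amplitude * exp(-((t - 0.0011) / 0.0003)^2)
  w
}

#' Simulate an MEA recording with planted spikes and network bursts
#'
#' Spike times for every channel are drawn as a homogeneous Poisson
#' background plus synchronized planted bursts: `floor(burst_rate *
#' duration)` burst windows, evenly spaced with small jitter, in which a
#' random `burst_participation` fraction of channels each fire once. Raw
#' voltage traces (Gaussian noise plus biphasic waveforms at the channel's
#' spike times) are synthesized for `trace_channels` only, keeping the
#' default 4,096-channel simulation desk-scale.
#'
#' @param spec An [mea_sim_spec()].
#' @return An `array_recording`: list with `spikes` (channel, time),
#'   `traces` (sample x channel matrix or NULL), `trace_channels`,
#'   `n_channels`, `grid`, `duration`, `sampling_rate`, and `truth`
#'   (`bursts` data frame and per-trace-channel planted spike times).
#' @export
simulate_mea <- function(spec) {
  stopifnot(inherits(spec, "mea_sim_spec"))
  with_seed(spec$seed, simulate_mea_impl(spec))
}

simulate_mea_impl <- function(spec) {
  n_base <- stats::rpois(spec$n_channels, spec$baseline_rate * spec$duration)
  spikes <- data.frame(
    channel = rep.int(seq_len(spec$n_channels), n_base),
    time = stats::runif(sum(n_base), 0, spec$duration))

  bursts <- data.frame(start = numeric(0), end = numeric(0),
                       participating_channels = integer(0))
  if (spec$burst_rate > 0) {
    n_bursts <- floor(spec$burst_rate * spec$duration)
    period <- 1 / spec$burst_rate
    centers <- (seq_len(n_bursts) - 0.5) * period +
      stats::runif(n_bursts, -0.05, 0.05) * period
    centers <- pmin(pmax(centers, spec$burst_width),
                    spec$duration - spec$burst_width)
    for (b in centers) {
      nch <- round(spec$burst_participation * spec$n_channels)
      ch <- sample.int(spec$n_channels, nch)
      t0 <- b - spec$burst_width / 2
      spikes <- rbind(spikes, data.frame(
        channel = ch, time = t0 + stats::runif(nch, 0, spec$burst_width)))
      bursts <- rbind(bursts, data.frame(
        start = t0, end = t0 + spec$burst_width,
        participating_channels = nch))
    }
  }
  spikes <- spikes[order(spikes$channel, spikes$time), ]
  rownames(spikes) <- NULL

  traces <- NULL; planted <- NULL
  if (length(spec$trace_channels) > 0) {
    ns <- round(spec$duration * spec$sampling_rate)
    tmpl <- spike_template(spec$sampling_rate,
                           spec$spike_amplitude * spec$noise_sd)
    traces <- matrix(stats::rnorm(ns * length(spec$trace_channels),
                                  0, spec$noise_sd),
                     ns, length(spec$trace_channels))
    planted <- vector("list", length(spec$trace_channels))
    names(planted) <- as.character(spec$trace_channels)
    for (k in seq_along(spec$trace_channels)) {
      tt <- spikes$time[spikes$channel == spec$trace_channels[k]]
      # enforce a refractory gap so planted events are unambiguous
      if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) > 0.004)]
      planted[[k]] <- tt
      for (t0 in tt) {
        i0 <- round(t0 * spec$sampling_rate) + 1L
        idx <- i0:min(ns, i0 + length(tmpl) - 1L)
        traces[idx, k] <- traces[idx, k] + tmpl[seq_along(idx)]
      }
    }
  }

  side <- round(sqrt(spec$n_channels))
  structure(list(spikes = spikes, traces = traces,
                 trace_channels = spec$trace_channels,
                 n_channels = spec$n_channels,
                 grid = c(side, side), duration = spec$duration,
                 sampling_rate = spec$sampling_rate,
                 truth = list(bursts = bursts, planted_spikes = planted)),
            class = "array_recording")
}

#' @export
print.array_recording <- function(x, ...) {
  cat(sprintf("<array_recording> %d channels (%dx%d), %.0f s, %d spikes, %d planted bursts\n",
              x$n_channels, x$grid[1], x$grid[2], x$duration,
              nrow(x$spikes), nrow(x$truth$bursts)))
  invisible(x)
}
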