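#' Specification of a simulated calcium-imaging recording
#'
#' Defaults follow the acquisition schedule of the assay: one frame every
#' 5 s for 20 min, i.e. 240 frames.
#'
#' @param n_rois Number of regions of interest.
#' @param frame_interval Seconds between frames (default 5).
#' @param duration Recording length, s (default 1,200); must be an integer
#'   multiple of `frame_interval`.
#' @param baseline Resting fluorescence, AFU.
#' @param transient_amplitude Peak transient amplitude above baseline, AFU.
#' @param transient_decay Exponential decay constant of transients, frames.
#' @param events_per_roi Planted transients per ROI.
#' @param noise_sd Frame noise SD, AFU.
#' @param seed Integer seed.
#' @return A `calcium_sim_spec`.
#' @export
calcium_sim_spec <- function(n_rois = 20, frame_interval = 5, duration = 1200,
                             baseline = 1000, transient_amplitude = 800,
                             transient_decay = 2, events_per_roi = 5,
                             noise_sd = 30, seed = 1L) {
  frames <- duration / frame_interval
  if (abs(frames - round(frames)) > 1e-9)
    stop_fmt("duration (%g s) is not a multiple of frame_interval (%g s)",
             duration, frame_interval)
  if (transient_amplitude <= 0) stop_fmt("transient_amplitude must be > 0")
  structure(list(n_rois = as.integer(n_rois),
                 frame_interval = frame_interval, duration = duration,
                 n_frames = as.integer(round(frames)), baseline = baseline,
                 transient_amplitude = transient_amplitude,
                 transient_decay = transient_decay,
                 events_per_roi = as.integer(events_per_roi),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "calcium_sim_spec")
}

#' Simulate ROI calcium traces with planted transients
#'
#' Each ROI trace is baseline plus Gaussian noise plus exponentially
#' decaying transients at planted frames (minimum separation 8 frames so
#' events are unambiguous).
#'
#' @param spec A [calcium_sim_spec()].
#' @return A `calcium_trace_set`: list with `traces` (ROI x frame matrix,
#'   AFU), `frame_interval`, `duration`, and `truth` (data frame of roi,
#'   frame).
#' @export
simulate_calcium <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  with_seed(spec$seed, {
    nf <- spec$n_frames
    traces <- matrix(spec$baseline +
                       stats::rnorm(spec$n_rois * nf, 0, spec$noise_sd),
                     spec$n_rois, nf)
    truth <- data.frame(roi = integer(0), frame = integer(0))
    kernel_len <- max(3L, ceiling(6 * spec$transient_decay))
    kernel <- spec$transient_amplitude *
      exp(-(seq_len(kernel_len) - 1) / spec$transient_decay)
    for (r in seq_len(spec$n_rois)) {
      if (spec$events_per_roi == 0) next
      candidates <- seq(5L, nf - kernel_len, by = 1L)
      frames <- integer(0)
      for (e in seq_len(spec$events_per_roi)) {
        ok <- candidates[vapply(candidates, function(f)
          length(frames) == 0 || min(abs(frames - f)) >= 8, logical(1))]
        if (length(ok) == 0) break
        f <- ok[sample.int(length(ok), 1)]
        frames <- c(frames, f)
      }
      frames <- sort(frames)
      for (f in frames) {
        idx <- f:min(nf, f + kernel_len - 1L)
        traces[r, idx] <- traces[r, idx] + kernel[seq_along(idx)]
      }
      if (length(frames) > 0)
        truth <- rbind(truth, data.frame(roi = r, frame = frames))
    }
    calcium_trace_set(traces, spec$frame_interval, spec$duration,
                      truth = truth)
  })
}

#' Construct (and validate) a calcium trace set
#'
#' @param traces ROI x frame matrix, AFU.
#' @param frame_interval Seconds between frames.
#' @param duration Declared recording length, s; the frame count must equal
#'   `duration / frame_interval` exactly.
#' @param truth Optional planted-event table.
#' @return A `calcium_trace_set`.
#' @export
calcium_trace_set <- function(traces, frame_interval = 5, duration = 1200,
                              truth = NULL) {
  expected <- duration / frame_interval
  if (abs(ncol(traces) - expected) > 1e-9)
    stop_fmt("frame count %d does not match schedule %g s / %g s = %g frames",
             ncol(traces), duration, frame_interval, expected)
  structure(list(traces = traces, frame_interval = frame_interval,
                 duration = duration, truth = truth),
            class = "calcium_trace_set")
}

#' @export
print.calcium_trace_set <- function(x, ...) {
  cat(sprintf("<calcium_trace_set> %d ROIs x %d frames (%g s @ %g s/frame)\n",
              nrow(x$traces), ncol(x$traces), x$duration, x$frame_interval))
  invisible(x)
}
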