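# File round-tripping: multi-page TIFF fields with JSON sidecars, per-well
# feature CSVs, spike tables and calcium matrices. CSV dialect: comma
# separated, UTF-8, mandatory header, '.' decimal.

#' Write an image field as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit page per channel in the fixed order DAPI, MAP2, FOS, EGR1,
#' SYN1, PSD95 (present channels only); pixel size, condition, seed,
#' channel order and ground truth go to `<path>.json`.
#'
#' @param field An `image_field`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  order_ref <- c("DAPI", "MAP2", "FOS", "EGR1", "SYN1", "PSD95")
  chans <- field$channels[intersect(order_ref, names(field$channels))]
  pages <- lapply(chans, function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size = field$pixel_size,
                  condition = field$condition,
                  channels = names(chans),
                  seed = field$spec$seed %||% NA,
                  preset = field$spec$preset_name %||% NA,
                  ground_truth = field$ground_truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read an image field written by [write_field_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return An `image_field`.
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- side$channels
  gt <- lapply(side$ground_truth, function(tb)
    if (is.list(tb) && length(tb)) as.data.frame(tb) else
      as.data.frame(tb))
  structure(list(channels = channels, pixel_size = side$pixel_size,
                 condition = side$condition,
                 spec = list(preset_name = side$preset, seed = side$seed),
                 ground_truth = gt),
            class = "image_field")
}

#' Write / read per-well screen feature tables
#'
#' @param features A `plate_features` data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); a `plate_features` data frame (read).
#' @export
write_plate_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate", "well", "row", "col", "condition", "compound_id",
              "replicate")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0)
    stop_fmt("plate CSV missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  class(d) <- c("plate_features", "data.frame")
  d
}

#' Write / read spike tables (channel, time_s)
#'
#' @param spikes Data frame with `channel` and `time` columns (an
#'   `array_recording$spikes` table).
#' @param path CSV path.
#' @export
write_spike_csv <- function(spikes, path) {
  utils::write.csv(data.frame(channel = spikes$channel,
                              time_s = spikes$time), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("channel", "time_s") %in% names(d)))
    stop_fmt("spike CSV needs columns channel, time_s")
  data.frame(channel = as.integer(d$channel), time = d$time_s)
}

#' Write / read a calcium ROI x frame matrix
#'
#' @param ca A `calcium_trace_set`.
#' @param path CSV path; rows are ROIs, columns frames.
#' @param frame_interval,duration Acquisition schedule used on read.
#' @export
write_calcium_csv <- function(ca, path) {
  m <- as.data.frame(ca$traces)
  names(m) <- sprintf("frame%03d", seq_len(ncol(m)))
  utils::write.csv(cbind(roi = seq_len(nrow(m)), m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calcium_csv
#' @export
read_calcium_csv <- function(path, frame_interval = 5, duration = 1200) {
  d <- utils::read.csv(path)
  traces <- as.matrix(d[, setdiff(names(d), "roi"), drop = FALSE])
  dimnames(traces) <- NULL
  calcium_trace_set(traces, frame_interval, duration)
}
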