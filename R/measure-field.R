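#' Measure the maturity feature vector of a field
#'
#' Runs the full imaging pipeline on one multi-channel field: nucleus
#' segmentation and morphometry, neurite tracing, IEG scoring, and -- when
#' SYN1/PSD95 channels are present -- puncta detection and apposition
#' counting. Per-nucleus neurite values are the field totals divided by the
#' nucleus count (no per-cell assignment); with zero nuclei they are
#' reported as missing.
#'
#' @param field An `image_field` (from [render_field()] or
#'   [read_field_tiff()]) or a named list of channel matrices with at least
#'   DAPI, MAP2, FOS and EGR1.
#' @param cfg A [threshold_config()].
#' @param pixel_size Pixel size, um/px; taken from the field when present.
#' @return A one-row data frame of `field_features`: `n_nuclei`,
#'   `mean_area`, `mean_roundness`, `neurite_length_per_nucleus`,
#'   `segments_per_nucleus`, `frac_fos`, `frac_egr1`, `frac_double`,
#'   `syn1_count`, `psd95_count`, `apposed_count`, `apposed_per_100um`.
#' @export
measure_field <- function(field, cfg = threshold_config(), pixel_size = NULL) {
  channels <- if (inherits(field, "image_field")) field$channels else field
  ps <- pixel_size %||%
    (if (inherits(field, "image_field")) field$pixel_size else 0.65)
  required <- c("DAPI", "MAP2", "FOS", "EGR1")
  missing_ch <- setdiff(required, names(channels))
  if (length(missing_ch) > 0)
    stop_fmt("field is missing required channel(s): %s",
             paste(missing_ch, collapse = ", "))

  nuclei <- segment_nuclei(channels$DAPI, cfg, ps)
  n <- nrow(nuclei$records)
  graph <- trace_neurites(channels$MAP2, nuclei, cfg, ps)
  ieg <- score_ieg(nuclei, channels$FOS, channels$EGR1, cfg)

  has_puncta <- all(c("SYN1", "PSD95") %in% names(channels))
  syn1_count <- psd95_count <- apposed_count <- NA_integer_
  apposed_per_100um <- NA_real_
  if (has_puncta) {
    mask <- graph$skeleton
    syn1 <- detect_puncta(channels$SYN1, cfg, mask, ps)
    psd95 <- detect_puncta(channels$PSD95, cfg, mask, ps)
    app <- count_appositions(syn1, psd95, cfg, graph$total_length, ps)
    syn1_count <- nrow(syn1); psd95_count <- nrow(psd95)
    apposed_count <- app$apposed_count
    apposed_per_100um <- app$apposed_per_100um
  }

  data.frame(
    n_nuclei = n,
    mean_area = if (n) mean(nuclei$records$area_um2) else NA_real_,
    mean_roundness = if (n) mean(nuclei$records$roundness) else NA_real_,
    neurite_length_per_nucleus = if (n) graph$total_length / n else NA_real_,
    segments_per_nucleus = if (n) graph$n_segments / n else NA_real_,
    frac_fos = unname(ieg$fractions["frac_fos"]),
    frac_egr1 = unname(ieg$fractions["frac_egr1"]),
    frac_double = unname(ieg$fractions["frac_double"]),
    syn1_count = syn1_count, psd95_count = psd95_count,
    apposed_count = apposed_count, apposed_per_100um = apposed_per_100um)
}

#' Measure a preset across replicate synthetic fields
#'
#' Renders `n_fields` independent fields of a preset and runs
#' [measure_field()] on each. This is the package's benchmark harness for
#' parameter-recovery studies: sparse plating (the default 25 neurons per
#' field) keeps neurite arbors from overlapping so that per-cell neurite
#' length is attributable, mirroring how sparse benchmark wells are used in
#' practice to validate per-cell tracing.
#'
#' @param preset Preset name, see [field_preset()].
#' @param n_fields Number of fields to render.
#' @param n_neurons Neurons per field.
#' @param seed Base seed; field i uses `seed + i`.
#' @param cfg A [threshold_config()].
#' @param ... Further [field_spec()] overrides.
#' @return Data frame with one `field_features` row per field.
#' @export
measure_preset_fields <- function(preset, n_fields = 8, n_neurons = 25,
                                  seed = 1, cfg = threshold_config(), ...) {
  out <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    fld <- render_field(field_preset(preset, n_neurons = n_neurons,
                                     seed = seed + i, ...))
    out[[i]] <- measure_field(fld, cfg)
  }
  do.call(rbind, out)
}
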