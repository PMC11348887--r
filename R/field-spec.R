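#' Specification of a synthetic microscopy field
#'
#' A `field_spec` fully determines one multi-channel fluorescence field of
#' cultured neurons: how many cells, nuclear geometry, neurite arbor size,
#' the fraction of cells mounting a depolarization-induced immediate-early
#' gene (IEG) response, and (optionally) synaptic puncta channels.
#' Intensities are in arbitrary fluorescence units (AFU) on a 16-bit scale.
#'
#' @param preset_name Label carried along for provenance.
#' @param n_neurons Number of neurons to place in the field.
#' @param nucleus_area_mean Mean nucleus area, um^2.
#' @param nucleus_area_cv Coefficient of variation of nucleus area.
#' @param roundness_mean Target mean roundness index 4*pi*A/P^2, in (0, 1].
#' @param neurite_length_mean Mean total neurite length per neuron, um.
#' @param branches_per_neuron Target number of neurite segments per neuron.
#' @param ieg_pos_fraction_stim,ieg_pos_fraction_unstim Fraction of neurons
#'   that are IEG-responders under KCl-stimulated / unstimulated conditions.
#' @param fos_pos_intensity,fos_neg_intensity Nuclear FOS intensity (AFU) of
#'   responder and non-responder cells; must straddle the FOS threshold.
#' @param egr1_pos_intensity,egr1_neg_intensity Same for EGR-1.
#' @param puncta_density_syn1,puncta_density_psd95 Puncta per 100 um of
#'   neurite; `NA` omits the synaptic channels.
#' @param apposed_fraction Fraction of PSD95 puncta placed within the
#'   apposition radius of a SYN1 punctum; `NA` when no puncta.
#' @param pixel_size Pixel size, um/px.
#' @param field_shape Integer vector (rows, cols) of the raster, px.
#' @param noise_sd Gaussian read-noise SD, AFU.
#' @param background Background level, AFU.
#' @param condition `"stimulated"` or `"unstimulated"`; selects which IEG
#'   responder fraction applies.
#' @param seed Integer seed making the render deterministic.
#'
#' @return A `field_spec` object (validated list).
#' @seealso [field_preset()], [render_field()]
#' @export
field_spec <- function(preset_name = "custom",
                       n_neurons = 60,
                       nucleus_area_mean = 110,
                       nucleus_area_cv = 0.12,
                       roundness_mean = 0.9,
                       neurite_length_mean = 1000,
                       branches_per_neuron = 8,
                       ieg_pos_fraction_stim = 0.5,
                       ieg_pos_fraction_unstim = 0.05,
                       fos_pos_intensity = 3000,
                       fos_neg_intensity = 200,
                       egr1_pos_intensity = 3500,
                       egr1_neg_intensity = 250,
                       puncta_density_syn1 = NA_real_,
                       puncta_density_psd95 = NA_real_,
                       apposed_fraction = NA_real_,
                       pixel_size = 0.65,
                       field_shape = c(1024L, 1024L),
                       noise_sd = 50,
                       background = 100,
                       condition = c("stimulated", "unstimulated"),
                       seed = 1L) {
  spec <- list(
    preset_name = preset_name, n_neurons = as.integer(n_neurons),
    nucleus_area_mean = nucleus_area_mean, nucleus_area_cv = nucleus_area_cv,
    roundness_mean = roundness_mean, neurite_length_mean = neurite_length_mean,
    branches_per_neuron = branches_per_neuron,
    ieg_pos_fraction_stim = ieg_pos_fraction_stim,
    ieg_pos_fraction_unstim = ieg_pos_fraction_unstim,
    fos_pos_intensity = fos_pos_intensity,
    fos_neg_intensity = fos_neg_intensity,
    egr1_pos_intensity = egr1_pos_intensity,
    egr1_neg_intensity = egr1_neg_intensity,
    puncta_density_syn1 = puncta_density_syn1,
    puncta_density_psd95 = puncta_density_psd95,
    apposed_fraction = apposed_fraction,
    pixel_size = pixel_size,
    field_shape = as.integer(field_shape),
    noise_sd = noise_sd, background = background,
    condition = match.arg(condition),
    seed = as.integer(seed))
  class(spec) <- "field_spec"
  validate_field_spec(spec)
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec '%s'> %d neurons, %dx%d px @ %.2f um/px\n",
              x$preset_name, x$n_neurons, x$field_shape[1], x$field_shape[2],
              x$pixel_size))
  cat(sprintf("  nucleus %.0f um^2 (roundness %.2f), neurites %.0f um/neuron,\n",
              x$nucleus_area_mean, x$roundness_mean, x$neurite_length_mean))
  cat(sprintf("  IEG responders %.0f%% (stim) / %.0f%% (unstim), condition: %s\n",
              100 * x$ieg_pos_fraction_stim, 100 * x$ieg_pos_fraction_unstim,
              x$condition))
  invisible(x)
}

validate_field_spec <- function(spec) {
  cfg <- threshold_config()
  if (spec$n_neurons < 0) stop_fmt("n_neurons must be >= 0")
  if (spec$nucleus_area_mean <= 0) stop_fmt("nucleus_area_mean must be > 0")
  if (spec$roundness_mean <= 0 || spec$roundness_mean > 1)
    stop_fmt("roundness_mean must lie in (0, 1]")
  assert_fraction(spec$ieg_pos_fraction_stim, "ieg_pos_fraction_stim")
  assert_fraction(spec$ieg_pos_fraction_unstim, "ieg_pos_fraction_unstim")
  if (!is.na(spec$apposed_fraction))
    assert_fraction(spec$apposed_fraction, "apposed_fraction")
  if (spec$fos_pos_intensity <= cfg$fos_afu || spec$fos_neg_intensity >= cfg$fos_afu)
    stop_fmt("FOS intensities must straddle the %g AFU threshold", cfg$fos_afu)
  if (spec$egr1_pos_intensity <= cfg$egr1_afu || spec$egr1_neg_intensity >= cfg$egr1_afu)
    stop_fmt("EGR-1 intensities must straddle the %g AFU threshold", cfg$egr1_afu)
  if (spec$pixel_size <= 0) stop_fmt("pixel_size must be > 0")
  if (length(spec$field_shape) != 2 || any(spec$field_shape < 8))
    stop_fmt("field_shape must be two integers >= 8")
  spec
}

.presets <- function() {
  list(
    # Mature primary rat cortical benchmark, day 14 after plating: large
    # round nuclei (130 um^2, 0.93 roundness), extensive arbors
    # (> 2,500 um per neuron; generative mean 2,800 um) and near-complete
    # KCl-induced IEG responses. No synaptic channels in the benchmark.
    rat_day14 = list(
      nucleus_area_mean = 130, nucleus_area_cv = 0.12,
      roundness_mean = 0.93, neurite_length_mean = 2800,
      branches_per_neuron = 14,
      ieg_pos_fraction_stim = 0.98, ieg_pos_fraction_unstim = 0.03),
    # Immature hPSC-derived cortical neurons at day 21 post-plating. The
    # source study reports no distributional parameters for this state;
    # these values are free choices that are strictly below the rat
    # benchmark on all four maturity axes.
    hpsc_day21 = list(
      nucleus_area_mean = 90, nucleus_area_cv = 0.15,
      roundness_mean = 0.82, neurite_length_mean = 600,
      branches_per_neuron = 4,
      ieg_pos_fraction_stim = 0.25, ieg_pos_fraction_unstim = 0.05,
      puncta_density_syn1 = 8, puncta_density_psd95 = 6,
      apposed_fraction = 0.3),
    # Maturation-cocktail-treated hPSC neurons: intermediate between the
    # immature hPSC state and the rat benchmark.
    hpsc_treated = list(
      nucleus_area_mean = 112, nucleus_area_cv = 0.13,
      roundness_mean = 0.88, neurite_length_mean = 1500,
      branches_per_neuron = 8,
      ieg_pos_fraction_stim = 0.60, ieg_pos_fraction_unstim = 0.05,
      puncta_density_syn1 = 12, puncta_density_psd95 = 10,
      apposed_fraction = 0.5))
}

#' Named field presets for the maturation assay
#'
#' Returns a fully populated [field_spec()] for one of the built-in culture
#' states: `rat_day14` (the mature primary rat cortical benchmark),
#' `hpsc_day21` (immature human pluripotent stem-cell-derived neurons) or
#' `hpsc_treated` (maturation-cocktail-treated hPSC neurons).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [field_spec()] (for example `n_neurons`,
#'   `seed`, `condition`).
#' @return A `field_spec`.
#' @examples
#' field_preset("rat_day14")$nucleus_area_mean # 130
#' @export
field_preset <- function(name, ...) {
  presets <- .presets()
  if (!name %in% names(presets))
    stop_fmt("unknown preset '%s'; valid presets: %s", name,
             paste(names(presets), collapse = ", "))
  args <- utils::modifyList(c(list(preset_name = name), presets[[name]]),
                            list(...))
  do.call(field_spec, args)
}
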