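#' Trace neurites from a MAP2 channel
#'
#' Thresholds the MAP2 raster (Otsu), removes nuclear/somatic regions using
#' the nucleus segmentation, prunes sub-threshold specks, thins the mask to
#' a 1-px-wide skeleton and decomposes the skeleton into branch segments:
#' maximal paths between junction or end nodes. Segment length is the chain
#' length of the path (1 per orthogonal step, sqrt(2) per diagonal step,
#' times the pixel size); isolated loops count as a single segment.
#'
#' @param map2 Numeric matrix, AFU; same shape as the DAPI channel.
#' @param nuclei A `nucleus_set` from [segment_nuclei()], or `NULL` to trace
#'   without somata removal.
#' @param cfg A [threshold_config()].
#' @param pixel_size Pixel size, um/px.
#' @return A `neurite_graph`: list with `total_length` (um), `n_segments`,
#'   `segment_lengths` (um), and `skeleton` (logical matrix).
#' @export
trace_neurites <- function(map2, nuclei = NULL, cfg = threshold_config(),
                           pixel_size = 0.65) {
  if (!is.null(nuclei) && !identical(dim(nuclei$labels), dim(map2)))
    stop_fmt("MAP2 raster and nucleus segmentation have different shapes")
  empty <- structure(list(total_length = 0, n_segments = 0L,
                          segment_lengths = numeric(0),
                          skeleton = matrix(FALSE, nrow(map2), ncol(map2)),
                          pixel_size = pixel_size), class = "neurite_graph")
  if (all(map2 == map2[1])) return(empty)
  if (!identical(cfg$map2_threshold_method, "otsu"))
    stop_fmt("unknown MAP2 threshold method '%s'", cfg$map2_threshold_method)
  th <- EBImage::otsu(EBImage::Image(map2 / 65535), range = c(0, 1))
  mask <- map2 / 65535 > th
  if (!is.null(nuclei)) mask[nuclei$labels > 0] <- FALSE
  if (sum(mask) == 0) return(empty)
  if (cfg$map2_min_component > 1) {
    # label on the dilated mask so 8-connected strands count as one
    # component (bwlabel itself is 4-connected), then size-filter the
    # original pixels
    dil <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(3))
    lab <- EBImage::bwlabel(dil)
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
    if (max(lab) > 0) {
      sizes <- tabulate(lab[mask], nbins = max(lab))
      mask[mask & sizes[pmax(lab, 1)] < cfg$map2_min_component] <- FALSE
    }
  }
  if (sum(mask) == 0) return(empty)
  skel <- cpp_thin(mask)
  seg <- cpp_skeleton_segments(skel)
  structure(list(total_length = seg$total_length * pixel_size,
                 n_segments = seg$n_segments,
                 segment_lengths = seg$segment_lengths * pixel_size,
                 skeleton = skel, pixel_size = pixel_size),
            class = "neurite_graph")
}

#' @export
print.neurite_graph <- function(x, ...) {
  cat(sprintf("<neurite_graph> %.1f um total in %d segments\n",
              x$total_length, x$n_segments))
  invisible(x)
}
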