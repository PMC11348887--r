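#' Imaging thresholds and geometric parameters
#'
#' Collects every tunable constant of the imaging stage. Defaults follow the
#' assay definition: nuclear FOS positivity requires mean intensity strictly
#' above 800 AFU and EGR-1 strictly above 1,000 AFU; nuclei outside the
#' plausible area range are discarded as debris or clumps.
#'
#' @param fos_afu,egr1_afu Strict nuclear positivity thresholds, AFU.
#' @param dapi_min_area,dapi_max_area Valid nucleus area range, um^2.
#' @param dapi_smooth_sigma Gaussian smoothing before nuclear thresholding, px.
#' @param watershed_tolerance h-maxima suppression depth for seed finding, px.
#' @param map2_threshold_method `"otsu"` (the only built-in method).
#' @param map2_min_component Minimum connected-component size kept in the
#'   neurite mask, px (suppresses noise specks).
#' @param puncta_min_sigma,puncta_max_sigma Blob-detection scale range, px.
#' @param puncta_threshold Minimum scale-normalized blob response, AFU.
#' @param apposition_radius Maximum SYN1--PSD95 centroid distance for an
#'   apposed (assembled-synapse) call, um.
#' @param neurite_mask_dilation Dilation of the MAP2 mask defining the
#'   region "surrounding" neurites in which puncta are counted, um.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(fos_afu = 800, egr1_afu = 1000,
                             dapi_min_area = 40, dapi_max_area = 500,
                             dapi_smooth_sigma = 2,
                             watershed_tolerance = 2,
                             map2_threshold_method = "otsu",
                             map2_min_component = 4,
                             puncta_min_sigma = 1, puncta_max_sigma = 3,
                             puncta_threshold = 500,
                             apposition_radius = 1.0,
                             neurite_mask_dilation = 2.0) {
  if (fos_afu <= 0 || egr1_afu <= 0) stop_fmt("AFU thresholds must be > 0")
  if (dapi_min_area >= dapi_max_area)
    stop_fmt("dapi_min_area must be < dapi_max_area")
  structure(list(fos_afu = fos_afu, egr1_afu = egr1_afu,
                 dapi_min_area = dapi_min_area, dapi_max_area = dapi_max_area,
                 dapi_smooth_sigma = dapi_smooth_sigma,
                 watershed_tolerance = watershed_tolerance,
                 map2_threshold_method = map2_threshold_method,
                 map2_min_component = map2_min_component,
                 puncta_min_sigma = puncta_min_sigma,
                 puncta_max_sigma = puncta_max_sigma,
                 puncta_threshold = puncta_threshold,
                 apposition_radius = apposition_radius,
                 neurite_mask_dilation = neurite_mask_dilation),
            class = "threshold_config")
}

# Cauchy-Crofton perimeter estimate from intercept counts in 4 directions
# (horizontal, vertical, both diagonals), computed for every label of a
# labelled matrix at once. Returns a vector indexed by label id.
crofton_perimeter <- function(labels, n_labels = max(labels)) {
  if (n_labels == 0) return(numeric(0))
  nr <- nrow(labels); nc <- ncol(labels)
  count_dir <- function(a, b) {
    # transitions where exactly one side belongs to a region
    d <- a != b
    tab <- tabulate(c(a[d & a > 0], b[d & b > 0]), nbins = n_labels)
    tab
  }
  h <- count_dir(labels[, -nc, drop = FALSE], labels[, -1, drop = FALSE])
  v <- count_dir(labels[-nr, , drop = FALSE], labels[-1, , drop = FALSE])
  d1 <- count_dir(labels[-nr, -nc, drop = FALSE], labels[-1, -1, drop = FALSE])
  d2 <- count_dir(labels[-nr, -1, drop = FALSE], labels[-1, -nc, drop = FALSE])
  # border pixels contribute as transitions to outside
  edge <- function(x) tabulate(x[x > 0], nbins = n_labels)
  h <- h + edge(labels[, 1]) + edge(labels[, nc])
  v <- v + edge(labels[1, ]) + edge(labels[nr, ])
  (pi / 8) * (h + v + (d1 + d2) / sqrt(2))
}

#' Nucleus area and roundness of a labelled region
#'
#' Area is the pixel count scaled by the squared pixel size; roundness is the
#' isoperimetric quotient 4*pi*A/P^2 with the perimeter P estimated by the
#' 4-direction Cauchy-Crofton formula, clipped to at most 1. A perfect disk
#' scores 1; elongation lowers the score.
#'
#' @param mask Logical matrix holding a single region (at least one pixel).
#' @param pixel_size Pixel size, um/px.
#' @return List with `area` (um^2), `perimeter` (um) and `roundness`.
#' @export
nucleus_morphometry <- function(mask, pixel_size = 0.65) {
  if (sum(mask) < 1) stop_fmt("region must contain at least one pixel")
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[mask] <- 1L
  p_px <- crofton_perimeter(labels, 1L)
  area <- sum(mask) * pixel_size^2
  perim <- p_px * pixel_size
  list(area = area, perimeter = perim,
       roundness = min(1, 4 * pi * area / perim^2))
}

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, global Otsu threshold, distance-transform watershed to
#' split touching nuclei, then removal of regions outside the valid area
#' range (debris and clumps), which operationalizes counting only intact
#' nuclei. An all-zero raster yields an empty result, not an error.
#'
#' @param dapi Numeric matrix, AFU.
#' @param cfg A [threshold_config()].
#' @param pixel_size Pixel size, um/px.
#' @return A `nucleus_set`: list with `records` (data frame: label, row, col,
#'   area_um2, perimeter_um, roundness) and `labels` (integer label matrix,
#'   0 = background).
#' @export
segment_nuclei <- function(dapi, cfg = threshold_config(), pixel_size = 0.65) {
  empty <- function() {
    structure(list(records = data.frame(
      label = integer(0), row = numeric(0), col = numeric(0),
      area_um2 = numeric(0), perimeter_um = numeric(0), roundness = numeric(0)),
      labels = matrix(0L, nrow(dapi), ncol(dapi)),
      pixel_size = pixel_size), class = "nucleus_set")
  }
  if (all(dapi == dapi[1])) return(empty())
  img <- EBImage::Image(dapi / 65535)
  sm <- if (cfg$dapi_smooth_sigma > 0)
    EBImage::gblur(img, sigma = cfg$dapi_smooth_sigma) else img
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > th
  if (sum(mask) == 0) return(empty())
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = cfg$watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(dapi), ncol(dapi))
  n <- max(labels)
  if (n == 0) return(empty())
  areas_px <- tabulate(labels[labels > 0], nbins = n)
  areas <- areas_px * pixel_size^2
  keep <- which(areas >= cfg$dapi_min_area & areas <= cfg$dapi_max_area)
  if (length(keep) == 0) return(empty())
  # relabel compactly
  remap <- integer(n); remap[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- remap[labels[pos]]
  n2 <- length(keep)
  perim <- crofton_perimeter(labels, n2) * pixel_size
  area2 <- areas[keep]
  idx <- which(labels > 0)
  rr <- (idx - 1) %% nrow(labels) + 1
  cc <- (idx - 1) %/% nrow(labels) + 1
  lab <- labels[idx]
  cen_r <- tapply(rr, lab, mean)
  cen_c <- tapply(cc, lab, mean)
  rec <- data.frame(label = seq_len(n2),
                    row = as.numeric(cen_r), col = as.numeric(cen_c),
                    area_um2 = area2, perimeter_um = perim,
                    roundness = pmin(1, 4 * pi * area2 / perim^2))
  structure(list(records = rec, labels = labels, pixel_size = pixel_size),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei; mean area %.1f um^2, mean roundness %.3f\n",
              nrow(x$records),
              if (nrow(x$records)) mean(x$records$area_um2) else NA,
              if (nrow(x$records)) mean(x$records$roundness) else NA))
  invisible(x)
}
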