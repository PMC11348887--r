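# Synaptic puncta: scale-space blob detection and apposition counting.

gaussian_kernel <- function(sigma) {
  ext <- max(1L, ceiling(3 * sigma))
  d <- seq.int(-ext, ext)
  k <- exp(-d^2 / (2 * sigma^2))
  k <- outer(k, k)
  k / sum(k)
}

# Local maxima of a matrix: strictly greater than all 8 neighbours.
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- x
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (x > pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  res
}

#' Detect fluorescent puncta by scale-space blob detection
#'
#' Difference-of-Gaussian approximation to the scale-normalized Laplacian:
#' the channel is filtered at a geometric ladder of scales between
#' `puncta_min_sigma` and `puncta_max_sigma`; blob candidates are local
#' maxima (over space and scale) of the normalized response above
#' `puncta_threshold`. When a neurite mask is supplied, detection is
#' restricted to the mask dilated by `neurite_mask_dilation` -- the region
#' containing and immediately surrounding MAP2-positive processes.
#'
#' @param channel Numeric matrix, AFU.
#' @param cfg A [threshold_config()].
#' @param neurite_mask Optional logical matrix (e.g. the skeleton or
#'   thresholded MAP2 mask) restricting where puncta are counted.
#' @param pixel_size Pixel size, um/px (used for the mask dilation).
#' @return Data frame with `row`, `col`, `sigma` and `response` per punctum.
#' @export
detect_puncta <- function(channel, cfg = threshold_config(),
                          neurite_mask = NULL, pixel_size = 0.65) {
  if (length(channel) == 0) stop_fmt("channel raster is empty")
  sigmas <- exp(seq(log(cfg$puncta_min_sigma), log(cfg$puncta_max_sigma),
                    length.out = 4))
  img <- EBImage::Image(channel)
  smooth <- lapply(sigmas * 1.6, function(s)
    EBImage::imageData(EBImage::filter2(img, gaussian_kernel(s))))
  base <- lapply(sigmas, function(s)
    EBImage::imageData(EBImage::filter2(img, gaussian_kernel(s))))
  responses <- lapply(seq_along(sigmas), function(i)
    (base[[i]] - smooth[[i]]) * 1.6)  # scale-normalized DoG, positive blobs
  hits <- NULL
  for (i in seq_along(sigmas)) {
    r <- responses[[i]]
    lm <- local_maxima(r) & r > cfg$puncta_threshold
    if (i > 1) lm <- lm & r >= responses[[i - 1]]
    if (i < length(sigmas)) lm <- lm & r >= responses[[i + 1]]
    if (any(lm)) {
      idx <- which(lm)
      hits <- rbind(hits, data.frame(
        row = (idx - 1) %% nrow(r) + 1,
        col = (idx - 1) %/% nrow(r) + 1,
        sigma = sigmas[i], response = r[idx]))
    }
  }
  if (is.null(hits))
    hits <- data.frame(row = numeric(0), col = numeric(0),
                       sigma = numeric(0), response = numeric(0))
  if (!is.null(neurite_mask) && nrow(hits) > 0) {
    rad <- max(1L, round(cfg$neurite_mask_dilation / pixel_size))
    brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
    dil <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(neurite_mask * 1), brush)) > 0
    hits <- hits[dil[cbind(hits$row, hits$col)], , drop = FALSE]
  }
  # merge near-duplicate detections across scales (keep strongest)
  if (nrow(hits) > 1) {
    hits <- hits[order(-hits$response), ]
    keep <- rep(TRUE, nrow(hits))
    for (j in seq_len(nrow(hits))[-1]) {
      prev <- which(keep[seq_len(j - 1)])
      d2 <- (hits$row[prev] - hits$row[j])^2 + (hits$col[prev] - hits$col[j])^2
      if (any(d2 <= 2.25)) keep[j] <- FALSE
    }
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Count pre/postsynaptic puncta appositions
#'
#' A PSD95 punctum is apposed when its centroid lies within
#' `apposition_radius` of at least one SYN1 centroid; each PSD95 punctum is
#' counted at most once. The density normalizes the apposed count to the
#' total neurite length, reported per 100 um.
#'
#' @param syn1_puncta,psd95_puncta Data frames with `row`/`col` centroids
#'   (px), as returned by [detect_puncta()].
#' @param cfg A [threshold_config()].
#' @param total_length Total neurite length of the field, um.
#' @param pixel_size Pixel size, um/px.
#' @return List with `apposed_count` and `apposed_per_100um`.
#' @export
count_appositions <- function(syn1_puncta, psd95_puncta,
                              cfg = threshold_config(),
                              total_length = NA_real_, pixel_size = 0.65) {
  n_psd <- nrow(psd95_puncta)
  if (n_psd == 0 || nrow(syn1_puncta) == 0)
    return(list(apposed_count = 0L,
                apposed_per_100um = if (is.na(total_length) || total_length <= 0)
                  NA_real_ else 0))
  rad2 <- (cfg$apposition_radius / pixel_size)^2
  apposed <- logical(n_psd)
  block <- 512L
  for (start in seq(1L, n_psd, by = block)) {
    j <- start:min(n_psd, start + block - 1L)
    d2 <- outer(psd95_puncta$row[j], syn1_puncta$row, "-")^2 +
      outer(psd95_puncta$col[j], syn1_puncta$col, "-")^2
    apposed[j] <- apply(d2 <= rad2, 1, any)
  }
  count <- sum(apposed)
  dens <- if (is.na(total_length) || total_length <= 0) NA_real_
  else count / (total_length / 100)
  list(apposed_count = as.integer(count), apposed_per_100um = dens)
}
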