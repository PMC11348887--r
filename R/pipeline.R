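# End-to-end pipeline: configuration, input validation, the screen
# workflow (pair -> b-score -> z-score -> viability filter -> PCA ->
# single-parameter hits), reporting and the run manifest.

#' Pipeline configuration with assay defaults
#'
#' Every numeric constant of the pipeline in one nested list, defaulting to
#' the assay's stated values: FOS/EGR-1 thresholds 800/1,000 AFU, viability
#' exclusion at z < -2, PC1 hit threshold 4, top-5 single-parameter hits,
#' 9-SD spike detection, 1 spike/s network-burst threshold, top-1/64
#' electrode summary, and the 5-s/20-min calcium schedule. The
#' configuration round-trips losslessly through YAML.
#'
#' @param thresholds A [threshold_config()] or override list.
#' @param screen Screen-stage settings (`viability_z`, `pc1_threshold`,
#'   `top_k`, `doses` in nM).
#' @param activity Activity-stage settings (`spike_k`, `burst_rate`,
#'   `burst_bin`, `top_fraction`, `frame_interval`, `calcium_duration`).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = threshold_config(),
                            screen = list(), activity = list(), seed = 1L) {
  screen_def <- list(viability_z = -2, pc1_threshold = 4, top_k = 5,
                     doses = c(30, 100, 300, 1000, 3000, 10000))
  act_def <- list(spike_k = 9, burst_rate = 1, burst_bin = 0.1,
                  top_fraction = 1 / 64, frame_interval = 5,
                  calcium_duration = 1200)
  cfg <- list(thresholds = utils::modifyList(unclass(threshold_config()),
                                             unclass(thresholds)),
              screen = utils::modifyList(screen_def, screen),
              activity = utils::modifyList(act_def, activity),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(thresholds = raw$thresholds %||% list(),
                  screen = raw$screen %||% list(),
                  activity = raw$activity %||% list(),
                  seed = raw$seed %||% 1L)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Validate pipeline inputs
#'
#' Checks whatever is handed in: plate feature tables (well-address grammar
#' for the 16 x 24 layout, paired stimulated/unstimulated plates per
#' replicate), image fields (required channels), calcium trace sets
#' (frame-count/schedule consistency) and spike tables (monotone,
#' non-negative times per channel). Returns every violation rather than
#' stopping at the first.
#'
#' @param x Input object.
#' @param ... Unused.
#' @return Data frame with columns `item` and `message`; zero rows when the
#'   input is valid.
#' @export
validate_inputs <- function(x, ...) UseMethod("validate_inputs")

violation <- function(item, message) data.frame(item = item, message = message,
                                                stringsAsFactors = FALSE)
no_violations <- function() violation(character(0), character(0))

#' @export
validate_inputs.plate_features <- function(x, ...) {
  v <- no_violations()
  bad_well <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", x$well)
  if (any(bad_well))
    v <- rbind(v, violation(unique(x$well[bad_well]),
                            "well address outside A01..P24"))
  if (!all(x$condition %in% c("stimulated", "unstimulated")))
    v <- rbind(v, violation("condition",
                            "conditions must be stimulated/unstimulated"))
  key <- unique(x[, c("plate", "replicate", "condition")])
  both <- stats::aggregate(list(n = key$condition),
                           by = key[, c("plate", "replicate")], length)
  for (i in which(both$n < 2))
    v <- rbind(v, violation(
      sprintf("plate %s replicate %s", both$plate[i], both$replicate[i]),
      "missing paired stimulated/unstimulated plate"))
  v
}

#' @export
validate_inputs.image_field <- function(x, ...) {
  v <- no_violations()
  missing_ch <- setdiff(c("DAPI", "MAP2", "FOS", "EGR1"), names(x$channels))
  for (ch in missing_ch)
    v <- rbind(v, violation(ch, "required channel missing"))
  shapes <- vapply(x$channels, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1)
    v <- rbind(v, violation("channels", "channel shapes differ"))
  v
}

#' @export
validate_inputs.calcium_trace_set <- function(x, ...) {
  v <- no_violations()
  expected <- x$duration / x$frame_interval
  if (abs(ncol(x$traces) - expected) > 1e-9)
    v <- rbind(v, violation("frames", sprintf(
      "frame count %d does not match %g s / %g s schedule",
      ncol(x$traces), x$duration, x$frame_interval)))
  v
}

#' @export
validate_inputs.array_recording <- function(x, ...) {
  v <- no_violations()
  if (any(x$spikes$time < 0 | x$spikes$time > x$duration))
    v <- rbind(v, violation("spikes", "spike times outside [0, duration]"))
  bad <- tapply(x$spikes$time, x$spikes$channel,
                function(t) any(diff(t) < 0))
  if (any(unlist(bad)))
    v <- rbind(v, violation("spikes", "spike times not sorted per channel"))
  v
}

#' Run the full screen workflow
#'
#' Validates the input, pairs stimulated/unstimulated plates, normalizes
#' (b-score per plate, robust z-score per replicate, replicate averaging),
#' excludes toxic compounds, performs PCA hit selection and adds
#' single-parameter hits. When `out_dir` is given, writes
#' `compound_scores.csv`, `screen_result.csv`, `hits.json` and
#' `manifest.json`.
#'
#' @param features A `plate_features` table (e.g. from
#'   [simulate_screen_features()] or [read_plate_csv()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `screen_result` (see [pca_hits()]) with `hits_single_param`
#'   and `excluded_toxic` filled in, plus `files` when written.
#' @export
run_screen <- function(features, config = pipeline_config(), out_dir = NULL) {
  v <- validate_inputs(features)
  if (nrow(v) > 0)
    stop_fmt("invalid screen input: %s",
             paste(sprintf("%s (%s)", v$message, v$item), collapse = "; "))
  paired <- pair_plates(features)
  scores <- screen_scores(paired)
  filt <- viability_filter(scores, config$screen$viability_z)
  result <- pca_hits(filt$retained, config$screen$pc1_threshold)
  result$excluded_toxic <- filt$excluded
  result$hits_single_param <- as.character(
    single_param_hits(filt$retained, k = config$screen$top_k,
                      exclude = result$hits_pca))
  result$scores <- scores
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_scores <- file.path(out_dir, "compound_scores.csv")
    utils::write.csv(as.data.frame(scores), f_scores, row.names = FALSE)
    res_df <- data.frame(compound_id = result$compound_id,
                         result$pc_scores,
                         cluster = result$cluster_labels,
                         hit_pca = result$compound_id %in% result$hits_pca,
                         hit_single_param =
                           result$compound_id %in% result$hits_single_param)
    f_result <- file.path(out_dir, "screen_result.csv")
    utils::write.csv(res_df, f_result, row.names = FALSE)
    f_hits <- file.path(out_dir, "hits.json")
    jsonlite::write_json(list(
      hits_pca = result$hits_pca,
      hits_single_param = result$hits_single_param,
      excluded_toxic = result$excluded_toxic,
      pc1_threshold = result$pc1_threshold,
      viability_z = config$screen$viability_z,
      loadings = as.data.frame(result$loadings),
      explained_variance = result$explained_variance),
      f_hits, digits = NA)
    files <- c(f_scores, f_result, f_hits)
    f_manifest <- file.path(out_dir, "manifest.json")
    write_manifest(config, files, f_manifest)
    result$files <- c(files, f_manifest)
  }
  result
}

#' Write a run manifest
#'
#' Records the configuration hash, seed, file inventory with MD5 checksums,
#' package version and a timestamp, so a deterministic run can be verified
#' byte-for-byte against a previous one.
#'
#' @param config A `pipeline_config`.
#' @param files Character vector of produced files.
#' @param path Manifest output path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))),
    tool_version = as.character(utils::packageVersion("neuromaturity")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable screen report
#'
#' Prints the key readouts of a screen result: compound counts, cluster
#' sizes, hit lists and explained variance; returns the lines invisibly.
#'
#' @param result A `screen_result`.
#' @return Character vector of report lines, invisibly.
#' @export
report <- function(result) {
  lines <- c(
    sprintf("compounds scored: %d", length(result$compound_id)),
    sprintf("excluded toxic: %d", length(result$excluded_toxic)),
    sprintf("PCA hits (PC1 > %g): %d", result$pc1_threshold,
            length(result$hits_pca)),
    sprintf("single-parameter hits: %d", length(result$hits_single_param)),
    sprintf("clusters: %s",
            paste(names(table(result$cluster_labels)),
                  table(result$cluster_labels), sep = "=", collapse = ", ")),
    sprintf("explained variance: %s",
            paste(sprintf("%.3f", result$explained_variance), collapse = " ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
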