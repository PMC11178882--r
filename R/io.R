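# File interfaces: multi-page TIFF movies with JSON sidecars, CSV tables
# for targets / traces / events / spike times, YAML run configuration.

#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per frame; acquisition metadata (frame rate, pixel size,
#' exposure, seed, protocol) goes to `<path>.json`.
#'
#' @param movie an `sv_movie`.
#' @param path output TIFF path.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, meta = list()) {
  stopifnot(inherits(movie, "sv_movie"))
  maxval <- 2^movie$bit_depth - 1
  pages <- lapply(seq_len(dim(movie$counts)[1]), function(j)
    movie$counts[j, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- c(list(frame_rate = movie$frame_rate,
                    pixel_size = movie$pixel_size,
                    exposure_ms = movie$exposure_ms,
                    bit_depth = movie$bit_depth,
                    n_frames = dim(movie$counts)[1]), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return An `sv_movie`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  maxval <- 2^meta$bit_depth - 1
  counts <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (j in seq_along(pages)) counts[j, , ] <- round(pages[[j]] * maxval)
  structure(list(counts = counts,
                 times_ms = (seq_along(pages) - 1) * 1000 / meta$frame_rate,
                 frame_rate = meta$frame_rate, pixel_size = meta$pixel_size,
                 exposure_ms = meta$exposure_ms, bit_depth = meta$bit_depth),
            class = "sv_movie")
}

#' Read / write a target-centroid table
#'
#' CSV with columns `cell_id`, `x_um`, `y_um`.
#'
#' @param targets data.frame (e.g. from [make_multi_target_scene()]).
#' @param path CSV path.
#' @return The data.frame (readers) or `path` invisibly (writers).
#' @export
write_targets_csv <- function(targets, path) {
  stopifnot(all(c("cell_id", "x_um", "y_um") %in% names(targets)))
  utils::write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets_csv
#' @export
read_targets_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "x_um", "y_um") %in% names(df)))
  df
}

#' Read / write ground-truth spike times
#'
#' CSV with columns `cell_id`, `spike_time_ms` (the format shared between
#' the generator and the evaluator).
#'
#' @param spikes data.frame with `cell_id` and `spike_time_ms`, or a list
#'   of per-cell spike-time vectors.
#' @param path CSV path.
#' @export
write_spikes_csv <- function(spikes, path) {
  if (!is.data.frame(spikes)) {
    spikes <- do.call(rbind, lapply(seq_along(spikes), function(i)
      if (length(spikes[[i]]))
        data.frame(cell_id = i, spike_time_ms = spikes[[i]])))
    if (is.null(spikes))
      spikes <- data.frame(cell_id = integer(0), spike_time_ms = numeric(0))
  }
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "spike_time_ms") %in% names(df)))
  df
}

#' Write an extracted trace table
#'
#' CSV with columns `time_ms`, `raw`, `detrended`, `dff_pct`.
#'
#' @param trace an `sv_trace`.
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sv_trace"))
  df <- data.frame(time_ms = trace$time_ms, raw = trace$raw,
                   detrended = if (is.null(trace$detrended)) NA else
                     trace$detrended,
                   dff_pct = if (is.null(trace$dff)) NA else trace$dff)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write pixel weights as a 32-bit float TIFF
#'
#' @param weights a [pixel_weights()].
#' @param path TIFF path.
#' @export
write_weights_tiff <- function(weights, path) {
  stopifnot(inherits(weights, "pixel_weights"))
  tiff::writeTIFF(weights$weights / max(weights$weights), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
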