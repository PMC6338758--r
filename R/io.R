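# File interchange: frame stacks (PNG sequence or multi-page TIFF with a
# JSON sidecar), event logs, outcome tables, copulation calls,
# space-time volumes, and YAML run configuration.

#' Write / read an assay recording
#'
#' Frames go to a zero-padded numbered PNG sequence
#' (`frame_000001.png`, ...) or a multi-page TIFF; arena geometry, frame
#' timestamps and the assay id go to a JSON sidecar (`metadata.json`)
#' next to them.
#'
#' @param rec an [assay_recording()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return `write_recording()`: the directory, invisibly.
#'   `read_recording()`: an [assay_recording()].
#' @export
write_recording <- function(rec, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "assay_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    for (k in seq_along(rec$frames))
      png::writePNG(rec$frames[[k]],
                    file.path(dir, sprintf("frame_%06d.png", k)))
  } else {
    tiff::writeTIFF(rec$frames, file.path(dir, "frames.tif"),
                    bits.per.sample = 8L)
  }
  meta <- list(assay_id = rec$assay_id, times_s = rec$times_s,
               format = format,
               arena = if (!is.null(rec$arena)) unclass(rec$arena))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    stop_input("no metadata.json in ", dir,
               "; expected a sidecar with assay_id, times_s, arena")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- if (identical(meta$format, "tiff")) {
    tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)
  } else {
    files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (length(files) == 0L) stop_input("no frame PNGs in ", dir)
    lapply(files, png::readPNG)
  }
  arena <- if (!is.null(meta$arena)) do.call(arena_spec, meta$arena)
  assay_recording(frames, meta$times_s, arena, meta$assay_id)
}

#' Write / read a behavioral event log
#'
#' CSV schema: `assay_id, fly, event_type, start_s, end_s, truncated`.
#'
#' @param log event-log data.frame.
#' @param path CSV path.
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "fly", "event_type", "start_s", "end_s",
            "truncated")
  if (!all(need %in% names(df)))
    stop_input("event log missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$event_type), STATE_NAMES)
  if (length(bad))
    stop_input("unknown event types: ", paste(bad, collapse = ", "))
  if (any(df$end_s < df$start_s))
    stop_input("event log has end_s < start_s")
  class(df) <- c("event_log", "data.frame")
  df
}

#' Write / read a per-male outcome table
#'
#' CSV schema: `male_id, angle_class, measured_angle_deg,
#' female_genotype, mating_days, copulated, offspring`.
#'
#' @param tab outcome table data.frame.
#' @param path CSV path.
#' @export
write_outcome_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_outcome_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("male_id", "angle_class", "measured_angle_deg",
            "female_genotype", "mating_days", "copulated", "offspring")
  if (!all(need %in% names(df)))
    stop_input("outcome table missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  parse_class(df$angle_class)
  df$mating_days <- as.integer(df$mating_days)
  if (any(df$offspring == 1 & df$copulated == 0))
    stop_input("invalid outcome table: offspring without copulation")
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Write a copulation call as JSON plus an intervals CSV
#'
#' @param call a `copulation_call`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_intervals.csv`.
#' @param assay_id stamped into the intervals CSV.
#' @export
write_copulation_call <- function(call, prefix, assay_id = "assay1") {
  jsonlite::write_json(
    list(assay_id = assay_id, success = call$success,
         latency_to_copulation_s = call$latency_to_copulation_s,
         single_fly_area_px = call$single_fly_area_px,
         interval_s = call$interval_s, intervals = call$intervals),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  iv <- call$intervals
  utils::write.csv(
    data.frame(assay_id = if (nrow(iv)) assay_id else character(0),
               start_s = iv$start_s, end_s = iv$end_s,
               truncated = as.integer(iv$truncated)),
    paste0(prefix, "_intervals.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Write / read a space-time volume as multi-page TIFF
#'
#' One binary page per sampled frame; timestamps in a JSON sidecar.
#'
#' @param vol a [build_volume()] result.
#' @param path TIFF path; the sidecar goes to `<path>.json`.
#' @export
write_volume <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(times_s = attr(vol, "times_s")),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  build_volume(lapply(pages, function(p) p > 0.5), meta$times_s)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, lst)
}
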