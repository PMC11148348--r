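# Readers and writers for the package's interchange formats: flat binary
# voltage + JSON sidecar, spike-train CSV, calcium CSV + protocol JSON,
# single-channel PNG masks.

#' Write a recording as flat binary plus JSON sidecar
#'
#' Voltage is stored as little-endian 32-bit floats, electrode-major (all
#' samples of electrode 1, then electrode 2, ...), in `<stem>.bin`; the
#' sidecar `<stem>.json` holds `sampling_rate_hz`, `electrode_positions_um`,
#' `channel_length_um`, `pitch_um`, `units`, `n_electrodes`, `n_samples`.
#' Values are quantised to float32 on disk.
#'
#' @param recording An `mea_recording`.
#' @param stem Path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "mea_recording"))
  v <- recording$voltage
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
  meta <- list(
    sampling_rate_hz = recording$sampling_rate_hz,
    electrode_positions_um = recording$layout$electrode_positions_um,
    channel_length_um = recording$layout$channel_length_um,
    pitch_um = recording$layout$pitch_um,
    units = recording$units %||% "uV",
    n_electrodes = nrow(v),
    n_samples = ncol(v)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem Path stem (without extension).
#' @return An `mea_recording`.
#' @export
read_recording <- function(stem) {
  meta_path <- paste0(stem, ".json")
  bin_path <- paste0(stem, ".bin")
  if (!file.exists(meta_path)) abort(sprintf("Missing sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("sampling_rate_hz", "electrode_positions_um",
              "channel_length_um", "n_electrodes", "n_samples")) {
    if (is.null(meta[[f]])) abort(sprintf("Sidecar missing field `%s`.", f))
  }
  ne <- meta$n_electrodes
  ns <- meta$n_samples
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = ne * ns, size = 4L, endian = "little")
  if (length(x) != ne * ns) {
    abort("Binary payload shape does not match `n_electrodes` x `n_samples`.")
  }
  layout <- channel_layout(meta$electrode_positions_um, meta$channel_length_um,
                           pitch_um = meta$pitch_um %||% 500,
                           sampling_rate_hz = meta$sampling_rate_hz)
  structure(
    list(voltage = matrix(x, nrow = ne, byrow = TRUE), layout = layout,
         sampling_rate_hz = meta$sampling_rate_hz,
         duration_s = ns / meta$sampling_rate_hz,
         units = meta$units %||% "uV"),
    class = "mea_recording"
  )
}

#' Write / read spike trains as CSV
#'
#' Columns `electrode_id`, `spike_time_s` and (when present) `peak_uv`.
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`, optional
#'   `peak_uv`).
#' @param path CSV path.
#' @return `path` (write) or the spike-train tibble (read, with
#'   `electrode`, `time_s`, `peak_uv` columns).
#' @export
write_spike_trains <- function(trains, path) {
  out <- tibble(
    electrode_id = trains$electrode,
    spike_time_s = trains$time_s,
    peak_uv = if ("peak_uv" %in% names(trains)) trains$peak_uv else NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  for (f in c("electrode_id", "spike_time_s")) {
    if (!f %in% names(d)) abort(sprintf("Spike-train CSV missing `%s`.", f))
  }
  tibble(electrode = as.integer(d$electrode_id), time_s = d$spike_time_s,
         peak_uv = if ("peak_uv" %in% names(d)) d$peak_uv else NA_real_)
}

#' Write / read a calcium trace as CSV plus protocol JSON
#'
#' The CSV holds `frame_index`, `time_s`, `f`; the protocol JSON sits next
#' to it as `<path>.protocol.json`.
#'
#' @param trace Trace tibble (`frame`, `time_s`, `f`).
#' @param protocol The [stim_protocol()].
#' @param path CSV path.
#' @return `path` (write) or a list `trace` / `protocol` (read).
#' @export
write_calcium <- function(trace, protocol, path) {
  readr::write_csv(
    tibble(frame_index = trace$frame, time_s = trace$time_s, f = trace$f),
    path
  )
  p <- unclass(protocol)
  jsonlite::write_json(p, paste0(path, ".protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calcium
#' @export
read_calcium <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  for (f in c("frame_index", "time_s", "f")) {
    if (!f %in% names(d)) abort(sprintf("Calcium CSV missing `%s`.", f))
  }
  pj <- jsonlite::read_json(paste0(path, ".protocol.json"),
                            simplifyVector = TRUE)
  protocol <- stim_protocol(
    kind = pj$kind, isi_ms = pj$isi_ms, n_pulses = pj$n_pulses,
    n_cycles = pj$n_cycles, pre_window_s = pj$pre_window_s,
    stim_duration_s = if (pj$kind == "continuous") pj$stim_duration_s else NULL,
    recovery_s = if (pj$kind == "burst") pj$recovery_s else NULL
  )
  list(
    trace = tibble(frame = as.integer(d$frame_index), time_s = d$time_s,
                   f = d$f),
    protocol = protocol
  )
}

#' Write / read a binary mask as single-channel PNG
#'
#' @param mask Logical (or 0/1) matrix, rows = y.
#' @param path PNG path.
#' @return `path` (write) or a logical matrix (read).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow = nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}
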