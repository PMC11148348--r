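#' Electrode layout of an axon guidance channel
#'
#' Describes the geometry of one microchannel aligned over a row of MEA
#' electrodes: electrode centre positions measured along the channel from the
#' source-well end, the channel length, the electrode pitch and the sampling
#' rate of the acquisition system.
#'
#' @param electrode_positions_um Numeric vector of electrode distances from
#'   the source-well end of the channel, in micrometres. Must be strictly
#'   increasing and lie within `[0, channel_length_um]`.
#' @param channel_length_um Channel length in micrometres.
#' @param pitch_um Electrode pitch in micrometres (default 500, the grid
#'   spacing of a standard 60-electrode glass MEA).
#' @param sampling_rate_hz Acquisition sampling rate in Hz (default 25000).
#'
#' @return An object of class `channel_layout`.
#' @examples
#' channel_layout(c(250, 750), channel_length_um = 1000)
#' @export
channel_layout <- function(electrode_positions_um, channel_length_um,
                           pitch_um = 500, sampling_rate_hz = 25000) {
  if (!is.numeric(electrode_positions_um) || length(electrode_positions_um) < 1L) {
    abort("`electrode_positions_um` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(electrode_positions_um))) {
    abort("`electrode_positions_um` must be finite.")
  }
  if (is.unsorted(electrode_positions_um, strictly = TRUE)) {
    abort("`electrode_positions_um` must be strictly increasing.")
  }
  check_number(channel_length_um, "channel_length_um", lower = 0, strict_lower = TRUE)
  if (min(electrode_positions_um) < 0 || max(electrode_positions_um) > channel_length_um) {
    abort("All electrode positions must lie within [0, channel_length_um].")
  }
  check_number(pitch_um, "pitch_um", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  structure(
    list(
      electrode_positions_um = as.numeric(electrode_positions_um),
      channel_length_um = as.numeric(channel_length_um),
      pitch_um = as.numeric(pitch_um),
      sampling_rate_hz = as.numeric(sampling_rate_hz)
    ),
    class = "channel_layout"
  )
}

#' Number of electrodes in a layout
#' @param layout A [channel_layout()].
#' @return Integer electrode count.
#' @export
n_electrodes <- function(layout) {
  stopifnot(inherits(layout, "channel_layout"))
  length(layout$electrode_positions_um)
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf(
    "<channel_layout> %d electrodes over %.0f um channel (pitch %.0f um, %.0f Hz)\n",
    n_electrodes(x), x$channel_length_um, x$pitch_um, x$sampling_rate_hz
  ))
  cat("positions (um):", paste(format(x$electrode_positions_um), collapse = ", "), "\n")
  invisible(x)
}

#' Standard channel layout for a given channel length
#'
#' Convenience constructor placing electrodes at half-pitch offset and then
#' every `pitch_um` along the channel (the alignment used when a guidance
#' channel is laid over a 500 um electrode grid).
#'
#' @param channel_length_mm Channel length in millimetres.
#' @inheritParams channel_layout
#' @return A [channel_layout()].
#' @examples
#' standard_layout(6) # 12 electrodes at 250, 750, ..., 5750 um
#' @export
standard_layout <- function(channel_length_mm, pitch_um = 500,
                            sampling_rate_hz = 25000) {
  check_number(channel_length_mm, "channel_length_mm", lower = 0, strict_lower = TRUE)
  len_um <- channel_length_mm * 1000
  pos <- seq(pitch_um / 2, len_um, by = pitch_um)
  pos <- pos[pos <= len_um]
  channel_layout(pos, len_um, pitch_um = pitch_um, sampling_rate_hz = sampling_rate_hz)
}
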