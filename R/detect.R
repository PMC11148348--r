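# Spike detection: causal high-pass Butterworth, robust MAD noise estimate,
# negative-peak thresholding with a post-detection dead time.

#' High-pass Butterworth filter
#'
#' Causal single-pass second-order high-pass Butterworth filter (-3 dB at
#' `cutoff_hz`). The same filter is applied identically to every electrode, so
#' the common group delay leaves inter-electrode spike latencies untouched.
#'
#' @param x Numeric vector, matrix (rows = electrodes), or `mea_recording`.
#' @param sampling_rate_hz Sampling rate in Hz (taken from the recording when
#'   `x` is an `mea_recording`).
#' @param cutoff_hz Cut-off frequency in Hz (default 200). Must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 2).
#' @return Filtered object of the same shape/class as `x`.
#' @examples
#' fs <- 25000
#' x <- sin(2 * pi * 200 * (0:fs) / fs)
#' y <- highpass_filter(x, fs)
#' sqrt(2 * mean(y[(fs / 2):fs]^2)) # ~ 1/sqrt(2): the -3 dB point
#' @export
highpass_filter <- function(x, sampling_rate_hz = NULL, cutoff_hz = 200, order = 2) {
  if (inherits(x, "mea_recording")) {
    x$voltage <- highpass_filter(x$voltage, x$sampling_rate_hz, cutoff_hz, order)
    return(x)
  }
  check_number(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  check_number(order, "order", lower = 1)
  if (is.null(sampling_rate_hz)) abort("`sampling_rate_hz` is required.")
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  if (cutoff_hz >= sampling_rate_hz / 2) {
    abort("`cutoff_hz` must be below the Nyquist frequency.")
  }
  bf <- signal::butter(order, cutoff_hz / (sampling_rate_hz / 2), type = "high")
  if (is.matrix(x)) {
    t(apply(x, 1L, function(row) as.numeric(signal::filter(bf, row))))
  } else {
    as.numeric(signal::filter(bf, as.numeric(x)))
  }
}

#' Robust noise estimate from the median absolute deviation
#'
#' `sigma = 1.4826 * median_i(|X_i - median_j(X_j)|)`. The MAD is insensitive
#' to the sparse large excursions produced by action potentials, so this
#' estimates the baseline noise SD of a spike-bearing trace far better than
#' the raw SD.
#'
#' @param x Numeric trace (non-empty).
#' @return Estimated noise SD (same units as `x`).
#' @examples
#' mad_sigma(c(1, 2, 3, 4, 100)) # 1.4826: MAD is 1
#' @export
mad_sigma <- function(x) {
  if (length(x) == 0L) abort("`x` must be non-empty.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  mad(x, constant = 1.4826)
}

# 0-based start indices of interior local-minimum runs (strictly below both
# neighbouring values; plateau minima resolve to their earliest sample)
local_minima0 <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1L)
  is_min <- r$values[i] < r$values[i - 1L] & r$values[i] < r$values[i + 1L]
  starts[i][is_min] - 1L
}

#' Detect spikes as thresholded negative peaks
#'
#' A spike is a local-minimum sample whose value lies below `-k * sigma`.
#' Scanning in time order, any qualifying peak within `dead_time_ms` of the
#' previously accepted spike is discarded (the earliest peak is kept), which
#' suppresses duplicate detections of one event. The spike time is the
#' negative-peak sample.
#'
#' @param x Numeric voltage trace (one electrode, filtered).
#' @param sigma Noise SD in the units of `x` (typically from [mad_sigma()]).
#'   A zero `sigma` with a non-constant trace is a degenerate noise estimate
#'   and raises an error.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param k Threshold multiplier (default 5): threshold is `-k * sigma`.
#' @param dead_time_ms Post-detection dead time in ms (default 3). Peaks at a
#'   separation less than or equal to the dead time are merged.
#' @return Tibble with columns `sample` (0-based negative-peak index),
#'   `time_s` and `peak` (trace value at the peak).
#' @examples
#' x <- rep(c(1, -1), 500); x[301] <- -10
#' detect_spikes(x, mad_sigma(x), 25000) # one spike at sample 300
#' @export
detect_spikes <- function(x, sigma, sampling_rate_hz, k = 5, dead_time_ms = 3) {
  check_number(sigma, "sigma", lower = 0)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(dead_time_ms, "dead_time_ms", lower = 0, strict_lower = TRUE)
  x <- as.numeric(x)
  if (sigma == 0 && length(x) > 0 && any(x != x[1L])) {
    abort("`sigma` is 0 for a non-constant trace: degenerate noise estimate.")
  }
  cand <- local_minima0(x)
  cand <- cand[x[cand + 1L] < -k * sigma]
  dead <- dead_time_ms / 1000 * sampling_rate_hz
  if (length(cand) > 1L) {
    keep <- logical(length(cand))
    keep[1L] <- TRUE
    last <- cand[1L]
    for (i in 2:length(cand)) {
      if (cand[i] - last > dead) { # separation must exceed the dead time
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    cand <- cand[keep]
  }
  tibble(
    sample = as.integer(cand),
    time_s = cand / sampling_rate_hz,
    peak = x[cand + 1L]
  )
}

#' Detect spikes on every electrode of a recording
#'
#' Applies [highpass_filter()] (optional), estimates per-electrode noise with
#' [mad_sigma()] on the filtered trace (unless `sigma` is supplied), and runs
#' [detect_spikes()] per electrode.
#'
#' @param recording An `mea_recording` (see [simulate_recording()] /
#'   [read_recording()]).
#' @param k,dead_time_ms See [detect_spikes()].
#' @param filter Apply the high-pass filter first (default TRUE).
#' @param cutoff_hz,order Filter parameters, see [highpass_filter()].
#' @param sigma Optional noise SD (scalar or one value per electrode)
#'   overriding the MAD estimate; needed e.g. for noiseless fixtures where
#'   the MAD is 0.
#' @return Tibble with columns `electrode`, `position_um`, `sample`,
#'   `time_s`, `peak_uv`; per-electrode noise estimates in attribute
#'   `sigma_uv`, the detection configuration in attribute `config`.
#' @export
detect_recording <- function(recording, k = 5, dead_time_ms = 3,
                             filter = TRUE, cutoff_hz = 200, order = 2,
                             sigma = NULL) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$sampling_rate_hz
  v <- recording$voltage
  if (filter) v <- highpass_filter(v, fs, cutoff_hz, order)
  ne <- nrow(v)
  sig <- if (is.null(sigma)) {
    apply(v, 1L, mad_sigma)
  } else {
    rep_len(as.numeric(sigma), ne)
  }
  pos <- recording$layout$electrode_positions_um
  res <- purrr::map(seq_len(ne), function(e) {
    sp <- detect_spikes(v[e, ], sig[e], fs, k = k, dead_time_ms = dead_time_ms)
    tibble(electrode = e, position_um = pos[e],
           sample = sp$sample, time_s = sp$time_s, peak_uv = sp$peak)
  }) |> purrr::list_rbind()
  attr(res, "sigma_uv") <- sig
  attr(res, "config") <- list(k = k, dead_time_ms = dead_time_ms,
                              filter = filter, cutoff_hz = cutoff_hz,
                              order = order)
  res
}

#' Firing rate of one spike train
#'
#' @param spike_times_s Numeric spike times (any unit of count works; only
#'   the count is used).
#' @param duration_s Recording duration in seconds (> 0).
#' @return Rate in Hz.
#' @examples
#' electrode_rate(seq_len(61), 60) # 1.0167 Hz
#' @export
electrode_rate <- function(spike_times_s, duration_s) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  length(spike_times_s) / duration_s
}

#' Per-electrode firing rates
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`), e.g. from
#'   [detect_recording()].
#' @param layout The [channel_layout()]; electrodes without spikes are
#'   reported with rate 0.
#' @param duration_s Recording duration in seconds.
#' @return Tibble with `electrode`, `position_um`, `n_spikes`, `rate_hz`.
#' @export
electrode_rates <- function(trains, layout, duration_s) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  counts <- if (is.null(trains) || nrow(trains) == 0L) {
    tibble(electrode = integer(), n_spikes = integer())
  } else {
    trains |> count(.data$electrode, name = "n_spikes")
  }
  tibble(
    electrode = seq_len(n_electrodes(layout)),
    position_um = layout$electrode_positions_um
  ) |>
    left_join(counts, by = "electrode") |>
    mutate(
      n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes),
      rate_hz = .data$n_spikes / duration_s
    )
}
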