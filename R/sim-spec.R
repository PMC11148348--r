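#' Simulation specification for a channel recording
#'
#' Parameters of the synthetic extracellular recording generator. Propagation
#' events occur as a Poisson process; each event travels along the channel at
#' a per-event velocity drawn around `true_velocity_mps`, leaving a biphasic
#' spike template on every electrode it is not dropped from, on top of
#' Gaussian electrode noise.
#'
#' @param duration_s Recording duration in seconds.
#' @param event_rate_hz Poisson rate of propagation events (events/s).
#' @param true_velocity_mps Ground-truth conduction velocity in m/s.
#' @param velocity_jitter_frac Fractional SD of the per-event velocity
#'   (e.g. 0.05 for 5% jitter).
#' @param forward_fraction Probability that an event travels forward
#'   (source to target); in `[0, 1]`.
#' @param dropout_prob_per_electrode Probability that an event leaves no
#'   template on a given electrode; in `[0, 1]`.
#' @param spike_amplitude_sigma Template negative-peak amplitude in multiples
#'   of the noise SD (default 8). When `noise_sigma_uv` is 0 the amplitude is
#'   interpreted in microvolts directly.
#' @param spike_template Optional numeric waveform (arbitrary length, peak
#'   normalised to -1) replacing the default 1.2 ms biphasic template. Must
#'   have a unique minimum.
#' @param noise_sigma_uv Gaussian electrode noise SD in microvolts.
#' @param seed Integer seed; mandatory, all randomness is derived from it.
#'
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(duration_s = 60, event_rate_hz = 5,
                     true_velocity_mps = 0.8, velocity_jitter_frac = 0.05,
                     forward_fraction = 1, dropout_prob_per_electrode = 0,
                     spike_amplitude_sigma = 8, spike_template = NULL,
                     noise_sigma_uv = 5, seed = NULL) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(event_rate_hz, "event_rate_hz", lower = 0)
  check_number(true_velocity_mps, "true_velocity_mps", lower = 0, strict_lower = TRUE)
  check_number(velocity_jitter_frac, "velocity_jitter_frac", lower = 0)
  check_number(forward_fraction, "forward_fraction", lower = 0, upper = 1)
  check_number(dropout_prob_per_electrode, "dropout_prob_per_electrode",
               lower = 0, upper = 1)
  check_number(spike_amplitude_sigma, "spike_amplitude_sigma",
               lower = 0, strict_lower = TRUE)
  check_number(noise_sigma_uv, "noise_sigma_uv", lower = 0)
  if (is.null(seed)) abort("`seed` is mandatory in sim_spec(); no implicit randomness.")
  check_number(seed, "seed")
  if (!is.null(spike_template)) {
    if (!is.numeric(spike_template) || length(spike_template) < 3) {
      abort("`spike_template` must be a numeric waveform of length >= 3.")
    }
    if (sum(spike_template == min(spike_template)) != 1L) {
      abort("`spike_template` must have a unique minimum (the spike time).")
    }
  }
  structure(
    list(
      duration_s = duration_s, event_rate_hz = event_rate_hz,
      true_velocity_mps = true_velocity_mps,
      velocity_jitter_frac = velocity_jitter_frac,
      forward_fraction = forward_fraction,
      dropout_prob_per_electrode = dropout_prob_per_electrode,
      spike_amplitude_sigma = spike_amplitude_sigma,
      spike_template = spike_template,
      noise_sigma_uv = noise_sigma_uv,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' Default biphasic spike template
#'
#' A 1.2 ms negative-then-positive waveform with a unique negative peak,
#' normalised so the negative peak is -1. The peak index (0-based) is
#' returned as the `"peak_index"` attribute; the generator aligns this sample
#' with the ground-truth arrival sample.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_ms Template duration in ms (default 1.2).
#' @return Numeric waveform with attribute `peak_index`.
#' @export
spike_template <- function(sampling_rate_hz, duration_ms = 1.2) {
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 0, strict_lower = TRUE)
  n <- max(5L, round(duration_ms / 1000 * sampling_rate_hz))
  # odd-length negative lobe -> unique minimum at its centre
  neg_n <- 2L * floor(n * 0.35 / 2) + 1L
  pos_n <- n - neg_n
  neg <- -sin(pi * (0:(neg_n - 1L)) / (neg_n - 1L))
  pos <- 0.35 * sin(pi * seq_len(pos_n) / (pos_n + 1L))
  w <- c(neg, pos)
  attr(w, "peak_index") <- (neg_n - 1L) %/% 2L # 0-based
  w
}

template_peak_index <- function(w) {
  pk <- attr(w, "peak_index")
  if (is.null(pk)) pk <- which.min(w) - 1L
  as.integer(pk)
}
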