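# Synthetic channel recordings with ground truth.
#
# Event mechanics: event k starts at t0[k]; a forward event arrives at
# electrode e at t0 + position_e / v, a backward event at
# t0 + (L - position_e) / v, with v drawn per event. Arrival samples are the
# rounded sample indices (0-based) of the template's negative peak.

# draws events and arrivals; assumes an active RNG (callers seed it)
sim_events_impl <- function(layout, spec) {
  fs <- layout$sampling_rate_hz
  pos <- layout$electrode_positions_um
  L <- layout$channel_length_um
  n_ev <- rpois(1L, spec$event_rate_hz * spec$duration_s)
  if (n_ev == 0L) {
    return(tibble(
      event_id = integer(), t0_s = numeric(), direction = character(),
      velocity_mps = numeric(), electrode = integer(), position_um = numeric(),
      arrival_sample = integer(), arrival_time_s = numeric(), dropped = logical()
    ))
  }
  travel_max <- (L * 1e-6) / (spec$true_velocity_mps * 0.5) # generous margin
  lo <- 0.005
  hi <- max(lo + 1e-4, spec$duration_s - 0.005 - travel_max)
  t0 <- sort(runif(n_ev, lo, hi))
  fwd <- rbinom(n_ev, 1L, spec$forward_fraction) == 1L
  v <- spec$true_velocity_mps *
    (1 + spec$velocity_jitter_frac * rnorm(n_ev))
  v <- pmax(v, 0.2 * spec$true_velocity_mps)
  ne <- length(pos)
  dropped <- matrix(rbinom(n_ev * ne, 1L, spec$dropout_prob_per_electrode) == 1L,
                    nrow = n_ev, ncol = ne)
  dist_um <- outer(fwd, pos, function(f, p) ifelse(f, p, L - p))
  arr_t <- t0 + (dist_um * 1e-6) / v
  arr_s <- matrix(as.integer(round(arr_t * fs)), nrow = n_ev)
  tibble(
    event_id = rep(seq_len(n_ev), each = ne),
    t0_s = rep(t0, each = ne),
    direction = rep(ifelse(fwd, "forward", "backward"), each = ne),
    velocity_mps = rep(v, each = ne),
    electrode = rep(seq_len(ne), times = n_ev),
    position_um = rep(pos, times = n_ev),
    arrival_sample = as.integer(t(arr_s)),
    arrival_time_s = as.numeric(t(arr_t)),
    dropped = as.logical(t(dropped))
  )
}

#' Simulate ground-truth propagation events and spike trains
#'
#' Draws Poisson-timed propagation events along the channel and returns the
#' per-event, per-electrode ground truth together with the observable spike
#' trains (non-dropped arrivals). This is the train-level generator; use
#' [simulate_recording()] to additionally synthesise the raw voltage traces.
#'
#' @param layout A [channel_layout()].
#' @param spec A [sim_spec()].
#' @return A list with elements `truth` (tibble: `event_id`, `t0_s`,
#'   `direction`, `velocity_mps`, `electrode`, `position_um`,
#'   `arrival_sample`, `arrival_time_s`, `dropped`) and `trains` (tibble:
#'   `electrode`, `position_um`, `sample`, `time_s`). Sample indices are
#'   0-based.
#' @examples
#' lay <- channel_layout(c(250, 750), 1000)
#' sim <- simulate_spike_trains(lay, sim_spec(duration_s = 5, seed = 1))
#' head(sim$truth)
#' @export
simulate_spike_trains <- function(layout, spec) {
  stopifnot(inherits(layout, "channel_layout"), inherits(spec, "sim_spec"))
  truth <- with_sim_seed(spec$seed, sim_events_impl(layout, spec))
  list(truth = truth, trains = truth_to_trains(truth, layout))
}

#' Spike trains implied by a ground-truth table
#'
#' Keeps non-dropped arrivals and orders them per electrode; the result is in
#' the same shape [detect_recording()] produces, so ground truth and detected
#' trains are directly comparable.
#'
#' @param truth Ground-truth tibble from [simulate_spike_trains()].
#' @param layout The [channel_layout()] used to generate it.
#' @return Tibble with columns `electrode`, `position_um`, `sample`, `time_s`.
#' @export
truth_to_trains <- function(truth, layout) {
  fs <- layout$sampling_rate_hz
  truth |>
    filter(!.data$dropped) |>
    transmute(
      electrode = .data$electrode,
      position_um = .data$position_um,
      sample = .data$arrival_sample,
      time_s = .data$arrival_sample / fs
    ) |>
    arrange(.data$electrode, .data$sample)
}

#' Simulate a raw channel recording with ground truth
#'
#' Generates a voltage matrix (electrodes x samples, microvolts) as Gaussian
#' noise plus a biphasic spike template injected at every non-dropped
#' ground-truth arrival, with the template's negative peak aligned to the
#' arrival sample. Identical seeds give bit-identical output.
#'
#' Template amplitude is `spike_amplitude_sigma * noise_sigma_uv`; when
#' `noise_sigma_uv` is 0 (noiseless fixtures) the amplitude is
#' `spike_amplitude_sigma` microvolts. Two events landing closer than the
#' template length on one electrode are superposed with a warning.
#'
#' @inheritParams simulate_spike_trains
#' @return A list with `recording` (an `mea_recording`: `voltage`, `layout`,
#'   `sampling_rate_hz`, `duration_s`, `units`) and `truth` (as in
#'   [simulate_spike_trains()]).
#' @examples
#' lay <- channel_layout(c(250, 750), 1000)
#' sim <- simulate_recording(lay, sim_spec(duration_s = 2, seed = 42))
#' dim(sim$recording$voltage)
#' @export
simulate_recording <- function(layout, spec) {
  stopifnot(inherits(layout, "channel_layout"), inherits(spec, "sim_spec"))
  fs <- layout$sampling_rate_hz
  ne <- n_electrodes(layout)
  ns <- round(spec$duration_s * fs)
  tmpl <- spec$spike_template %||% spike_template(fs)
  pk <- template_peak_index(tmpl)
  nt <- length(tmpl)
  amp <- spec$spike_amplitude_sigma *
    (if (spec$noise_sigma_uv > 0) spec$noise_sigma_uv else 1)

  out <- with_sim_seed(spec$seed, {
    truth <- sim_events_impl(layout, spec)
    v <- if (spec$noise_sigma_uv > 0) {
      matrix(rnorm(ne * ns, 0, spec$noise_sigma_uv), nrow = ne)
    } else {
      matrix(0, nrow = ne, ncol = ns)
    }
    list(truth = truth, voltage = v)
  })
  truth <- out$truth
  v <- out$voltage

  hits <- truth[!truth$dropped, , drop = FALSE]
  # drop arrivals whose template would fall outside the trace
  ok <- hits$arrival_sample - pk >= 0 & hits$arrival_sample - pk + nt - 1L < ns
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) > 0) {
    n_overlap <- hits |>
      group_by(.data$electrode) |>
      summarise(o = sum(diff(sort(.data$arrival_sample)) < nt), .groups = "drop") |>
      pull(.data$o) |>
      sum()
    if (n_overlap > 0) {
      warn(sprintf(
        "%d template pair(s) closer than the template length on one electrode; superposing.",
        n_overlap
      ))
    }
    for (i in seq_len(nrow(hits))) {
      e <- hits$electrode[i]
      s0 <- hits$arrival_sample[i] - pk + 1L # to 1-based column
      v[e, s0:(s0 + nt - 1L)] <- v[e, s0:(s0 + nt - 1L)] + amp * tmpl
    }
  }

  rec <- structure(
    list(voltage = v, layout = layout, sampling_rate_hz = fs,
         duration_s = ns / fs, units = "uV"),
    class = "mea_recording"
  )
  list(recording = rec, truth = truth)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d electrodes x %d samples (%.1f s at %.0f Hz, %s)\n",
    nrow(x$voltage), ncol(x$voltage), x$duration_s, x$sampling_rate_hz, x$units
  ))
  invisible(x)
}
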