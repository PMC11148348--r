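# Synthetic GCaMP traces with stimulus-locked transients.
#
# Fluorescence model: F(t) = F0 * (1 + sum_k a_k * A * K(t - t_k)) + noise,
# where K is a normalised rise/decay kernel, A the per-pulse peak dF/F0, and
# a_k the per-pulse efficacy of a single-pool depression model. Utilization
# engages only above the cutoff frequency:
#   u(f) = u_max * max(0, 1 - cutoff_hz / f),
# so trains at pulse rates at or below the cutoff do not depress (sustained
# plateau) while faster trains deplete the pool and the response collapses
# towards baseline (transient). After a pulse the pool recovers towards 1
# with time constant `depression_recovery_s`:
#   R' = 1 - (1 - R * (1 - u)) * exp(-gap / tau_rec).

#' Calcium-trace simulation specification
#'
#' @param protocol A [stim_protocol()].
#' @param frame_interval_s Acquisition frame interval in seconds
#'   (default 0.01, i.e. 10 ms/frame).
#' @param baseline_f0 Baseline fluorescence in arbitrary units (default 100).
#' @param noise_sigma Gaussian noise SD on F, same units (default 1, i.e. 1%
#'   of baseline).
#' @param kernel_rise_s,kernel_decay_s Calcium kernel rise and decay time
#'   constants in seconds (defaults 0.05 and 1.5).
#' @param kernel_peak Peak dF/F0 of a single, undepressed pulse response
#'   (default 0.05).
#' @param cutoff_hz Pulse rate above which per-pulse efficacy depresses
#'   (default 32).
#' @param u_max Maximal per-pulse utilization of the depression pool
#'   (default 0.1).
#' @param depression_recovery_s Pool recovery time constant in seconds
#'   (default 3).
#' @param seed Integer seed; mandatory.
#' @return An object of class `calcium_sim_spec`.
#' @export
calcium_sim_spec <- function(protocol, frame_interval_s = 0.01,
                             baseline_f0 = 100, noise_sigma = 1,
                             kernel_rise_s = 0.05, kernel_decay_s = 1.5,
                             kernel_peak = 0.05, cutoff_hz = 32,
                             u_max = 0.1, depression_recovery_s = 3,
                             seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  check_number(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  check_number(baseline_f0, "baseline_f0", lower = 0, strict_lower = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(kernel_rise_s, "kernel_rise_s", lower = 0, strict_lower = TRUE)
  check_number(kernel_decay_s, "kernel_decay_s", lower = 0, strict_lower = TRUE)
  check_number(kernel_peak, "kernel_peak", lower = 0, strict_lower = TRUE)
  check_number(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  check_number(u_max, "u_max", lower = 0, upper = 1)
  check_number(depression_recovery_s, "depression_recovery_s",
               lower = 0, strict_lower = TRUE)
  if (is.null(seed)) abort("`seed` is mandatory in calcium_sim_spec().")
  check_number(seed, "seed")
  structure(
    list(protocol = protocol, frame_interval_s = frame_interval_s,
         baseline_f0 = baseline_f0, noise_sigma = noise_sigma,
         kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
         kernel_peak = kernel_peak, cutoff_hz = cutoff_hz, u_max = u_max,
         depression_recovery_s = depression_recovery_s,
         seed = as.integer(seed)),
    class = "calcium_sim_spec"
  )
}

#' Normalised calcium response kernel
#'
#' `K(s) = (1 - exp(-s/rise)) * exp(-s/decay)`, scaled so the continuous-time
#' peak equals `peak`. The peak sits at `s* = rise * log(1 + decay/rise)`.
#'
#' @param s Time offsets since the pulse (s >= 0; negative offsets give 0).
#' @param rise_s,decay_s Kernel time constants in seconds.
#' @param peak Peak amplitude (default 1).
#' @return Kernel values at `s`.
#' @export
calcium_kernel <- function(s, rise_s, decay_s, peak = 1) {
  kmax <- (decay_s / (rise_s + decay_s)) *
    ((rise_s + decay_s) / rise_s)^(-rise_s / decay_s)
  out <- ifelse(s >= 0, (1 - exp(-s / rise_s)) * exp(-s / decay_s), 0)
  peak * out / kmax
}

# per-pulse efficacies for a pulse-time vector (absolute seconds)
pulse_efficacies <- function(times, isi_s, spec) {
  f <- 1 / isi_s
  u <- spec$u_max * max(0, 1 - spec$cutoff_hz / f)
  n <- length(times)
  a <- numeric(n)
  R <- 1
  for (k in seq_len(n)) {
    a[k] <- R
    R <- R * (1 - u)
    if (k < n) {
      gap <- times[k + 1L] - times[k]
      R <- 1 - (1 - R) * exp(-gap / spec$depression_recovery_s)
    }
  }
  a
}

#' Simulate a stimulus-locked calcium trace with ground truth
#'
#' Generates a single-ROI fluorescence series over all protocol cycles.
#' Per-pulse efficacies follow a single-pool depression model whose
#' utilization engages only above `cutoff_hz`, so pulse rates at or below
#' the cutoff give a sustained plateau and faster rates a transient response
#' decaying towards baseline. Seed-deterministic.
#'
#' @param spec A [calcium_sim_spec()].
#' @return List with `trace` (tibble: `frame` 0-based, `time_s`, `f`),
#'   `pulses` (tibble: `cycle`, `pulse`, `time_s`, `efficacy`), `truth`
#'   (tibble per cycle: `cycle`, `rate_hz`, `true_per`, `true_per_time_s`,
#'   `true_slope`, `sustained_true`), and the `protocol` / `spec` used.
#'   `true_per` and `true_slope` are computed from the noiseless signal.
#' @export
simulate_calcium <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  p <- spec$protocol
  dt <- spec$frame_interval_s
  total_s <- p$n_cycles * p$cycle_s
  n_frames <- floor(total_s / dt)
  t <- (seq_len(n_frames) - 1L) * dt

  pulses <- protocol_pulses(p)
  if (nrow(pulses) > 0 && max(pulses$time_s) >= total_s) {
    abort("Protocol pulses fall outside the trace duration.")
  }
  pulses$efficacy <- pulse_efficacies(pulses$time_s, p$isi_ms / 1000, spec)

  sig <- numeric(n_frames)
  horizon <- 8 * spec$kernel_decay_s
  for (k in seq_len(nrow(pulses))) {
    i0 <- max(1L, ceiling(pulses$time_s[k] / dt) + 1L)
    i1 <- min(n_frames, floor((pulses$time_s[k] + horizon) / dt) + 1L)
    if (i1 >= i0) {
      idx <- i0:i1
      sig[idx] <- sig[idx] + pulses$efficacy[k] *
        calcium_kernel(t[idx] - pulses$time_s[k], spec$kernel_rise_s,
                       spec$kernel_decay_s, peak = spec$kernel_peak)
    }
  }

  noise <- with_sim_seed(spec$seed, rnorm(n_frames, 0, spec$noise_sigma))
  f <- spec$baseline_f0 * (1 + sig) + noise

  # per-cycle ground truth from the noiseless signal
  cyc <- protocol_cycles(p)
  win <- if (p$kind == "continuous") 5 else 1
  truth <- purrr::map(seq_len(nrow(cyc)), function(i) {
    in_win <- t >= cyc$stim_on_s[i] & t <= pmin(cyc$stim_on_s[i] + win,
                                                cyc$cycle_end_s[i])
    per <- max(sig[in_win])
    per_t <- t[in_win][which.max(sig[in_win])]
    # noiseless sustain slope: PER frame (within the 5 s search window,
    # capped at stimulation end) to stimulation end
    slope <- NA_real_
    if (p$kind == "continuous") {
      sw <- t >= cyc$stim_on_s[i] & t <= pmin(cyc$stim_on_s[i] + 5,
                                              cyc$stim_end_s[i])
      j0 <- t[sw][which.max(sig[sw])]
      reg <- t >= j0 & t <= cyc$stim_end_s[i]
      if (sum(reg) >= 2L) {
        slope <- unname(lsfit(t[reg], sig[reg])$coefficients[2L])
      }
    }
    tibble(
      cycle = cyc$cycle[i], rate_hz = p$rate_hz,
      true_per = per,
      true_per_time_s = per_t,
      true_slope = slope,
      sustained_true = p$rate_hz <= spec$cutoff_hz
    )
  }) |> purrr::list_rbind()

  list(
    trace = tibble(frame = seq_len(n_frames) - 1L, time_s = t, f = f),
    pulses = pulses, truth = truth, protocol = p, spec = spec
  )
}
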