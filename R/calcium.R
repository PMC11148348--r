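# Stimulus-evoked calcium response metrics: dF/F0, peak evoked response,
# sustain slope, sustained/transient classification, transmission fidelity.

#' Block-average consecutive frames
#'
#' Non-overlapping means of `n` consecutive frames (the acquisition-side
#' averaging used for continuous-stimulation recordings); a trailing
#' remainder shorter than `n` is dropped. The effective frame interval
#' scales by `n`.
#'
#' @param f Numeric fluorescence series.
#' @param n Block size (>= 1; `n = 1` is the identity).
#' @return Averaged numeric series.
#' @examples
#' average_frames(1:10, 10) # 5.5
#' @export
average_frames <- function(f, n = 10) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  if (n == 1L) return(as.numeric(f))
  nb <- length(f) %/% n
  if (nb == 0L) abort("Series shorter than one block.")
  colMeans(matrix(f[seq_len(nb * n)], nrow = n))
}

#' Normalised fluorescence change dF/F0
#'
#' `dF/F0 = (F - F0) / F0` per frame, with `F0` the mean fluorescence over
#' the baseline frames.
#'
#' @param f Numeric fluorescence series.
#' @param baseline_idx Indices (1-based) of the baseline frames used for
#'   `F0`.
#' @return Numeric dF/F0 series, with `F0` as attribute `f0`.
#' @examples
#' dff(c(98, 100, 102, 110), baseline_idx = 1:3) # F0 = 100
#' @export
dff <- function(f, baseline_idx) {
  if (length(baseline_idx) == 0L) abort("`baseline_idx` must be non-empty.")
  f0 <- mean(f[baseline_idx])
  if (!is.finite(f0) || f0 <= 0) {
    abort("Baseline F0 must be positive for an interpretable dF/F0.")
  }
  out <- (f - f0) / f0
  attr(out, "f0") <- f0
  out
}

# frame indices (1-based) of a [t0, t1] window on a regular grid
window_idx <- function(time_s, t0, t1) which(time_s >= t0 & time_s <= t1)

#' Peak evoked response per stimulation cycle
#'
#' The PER of a cycle is the maximum dF/F0 in the response search window
#' after stimulation onset: the first 5 s for continuous stimulation, the
#' first 1 s (within the recovery pause) for burst stimulation.
#'
#' @param dffs Numeric dF/F0 series (whole recording).
#' @param time_s Frame times in seconds (same length as `dffs`).
#' @param protocol The [stim_protocol()].
#' @param search_window_s Response window after onset in seconds (default
#'   5 for continuous, 1 for burst protocols).
#' @return Tibble with `cycle`, `per`, `per_time_s`.
#' @export
peak_evoked_response <- function(dffs, time_s, protocol, search_window_s = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  win <- search_window_s %||% (if (protocol$kind == "continuous") 5 else 1)
  check_number(win, "search_window_s", lower = 0, strict_lower = TRUE)
  cyc <- protocol_cycles(protocol)
  purrr::map(seq_len(nrow(cyc)), function(i) {
    idx <- window_idx(time_s, cyc$stim_on_s[i],
                      min(cyc$stim_on_s[i] + win, cyc$cycle_end_s[i]))
    if (length(idx) == 0L) abort("Empty PER search window.")
    j <- idx[which.max(dffs[idx])]
    tibble(cycle = cyc$cycle[i], per = dffs[j], per_time_s = time_s[j])
  }) |> purrr::list_rbind()
}

#' Sustain slope of the calcium response
#'
#' For each cycle, fits a least-squares line to dF/F0 between the peak
#' evoked response (within the first `search_window_s` after onset) and the
#' end of the stimulation phase; the slope is in dF/F0 per second. A slope
#' close to 0 indicates a sustained response, a clearly negative slope a
#' transient one. The summary statistic `m` is the mean slope over cycles.
#'
#' @inheritParams peak_evoked_response
#' @param search_window_s PER search window after onset (default 5 s).
#' @return Tibble with `cycle`, `slope`; the mean slope is attribute `m`.
#' @export
sustain_slope <- function(dffs, time_s, protocol, search_window_s = 5) {
  stopifnot(inherits(protocol, "stim_protocol"))
  cyc <- protocol_cycles(protocol)
  res <- purrr::map(seq_len(nrow(cyc)), function(i) {
    per_idx <- window_idx(time_s, cyc$stim_on_s[i],
                          min(cyc$stim_on_s[i] + search_window_s,
                              cyc$stim_end_s[i]))
    if (length(per_idx) == 0L) abort("Empty PER search window.")
    j0 <- per_idx[which.max(dffs[per_idx])]
    idx <- window_idx(time_s, time_s[j0], cyc$stim_end_s[i])
    if (length(idx) < 2L) abort("Fewer than 2 frames between PER and stimulation end.")
    fit <- lsfit(time_s[idx], dffs[idx])
    tibble(cycle = cyc$cycle[i], slope = unname(fit$coefficients[2L]))
  }) |> purrr::list_rbind()
  attr(res, "m") <- mean(res$slope)
  res
}

#' Classify a response as sustained or transient
#'
#' Sustained iff the mean sustain slope `m` is at or above the threshold.
#'
#' @param m Mean sustain slope(s) in dF/F0 per second.
#' @param threshold Classification threshold (default -0.005 per second; the
#'   boundary of "close to zero").
#' @return Character vector of `"sustained"` / `"transient"`.
#' @examples
#' classify_sustained(c(0, -0.05))
#' @export
classify_sustained <- function(m, threshold = -0.005) {
  if (any(!is.finite(m))) abort("`m` must be finite.")
  ifelse(m >= threshold, "sustained", "transient")
}

#' Transmission fidelity of burst stimulation
#'
#' Percentage of stimulation cycles with a detectable response. A cycle is
#' detectable when its PER exceeds the baseline dF/F0 mean by
#' `sd_multiplier` robust standard deviations, with the SD taken as
#' `1.4826 * MAD` of the pooled baseline segment. If the baseline is exactly
#' constant (robust SD 0) any PER above the baseline mean is detectable.
#'
#' @param per_values Per-cycle PER values.
#' @param baseline_dff Pooled baseline dF/F0 segment (non-empty).
#' @param sd_multiplier Detection multiplier (default 5).
#' @return Percentage in `[0, 100]`.
#' @export
transmission_fidelity <- function(per_values, baseline_dff, sd_multiplier = 5) {
  if (length(baseline_dff) == 0L) abort("`baseline_dff` must be non-empty.")
  check_number(sd_multiplier, "sd_multiplier", lower = 0)
  sigma_b <- mad_sigma(baseline_dff)
  thr <- mean(baseline_dff) + sd_multiplier * sigma_b
  100 * mean(per_values > thr)
}

#' Full analysis of one stimulus-locked calcium recording
#'
#' Computes per-cycle dF/F0 (baseline = each cycle's pre-stimulus window),
#' the per-cycle PER, and, for continuous protocols, the sustain slope and
#' sustained/transient label; for burst protocols the PER mean/variance and
#' the transmission fidelity against the pooled baseline.
#'
#' @param trace Trace tibble (`time_s`, `f`) or numeric fluorescence vector.
#' @param protocol The [stim_protocol()].
#' @param frame_interval_s Frame interval (required when `trace` is a bare
#'   vector).
#' @param n_average Optional frame-averaging factor applied first
#'   (default 1).
#' @param slope_threshold Classification threshold, see
#'   [classify_sustained()].
#' @param sd_multiplier Detection multiplier, see [transmission_fidelity()].
#' @return An object of class `calcium_response`; see
#'   [glance.calcium_response()].
#' @export
analyze_calcium <- function(trace, protocol, frame_interval_s = NULL,
                            n_average = 1, slope_threshold = -0.005,
                            sd_multiplier = 5) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (is.data.frame(trace)) {
    f <- trace$f
    dt <- if (nrow(trace) > 1) diff(trace$time_s[1:2]) else frame_interval_s
  } else {
    f <- as.numeric(trace)
    if (is.null(frame_interval_s)) abort("`frame_interval_s` required for a bare vector.")
    dt <- frame_interval_s
  }
  if (n_average > 1) {
    f <- average_frames(f, n_average)
    dt <- dt * n_average
  }
  time_s <- (seq_along(f) - 1L) * dt

  cyc <- protocol_cycles(protocol)
  # cycle-wise dF/F0 with per-cycle baseline F0
  dffs <- numeric(length(f))
  f0s <- numeric(nrow(cyc))
  base_idx_all <- integer()
  for (i in seq_len(nrow(cyc))) {
    ci <- window_idx(time_s, cyc$cycle_start_s[i], cyc$cycle_end_s[i] - dt / 2)
    bi <- window_idx(time_s, cyc$cycle_start_s[i], cyc$stim_on_s[i] - dt / 2)
    if (length(bi) == 0L) abort("Cycle has no pre-stimulus baseline frames.")
    d <- dff(f[ci], match(bi, ci))
    f0s[i] <- attr(d, "f0")
    dffs[ci] <- as.numeric(d)
    base_idx_all <- c(base_idx_all, bi)
  }

  pers <- peak_evoked_response(dffs, time_s, protocol)
  cycles <- cyc |>
    select("cycle") |>
    mutate(f0 = f0s) |>
    left_join(pers, by = "cycle")

  if (protocol$kind == "continuous") {
    sl <- sustain_slope(dffs, time_s, protocol)
    cycles <- cycles |> left_join(sl, by = "cycle")
    m <- attr(sl, "m")
    label <- classify_sustained(m, threshold = slope_threshold)
    fid <- NA_real_
  } else {
    m <- NA_real_
    label <- NA_character_
    fid <- transmission_fidelity(cycles$per, dffs[base_idx_all],
                                 sd_multiplier = sd_multiplier)
  }

  structure(
    list(
      cycles = cycles, dff = dffs, time_s = time_s, protocol = protocol,
      summary = tibble(
        kind = protocol$kind, isi_ms = protocol$isi_ms,
        frequency_hz = protocol$rate_hz,
        per_mean = mean(cycles$per), per_var = stats::var(cycles$per),
        slope_m = m, label = label, fidelity_pct = fid
      )
    ),
    class = "calcium_response"
  )
}

#' @describeIn analyze_calcium Per-cycle tibble (`cycle`, `f0`, `per`,
#'   `per_time_s` and, for continuous protocols, `slope`).
#' @param x,object A `calcium_response`.
#' @param ... Unused.
#' @method tidy calcium_response
#' @export
tidy.calcium_response <- function(x, ...) {
  x$cycles
}

#' One-row summary of a calcium response
#'
#' @param x A `calcium_response` from [analyze_calcium()].
#' @param ... Unused.
#' @return One-row tibble: `isi_ms`, `frequency_hz`, `per_mean`, `per_var`,
#'   `slope_m`, `label`, `fidelity_pct`.
#' @method glance calcium_response
#' @export
glance.calcium_response <- function(x, ...) {
  x$summary
}

#' @export
print.calcium_response <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<calcium_response:%s> ISI %.1f ms (%.2f Hz), %d cycles\n",
              s$kind, s$isi_ms, s$frequency_hz, nrow(x$cycles)))
  cat(sprintf("PER %.4f (var %.2g) | slope %.4g /s [%s] | fidelity %.1f%%\n",
              s$per_mean, s$per_var, s$slope_m,
              s$label %||% NA, s$fidelity_pct))
  invisible(x)
}

#' @method autoplot calcium_response
#' @export
autoplot.calcium_response <- function(object, ...) {
  df <- tibble(time_s = object$time_s, dff = object$dff)
  cyc <- protocol_cycles(object$protocol)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = cyc$stim_on_s, linetype = 3,
                        colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "dF/F0") +
    ggplot2::theme_minimal()
}
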