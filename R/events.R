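# Grouping per-electrode spikes into propagation events and the derived
# directionality / velocity / fidelity statistics.

#' Group spikes into propagation events
#'
#' Greedy, time-ordered chaining. The forward pass walks all spikes in time
#' order; each yet-unassigned spike starts a chain on its electrode, which is
#' extended towards the target end by taking, on each successive electrode,
#' the earliest unassigned spike no earlier than the chain's last spike and
#' within `pair_window_ms` of it (electrodes with no match are skipped, which
#' tolerates per-electrode dropout). Chains spanning at least two electrodes
#' become forward events and their spikes are consumed. The mirror pass over
#' the remaining spikes builds backward events. Every spike belongs to at
#' most one event; chains with zero time span have no direction and are
#' labelled `ambiguous`.
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`), electrodes
#'   indexed 1..n in layout order.
#' @param layout The [channel_layout()].
#' @param pair_window_ms Maximum lag between chained spikes on successive
#'   electrodes, in ms (default 5; with 500 um pitch this implies a 0.1 m/s
#'   minimum conduction speed).
#' @return A tibble of class `mea_events`, one row per (event, electrode):
#'   `event_id`, `direction` (`forward`/`backward`/`ambiguous`),
#'   `electrode`, `position_um`, `time_s`.
#' @export
group_events <- function(trains, layout, pair_window_ms = 5) {
  stopifnot(inherits(layout, "channel_layout"))
  check_number(pair_window_ms, "pair_window_ms", lower = 0, strict_lower = TRUE)
  ne <- n_electrodes(layout)
  pos <- layout$electrode_positions_um
  w <- pair_window_ms / 1000

  df <- trains |>
    filter(.data$electrode %in% seq_len(ne)) |>
    arrange(.data$time_s) |>
    mutate(.sid = row_number())
  n <- nrow(df)
  empty <- tibble(event_id = integer(), direction = character(),
                  electrode = integer(), position_um = numeric(),
                  time_s = numeric())
  if (n == 0L || dplyr::n_distinct(df$electrode) < 2L) {
    return(structure(empty, class = c("mea_events", class(empty))))
  }

  time <- df$time_s
  elec <- df$electrode
  # per-electrode sorted views (df is time-sorted, so these are too)
  sid_by_e <- split(df$.sid, factor(elec, levels = seq_len(ne)))
  t_by_e <- split(time, factor(elec, levels = seq_len(ne)))
  assigned <- logical(n)

  first_free_in_window <- function(e, t_lo, t_hi) {
    ts <- t_by_e[[e]]
    if (length(ts) == 0L) return(NA_integer_)
    i <- findInterval(t_lo, ts, left.open = TRUE) + 1L
    while (i <= length(ts) && ts[i] <= t_hi) {
      s <- sid_by_e[[e]][i]
      if (!assigned[s]) return(s)
      i <- i + 1L
    }
    NA_integer_
  }

  run_pass <- function(elec_order, label) {
    events <- list()
    k <- 0L
    for (s in seq_len(n)) {
      if (assigned[s]) next
      k0 <- match(elec[s], elec_order)
      if (is.na(k0) || k0 == length(elec_order)) next
      chain <- s
      t_last <- time[s]
      for (j in (k0 + 1L):length(elec_order)) {
        cand <- first_free_in_window(elec_order[j], t_last, t_last + w)
        if (!is.na(cand)) {
          chain <- c(chain, cand)
          t_last <- time[cand]
        }
      }
      if (length(chain) >= 2L) {
        assigned[chain] <<- TRUE
        k <- k + 1L
        dir <- if (time[chain[length(chain)]] > time[chain[1L]]) label else "ambiguous"
        events[[k]] <- tibble(
          direction = dir, electrode = elec[chain],
          position_um = pos[elec[chain]], time_s = time[chain]
        )
      }
    }
    events
  }

  fwd <- run_pass(seq_len(ne), "forward")
  bwd <- run_pass(rev(seq_len(ne)), "backward")
  evs <- c(fwd, bwd)
  if (length(evs) == 0L) {
    return(structure(empty, class = c("mea_events", class(empty))))
  }
  out <- purrr::list_rbind(evs)
  out <- tibble(event_id = rep(seq_along(evs), times = purrr::map_int(evs, nrow))) |>
    dplyr::bind_cols(out)
  # stable ordering: by first spike time of each event
  ord <- out |>
    group_by(.data$event_id) |>
    summarise(t0 = min(.data$time_s), .groups = "drop") |>
    arrange(.data$t0) |>
    mutate(new_id = row_number())
  out <- out |>
    left_join(ord |> select("event_id", "new_id"), by = "event_id") |>
    mutate(event_id = .data$new_id) |>
    select(-"new_id") |>
    arrange(.data$event_id, .data$position_um)
  structure(out, class = c("mea_events", class(empty)))
}

#' Percentage of forward-propagating events
#'
#' `100 * n_forward / (n_forward + n_backward)`; ambiguous events are
#' excluded. With zero directional events the fraction is undefined and `NA`
#' is returned.
#'
#' @param events An `mea_events` tibble from [group_events()].
#' @param weight `"event"` (default) counts each event once; `"spike"`
#'   weights events by their number of constituent spikes.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
forward_fraction <- function(events, weight = c("event", "spike")) {
  weight <- match.arg(weight)
  if (nrow(events) == 0L) return(NA_real_)
  per_event <- events |> distinct(.data$event_id, .data$direction)
  if (weight == "spike") {
    sizes <- events |> count(.data$event_id, name = "w")
    per_event <- per_event |> left_join(sizes, by = "event_id")
  } else {
    per_event$w <- 1L
  }
  nf <- sum(per_event$w[per_event$direction == "forward"])
  nb <- sum(per_event$w[per_event$direction == "backward"])
  if (nf + nb == 0L) return(NA_real_)
  100 * nf / (nf + nb)
}

#' Per-event conduction velocity
#'
#' Least-squares slope of electrode position (m) against spike time (s) over
#' each event's electrodes; the velocity is the absolute slope. Events with
#' zero time span would have infinite speed and are flagged invalid.
#'
#' @param events An `mea_events` tibble from [group_events()].
#' @return Tibble with `event_id`, `direction`, `n_electrodes`,
#'   `velocity_mps`, `valid`.
#' @examples
#' # positions 250/750/1250 um at 0/0.625/1.25 ms -> 0.8 m/s
#' @export
event_velocities <- function(events) {
  if (nrow(events) == 0L) {
    return(tibble(event_id = integer(), direction = character(),
                  n_electrodes = integer(), velocity_mps = numeric(),
                  valid = logical()))
  }
  events |>
    group_by(.data$event_id, .data$direction) |>
    summarise(
      n_electrodes = dplyr::n(),
      velocity_mps = {
        dt <- diff(range(.data$time_s))
        if (dt <= 0) NA_real_ else {
          abs(unname(lsfit(.data$time_s, .data$position_um * 1e-6)$coefficients[2L]))
        }
      },
      .groups = "drop"
    ) |>
    mutate(valid = is.finite(.data$velocity_mps)) |>
    arrange(.data$event_id)
}

#' Mean conduction velocity of a recording
#'
#' Mean over valid per-event velocities, the per-network conduction-speed
#' summary reported for a recording window.
#'
#' @param velocities Tibble from [event_velocities()].
#' @return Mean velocity in m/s, or `NA_real_` if no event is valid.
#' @export
mean_velocity <- function(velocities) {
  v <- velocities$velocity_mps[velocities$valid]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Conduction fidelity between a proximal and a distal electrode
#'
#' How many spikes at the proximal (source-side) electrode reach the distal
#' (target-side) electrode. With the expected delay `T = distance / velocity`
#' a proximal spike counts as conducted if an as-yet-unmatched distal spike
#' falls in `[tol[1] * T, tol[2] * T]` after it; proximal spikes are matched
#' earliest-first and each distal spike matches at most one of them.
#'
#' @param prox_times_s Spike times at the proximal electrode (s).
#' @param dist_times_s Spike times at the distal electrode (s).
#' @param distance_um Electrode separation in micrometres (> 0).
#' @param mean_velocity_mps Mean conduction velocity in m/s (> 0), typically
#'   from [mean_velocity()] on the same recording.
#' @param tol Multiplicative window `(lo, hi)` applied to `T`
#'   (default `c(0.5, 2)`).
#' @return Fidelity percentage in `[0, 100]`; `NA_real_` when the proximal
#'   train is empty (undefined).
#' @export
conduction_fidelity <- function(prox_times_s, dist_times_s, distance_um,
                                mean_velocity_mps, tol = c(0.5, 2)) {
  check_number(distance_um, "distance_um", lower = 0, strict_lower = TRUE)
  check_number(mean_velocity_mps, "mean_velocity_mps", lower = 0, strict_lower = TRUE)
  if (length(tol) != 2L || tol[1L] < 0 || tol[2L] <= tol[1L]) {
    abort("`tol` must be increasing non-negative bounds (lo, hi).")
  }
  if (length(prox_times_s) == 0L) return(NA_real_)
  if (length(dist_times_s) == 0L) return(0)
  T_exp <- (distance_um * 1e-6) / mean_velocity_mps
  prox <- sort(prox_times_s)
  dist <- sort(dist_times_s)
  used <- logical(length(dist))
  matched <- 0L
  for (tp in prox) {
    lo <- tp + tol[1L] * T_exp
    hi <- tp + tol[2L] * T_exp
    i <- findInterval(lo, dist, left.open = TRUE) + 1L
    while (i <= length(dist) && dist[i] <= hi) {
      if (!used[i]) {
        used[i] <- TRUE
        matched <- matched + 1L
        break
      }
      i <- i + 1L
    }
  }
  100 * matched / length(prox)
}

#' Full propagation analysis of one recording window
#'
#' Runs [group_events()], [event_velocities()], [forward_fraction()] and
#' [conduction_fidelity()] (between the first and last electrode of the
#' channel) and bundles the results. When no event yields a velocity the
#' fidelity window falls back to `default_velocity_mps`.
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`).
#' @param layout The [channel_layout()].
#' @param duration_s Recording duration in seconds.
#' @param pair_window_ms See [group_events()].
#' @param fidelity_tol See [conduction_fidelity()].
#' @param default_velocity_mps Fallback mean velocity (m/s) when none is
#'   estimable (default 0.8).
#' @return An object of class `channel_propagation` with elements `events`,
#'   `velocities` and `summary`; see [glance.channel_propagation()].
#' @export
analyze_propagation <- function(trains, layout, duration_s,
                                pair_window_ms = 5, fidelity_tol = c(0.5, 2),
                                default_velocity_mps = 0.8) {
  events <- group_events(trains, layout, pair_window_ms = pair_window_ms)
  vel <- event_velocities(events)
  v_mean <- mean_velocity(vel)
  v_for_fid <- if (is.na(v_mean)) default_velocity_mps else v_mean
  ne <- n_electrodes(layout)
  prox <- trains$time_s[trains$electrode == 1L]
  dist <- trains$time_s[trains$electrode == ne]
  span_um <- diff(range(layout$electrode_positions_um))
  fid <- if (ne >= 2L && span_um > 0) {
    conduction_fidelity(prox, dist, span_um, v_for_fid, tol = fidelity_tol)
  } else {
    NA_real_
  }
  per_event <- events |> distinct(.data$event_id, .data$direction)
  summary <- tibble(
    n_events = nrow(per_event),
    n_forward = sum(per_event$direction == "forward"),
    n_backward = sum(per_event$direction == "backward"),
    n_ambiguous = sum(per_event$direction == "ambiguous"),
    forward_pct = forward_fraction(events),
    mean_velocity_mps = v_mean,
    fidelity_pct = fid,
    duration_s = duration_s
  )
  structure(
    list(events = events, velocities = vel, summary = summary,
         layout = layout),
    class = "channel_propagation"
  )
}

#' @describeIn analyze_propagation Per-event tibble (direction, electrode
#'   span, fitted velocity).
#' @param x,object A `channel_propagation`.
#' @param ... Unused.
#' @method tidy channel_propagation
#' @export
tidy.channel_propagation <- function(x, ...) {
  x$velocities
}

#' One-row summary of a propagation analysis
#'
#' @param x A `channel_propagation` from [analyze_propagation()].
#' @param ... Unused.
#' @return One-row tibble: event counts, `forward_pct`,
#'   `mean_velocity_mps`, `fidelity_pct`.
#' @method glance channel_propagation
#' @export
glance.channel_propagation <- function(x, ...) {
  x$summary
}

#' @export
print.channel_propagation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<channel_propagation> %d events (%d fwd / %d bwd / %d amb)\n",
    s$n_events, s$n_forward, s$n_backward, s$n_ambiguous
  ))
  cat(sprintf("forward %.1f%% | mean speed %.3f m/s | fidelity %.1f%%\n",
              s$forward_pct, s$mean_velocity_mps, s$fidelity_pct))
  invisible(x)
}

#' @method autoplot channel_propagation
#' @export
autoplot.channel_propagation <- function(object, ...) {
  v <- object$velocities |> filter(.data$valid)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$velocity_mps, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = "conduction velocity (m/s)", y = "events") +
    ggplot2::theme_minimal()
}
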