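# Event grouping, directionality, STTH, conduction velocity and fidelity.

test_that("monotone chains across electrodes become single directional events", {
  lay <- lay4()
  fwd <- trains_tbl(list(`1` = 0.1, `2` = 0.1 + 6e-4, `3` = 0.1 + 12e-4,
                         `4` = 0.1 + 18e-4), lay)
  ev <- group_events(fwd, lay)
  expect_equal(dplyr::n_distinct(ev$event_id), 1L)
  expect_equal(unique(ev$direction), "forward")
  expect_equal(nrow(ev), 4L)

  bwd <- trains_tbl(list(`4` = 0.1, `3` = 0.1 + 6e-4, `2` = 0.1 + 12e-4,
                         `1` = 0.1 + 18e-4), lay)
  evb <- group_events(bwd, lay)
  expect_equal(dplyr::n_distinct(evb$event_id), 1L)
  expect_equal(unique(evb$direction), "backward")
})

test_that("direction labels flip under reversal of the position axis", {
  lay <- lay4()
  # sparse traffic: greedy grouping is only exactly symmetric when events
  # do not overlap within the pairing window
  sp <- sim_spec(duration_s = 40, event_rate_hz = 0.8, forward_fraction = 0.7,
                 seed = 17)
  st <- simulate_spike_trains(lay, sp)
  ev <- group_events(st$trains, lay)
  # reverse the axis: electrode e -> ne + 1 - e
  rev_trains <- st$trains |>
    dplyr::mutate(electrode = 5L - electrode,
                  position_um = lay$electrode_positions_um[electrode])
  ev_rev <- group_events(rev_trains, lay)
  tab <- function(e) table(factor(dplyr::distinct(e, event_id, direction)$direction,
                                  levels = c("forward", "backward", "ambiguous")))
  t1 <- tab(ev); t2 <- tab(ev_rev)
  expect_equal(unname(t1["forward"]), unname(t2["backward"]))
  expect_equal(unname(t1["backward"]), unname(t2["forward"]))
})

test_that("on jitter-free dropout-free synthetics grouping recovers ground truth", {
  lay <- lay4()
  sp <- sim_spec(duration_s = 60, event_rate_hz = 1, velocity_jitter_frac = 0,
                 forward_fraction = 0.8, dropout_prob_per_electrode = 0, seed = 23)
  st <- simulate_spike_trains(lay, sp)
  ev <- group_events(st$trains, lay)
  expect_equal(dplyr::n_distinct(ev$event_id),
               dplyr::n_distinct(st$truth$event_id))
  got <- ev |> dplyr::arrange(time_s) |> dplyr::pull(time_s)
  want <- st$truth |> dplyr::arrange(arrival_time_s) |>
    dplyr::pull(arrival_sample) / 25000
  expect_equal(got, want)
  # per-event direction matches
  dir_got <- ev |> dplyr::distinct(event_id, direction) |>
    dplyr::count(direction) |> as.data.frame()
  dir_want <- st$truth |> dplyr::distinct(event_id, direction) |>
    dplyr::count(direction) |> as.data.frame()
  expect_equal(dir_got, dir_want)
})

test_that("forward_fraction is the forward share of directional events", {
  lay <- lay2()
  mk <- function(n_f, n_b) {
    evs <- c(
      purrr::map(seq_len(n_f), ~ tibble::tibble(
        event_id = .x, direction = "forward", electrode = 1:2,
        position_um = c(250, 750), time_s = .x + c(0, 5e-4))),
      purrr::map(seq_len(n_b), ~ tibble::tibble(
        event_id = n_f + .x, direction = "backward", electrode = 2:1,
        position_um = c(750, 250), time_s = 100 + .x + c(0, 5e-4)))
    )
    purrr::list_rbind(evs)
  }
  expect_equal(forward_fraction(mk(9, 1)), 90)
  expect_equal(forward_fraction(mk(5, 0)), 100)
  expect_true(is.na(forward_fraction(mk(0, 0))))
})

test_that("event velocity is the regression slope of position on time", {
  lay3 <- channel_layout(c(250, 750, 1250), 1500)
  ev <- tibble::tibble(event_id = 1L, direction = "forward", electrode = 1:3,
                       position_um = c(250, 750, 1250),
                       time_s = c(0, 0.625e-3, 1.25e-3))
  v <- event_velocities(ev)
  expect_equal(v$velocity_mps, 0.8)
  # two electrodes 500 um apart, 0.5 ms lag -> 1 m/s
  ev2 <- tibble::tibble(event_id = 1L, direction = "forward", electrode = 1:2,
                        position_um = c(250, 750), time_s = c(0, 5e-4))
  expect_equal(event_velocities(ev2)$velocity_mps, 1)
  # zero time span -> invalid, excluded from the mean
  ev0 <- ev2 |> dplyr::mutate(time_s = 0)
  v0 <- event_velocities(ev0)
  expect_false(v0$valid)
  expect_true(is.na(mean_velocity(v0)))
  # invariant to a constant shift of all spike times
  ev_shift <- ev |> dplyr::mutate(time_s = time_s + 3.21)
  expect_equal(event_velocities(ev_shift)$velocity_mps, 0.8)
})

test_that("velocity recovery is exact without jitter and unbiased with jitter", {
  lay <- standard_layout(2)
  sp0 <- sim_spec(duration_s = 30, event_rate_hz = 4, true_velocity_mps = 0.75,
                  velocity_jitter_frac = 0, seed = 31)
  st <- simulate_spike_trains(lay, sp0)
  # regression on exact arrival times (no sample quantisation) is exact
  tr_exact <- st$truth |>
    dplyr::filter(!dropped) |>
    dplyr::transmute(electrode, position_um, time_s = arrival_time_s)
  v <- event_velocities(group_events(tr_exact, lay))
  expect_equal(v$velocity_mps, rep(0.75, nrow(v)), tolerance = 1e-9)
})

test_that("conduction fidelity counts matched proximal spikes in the delay window", {
  # 10 proximal spikes; 5 have a distal partner at exactly T
  T_exp <- 5e-4 # 500 um at 1 m/s
  prox <- seq(1, 10)
  dist <- prox[1:5] + T_exp
  expect_equal(conduction_fidelity(prox, dist, 500, 1), 50)
  expect_equal(conduction_fidelity(prox, numeric(), 500, 1), 0)
  expect_true(is.na(conduction_fidelity(numeric(), dist, 500, 1)))
  # each distal spike matches at most one proximal spike
  expect_equal(conduction_fidelity(c(1, 1.0001), c(1 + T_exp), 500, 1), 50)
  expect_error(conduction_fidelity(prox, dist, 500, 1, tol = c(2, 0.5)), "tol")
})

test_that("STTH concentrates forward mass at lags growing with distance", {
  lay <- lay4()
  # one forward event at 0.8 m/s: lags 0.625 ms per 500 um rank
  tr <- trains_tbl(list(`1` = 0.1, `2` = 0.1 + 0.625e-3,
                        `3` = 0.1 + 1.25e-3, `4` = 0.1 + 1.875e-3), lay)
  h <- build_stth(tr, lay, trigger_electrode = 1)
  mass <- h |> dplyr::filter(count > 0)
  expect_equal(nrow(mass), 3L)
  expect_equal(mass$electrode, 2:4)
  lag_expect <- 0.625 * 1:3
  expect_true(all(abs(mass$lag_ms - lag_expect) <= 0.1 + 1e-9)) # within half a bin
  expect_true(all(mass$lag_ms > 0))
  # no spikes on other electrodes -> all-zero histograms
  h0 <- build_stth(trains_tbl(list(`1` = c(0.1, 0.2)), lay), lay, 1)
  expect_true(all(h0$count == 0))
  # support bounded by the window
  expect_true(all(abs(h$lag_ms) <= 5))
})

test_that("analyze_propagation bundles summary, tidy and glance views", {
  lay <- lay4()
  sp <- sim_spec(duration_s = 30, event_rate_hz = 3, forward_fraction = 0.9,
                 seed = 41)
  st <- simulate_spike_trains(lay, sp)
  pa <- analyze_propagation(st$trains, lay, 30)
  g <- glance(pa)
  expect_true(all(c("forward_pct", "mean_velocity_mps", "fidelity_pct") %in%
                    names(g)))
  expect_gte(g$forward_pct, 0); expect_lte(g$forward_pct, 100)
  expect_gte(g$fidelity_pct, 0); expect_lte(g$fidelity_pct, 100)
  expect_equal(nrow(tidy(pa)), g$n_events)
})
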