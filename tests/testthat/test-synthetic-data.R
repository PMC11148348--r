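# The recording / calcium / mask / cohort generators and their ground truth.

test_that("arrival lag between electrodes follows distance / velocity", {
  lay <- lay2()
  sp <- sim_spec(duration_s = 5, event_rate_hz = 1, true_velocity_mps = 1,
                 velocity_jitter_frac = 0, forward_fraction = 1,
                 noise_sigma_uv = 0, seed = 11)
  sim <- simulate_recording(lay, sp)
  tr <- sim$truth
  lag_t <- tr$arrival_time_s[tr$electrode == 2] - tr$arrival_time_s[tr$electrode == 1]
  expect_equal(lag_t, rep(5e-4, length(lag_t))) # 0.5 mm at 1 m/s = 0.5 ms
  lag_s <- tr$arrival_sample[tr$electrode == 2] - tr$arrival_sample[tr$electrode == 1]
  expect_true(all(lag_s %in% c(12L, 13L))) # 12.5 samples at 25 kHz, rounded
})

test_that("zero noise and zero event rate give an all-zero recording", {
  sim <- simulate_recording(
    lay2(), sim_spec(duration_s = 1, event_rate_hz = 0, noise_sigma_uv = 0, seed = 1)
  )
  expect_true(all(sim$recording$voltage == 0))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("generators are bit-reproducible and match a direct Poisson draw", {
  lay <- lay2()
  sp <- sim_spec(duration_s = 60, event_rate_hz = 5, seed = 42)
  # dense traffic: occasional template overlaps (warned elsewhere) are fine here
  s1 <- suppressWarnings(simulate_recording(lay, sp))
  s2 <- suppressWarnings(simulate_recording(lay, sp))
  expect_identical(s1$recording$voltage, s2$recording$voltage)
  expect_identical(s1$truth, s2$truth)
  n_events <- dplyr::n_distinct(s1$truth$event_id)
  # oracle: same seed, same draw path -> identical Poisson count
  expect_identical(n_events, withr::with_seed(42L, rpois(1L, 5 * 60)))
  expect_lt(abs(n_events - 300), 3 * sqrt(300))
  # the train-level generator shares the event draw path
  st <- simulate_spike_trains(lay, sp)
  expect_identical(st$truth, s1$truth)
})

test_that("forward arrivals increase and backward arrivals decrease with position", {
  for (i in 1:10) {
    lay <- standard_layout(sample(c(2, 4, 6), 1))
    sp <- sim_spec(duration_s = 10, event_rate_hz = 3,
                   true_velocity_mps = runif(1, 0.3, 1.5),
                   velocity_jitter_frac = 0.1,
                   forward_fraction = 0.5, seed = i)
    tr <- simulate_spike_trains(lay, sp)$truth
    mono <- tr |>
      dplyr::group_by(event_id, direction) |>
      dplyr::summarise(
        ok = all(diff(arrival_time_s[order(position_um)]) *
                   ifelse(direction[1] == "forward", 1, -1) > 0),
        .groups = "drop"
      )
    expect_true(all(mono$ok))
  }
})

test_that("empirical event rate converges to the configured rate", {
  lay <- lay2()
  sp <- sim_spec(duration_s = 600, event_rate_hz = 4, seed = 7)
  n <- dplyr::n_distinct(simulate_spike_trains(lay, sp)$truth$event_id)
  expect_lt(abs(n / 600 - 4), 3 * sqrt(4 / 600)) # 3 SE of a Poisson rate
})

test_that("overlapping templates on one electrode superpose with a warning", {
  lay <- channel_layout(c(250, 750), 1000)
  sp <- sim_spec(duration_s = 0.5, event_rate_hz = 150, noise_sigma_uv = 0,
                 velocity_jitter_frac = 0, seed = 13)
  expect_warning(simulate_recording(lay, sp), "superposing")
})

test_that("dropped arrivals leave no template on that electrode", {
  lay <- lay2()
  sp <- sim_spec(duration_s = 20, event_rate_hz = 2, noise_sigma_uv = 0,
                 dropout_prob_per_electrode = 0.5, seed = 3)
  sim <- simulate_recording(lay, sp)
  det <- detect_recording(sim$recording, filter = FALSE, sigma = 1)
  expect_identical(det$sample, truth_to_trains(sim$truth, lay)$sample)
  expect_gt(sum(sim$truth$dropped), 0)
})

test_that("calcium: single pulse reaches the kernel peak; slow trains do not depress", {
  # kernel normalisation is exact in continuous time
  rise <- 0.05; decay <- 1.5
  s_star <- rise * log(1 + decay / rise)
  expect_equal(calcium_kernel(s_star, rise, decay, peak = 0.3), 0.3)
  p1 <- stim_protocol("continuous", isi_ms = 256, n_cycles = 1)
  spec <- calcium_sim_spec(p1, noise_sigma = 0, kernel_peak = 0.3, seed = 2,
                           frame_interval_s = 0.001)
  sim <- simulate_calcium(spec)
  # ISI 256 ms is far below the cutoff: every pulse at full efficacy
  expect_true(all(abs(sim$pulses$efficacy - 1) < 1e-9))
  # trace maximum approaches the single-kernel peak (dense sampling)
  one <- calcium_sim_spec(
    stim_protocol("continuous", isi_ms = 256, n_cycles = 1, n_pulses = 1,
                  stim_duration_s = 10),
    noise_sigma = 0, kernel_peak = 0.3, frame_interval_s = 0.001, seed = 2
  )
  tr <- simulate_calcium(one)$trace
  dffmax <- max(tr$f / one$baseline_f0 - 1)
  expect_equal(dffmax, 0.3, tolerance = 1e-3)
})

test_that("calcium generator is seed-deterministic and validates the protocol", {
  p <- stim_protocol("burst", n_cycles = 3)
  a <- simulate_calcium(calcium_sim_spec(p, seed = 5))
  b <- simulate_calcium(calcium_sim_spec(p, seed = 5))
  expect_identical(a$trace$f, b$trace$f)
  expect_error(
    stim_protocol("continuous", isi_ms = 32, n_pulses = 1000),
    "beyond the cycle"
  )
})

test_that("neurite masks are deterministic and rays hit every shell", {
  m1 <- simulate_neurite_mask(3, 100, 400, px_per_um = 0.5, seed = 21)
  m2 <- simulate_neurite_mask(3, 100, 400, px_per_um = 0.5, seed = 21)
  expect_identical(m1$mask, m2$mask)
  expect_error(simulate_neurite_mask(2, 100, 400, px_per_um = 0.5,
                                     seed = 1, img_px = 50),
               "exceeds the image bounds")
  m0 <- simulate_neurite_mask(0, 100, 0, px_per_um = 0.5, img_px = 301)
  pr <- sholl_profile(m0$mask, m0$center_px, 100, max_radius_um = 150,
                      px_per_um = 0.5)
  expect_true(all(pr$n_intersections == 0L))
})

test_that("cohorts realise configured integrity fractions exactly", {
  co <- simulate_cohort(10, morph_fraction = 0.9, func_fraction = 0.5,
                        n_electrodes = 6, seed = 8)
  ann <- purrr::map_lgl(co, ~ .x$annotations$axons_reach_target_well)
  expect_equal(sum(ann), 9L)
  cs <- cohort_summary(co)
  expect_equal(sum(cs$pct_active >= 75), 5L)
  expect_equal(sum(cs$functional), 5L)
  coh <- attr(cs, "cohort")
  expect_equal(coh$morphological_integrity_pct, 90)
  expect_equal(coh$functional_integrity_pct, 50)
  one <- simulate_cohort(1, 1, 1, seed = 2)
  cs1 <- cohort_summary(one)
  expect_true(cs1$functional && cs1$axons_reach_target_well && cs1$included)
  expect_error(simulate_cohort(5, morph_fraction = 1.2, seed = 1), "morph_fraction")
})
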