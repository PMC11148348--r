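# dF/F0 metrics: frame averaging, normalisation, PER, sustain slope,
# classification and transmission fidelity.

test_that("frame averaging takes non-overlapping block means", {
  expect_equal(average_frames(1:10, 10), 5.5)
  expect_equal(average_frames(c(1, 5, 3), 1), c(1, 5, 3))
  expect_equal(average_frames(rep(2, 40), 10), rep(2, 4))
  expect_equal(average_frames(1:25, 10), c(5.5, 15.5)) # remainder dropped
  expect_error(average_frames(1:10, 0), "n")
})

test_that("dF/F0 normalises to the pre-stimulus baseline mean", {
  d <- dff(c(98, 100, 102, 110), baseline_idx = 1:3)
  expect_equal(attr(d, "f0"), 100)
  expect_equal(d[4], 0.10)
  expect_equal(as.numeric(dff(rep(7, 5), 1:2)), rep(0, 5))
  expect_error(dff(c(-3, -3, 1), 1:2), "positive")
})

test_that("dF/F0 is invariant under fluorescence rescaling", {
  for (i in 1:15) {
    f <- withr::with_seed(i, 100 + rnorm(50))
    a <- withr::with_seed(i + 50, runif(1, 0.1, 10))
    expect_equal(as.numeric(dff(a * f, 1:10)), as.numeric(dff(f, 1:10)))
  }
})

test_that("PER is the windowed maximum and identical cycles give zero variance", {
  p <- stim_protocol("continuous", isi_ms = 32, n_cycles = 1)
  dt <- 0.1
  time_s <- seq(0, p$cycle_s - dt, by = dt)
  dffs <- numeric(length(time_s))
  # triangle peaking at 0.5 at t = 17 s (2 s after onset)
  up <- time_s >= 15 & time_s <= 17
  down <- time_s > 17 & time_s <= 19
  dffs[up] <- 0.5 * (time_s[up] - 15) / 2
  dffs[down] <- 0.5 * (1 - (time_s[down] - 17) / 2)
  per <- peak_evoked_response(dffs, time_s, p)
  expect_equal(per$per, 0.5)
  expect_equal(per$per_time_s, 17)
  # 40 identical cycles -> variance exactly 0 (cycle length aligned to the
  # frame grid so every cycle samples the same pattern)
  pb <- stim_protocol("burst", n_cycles = 40, recovery_s = 3.025)
  tb <- seq(0, 40 * pb$cycle_s - 0.01, by = 0.01)
  # triangular response peaking mid-window, away from window boundaries
  one <- pmax(0, 1 - abs(seq_len(330) - 100) / 50)
  d40 <- rep(one, 40)[seq_along(tb)]
  pers <- peak_evoked_response(d40, tb, pb)
  expect_equal(stats::var(pers$per), 0)
})

test_that("sustain slope fits the PER-to-stimulation-end region exactly", {
  p <- stim_protocol("continuous", isi_ms = 32, n_cycles = 1)
  dt <- 0.1
  time_s <- seq(0, p$cycle_s - dt, by = dt)
  mk <- function(end_val) {
    d <- numeric(length(time_s))
    ramp <- time_s >= 15 & time_s < 17
    d[ramp] <- 0.5 * (time_s[ramp] - 15) / 2
    dec <- time_s >= 17 & time_s <= 30 - dt + 1e-9
    d[dec] <- 0.5 + (end_val - 0.5) * (time_s[dec] - 17) / 13
    d
  }
  # linear decay 0.5 -> 0.2 over 13 s: slope -0.3/13
  sl <- sustain_slope(mk(0.2), time_s, p)
  expect_equal(attr(sl, "m"), -0.3 / 13, tolerance = 1e-6)
  # flat plateau after the PER -> slope ~ 0 (sustained)
  expect_equal(attr(sustain_slope(mk(0.5), time_s, p), "m"), 0, tolerance = 1e-9)
  # rising tail -> positive slope
  expect_gt(attr(sustain_slope(mk(0.8), time_s, p), "m"), 0)
})

test_that("classification is a monotone threshold on the slope", {
  expect_equal(classify_sustained(0), "sustained")
  expect_equal(classify_sustained(-0.05), "transient")
  expect_equal(classify_sustained(-0.005), "sustained") # inclusive boundary
  ms <- seq(-0.02, 0.01, by = 0.001)
  lab <- classify_sustained(ms)
  expect_true(all(diff(lab == "sustained") >= 0)) # monotone in m
  expect_error(classify_sustained(NaN), "finite")
})

test_that("transmission fidelity thresholds PERs at baseline + 5 robust SD", {
  base <- rep(c(0.01, -0.01), 50) # sigma_b = 0.014826, mean 0
  expect_equal(transmission_fidelity(0.08, base), 100) # 0.08 > 0.0741
  expect_equal(transmission_fidelity(0.07, base), 0)   # 0.07 < 0.0741
  pers <- c(rep(0.08, 30), rep(0.01, 10))
  expect_equal(transmission_fidelity(pers, base), 75)
  expect_equal(transmission_fidelity(rep(0.001, 40), base), 0)
  # degenerate constant baseline: any PER above the mean is detectable
  expect_equal(transmission_fidelity(c(0.2, 0), rep(0, 100)), 50)
  # non-increasing in the SD multiplier
  fids <- vapply(c(2, 5, 8, 12), function(k)
    transmission_fidelity(pers, base, sd_multiplier = k), numeric(1))
  expect_true(all(diff(fids) <= 0))
})

test_that("noise-free cycles recover generator PER and slope to 1e-9", {
  for (isi in c(16, 64)) {
    p <- stim_protocol("continuous", isi_ms = isi, n_cycles = 1)
    sim <- simulate_calcium(calcium_sim_spec(p, noise_sigma = 0, seed = 1))
    cr <- analyze_calcium(sim$trace, p)
    cy <- tidy(cr)
    expect_equal(cy$per, sim$truth$true_per, tolerance = 1e-9)
    expect_equal(cy$slope, sim$truth$true_slope, tolerance = 1e-9)
  }
})

test_that("burst analysis reports PER statistics and fidelity", {
  pb <- stim_protocol("burst", n_cycles = 10)
  sim <- simulate_calcium(calcium_sim_spec(pb, noise_sigma = 0.3, seed = 9))
  cr <- analyze_calcium(sim$trace, pb)
  g <- glance(cr)
  expect_equal(g$frequency_hz, 200)
  expect_gt(g$per_mean, 0.1)
  expect_equal(g$fidelity_pct, 100)
  expect_true(is.na(g$slope_m))
})
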