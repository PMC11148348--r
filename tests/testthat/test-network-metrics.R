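# Inclusion screening and the cohort-level integrity metrics.

ok_flags <- list(spheroid_in_well = TRUE, axon_escaped = FALSE,
                 channel_over_electrodes = TRUE, cross_network_growth = FALSE,
                 reached_first_electrode = TRUE)

test_that("inclusion requires all five criteria and lists every violation", {
  res <- apply_inclusion(ok_flags)
  expect_true(res$included)
  expect_length(res$reasons, 0L)

  esc <- modifyList(ok_flags, list(axon_escaped = TRUE))
  res2 <- apply_inclusion(esc)
  expect_false(res2$included)
  expect_match(res2$reasons, "criterion 2")

  two <- modifyList(ok_flags, list(axon_escaped = TRUE, spheroid_in_well = FALSE))
  expect_length(apply_inclusion(two)$reasons, 2L)

  expect_error(apply_inclusion(ok_flags[-1]), "Missing inclusion flag")
})

test_that("active electrodes use a strict rate threshold", {
  lay <- channel_layout(c(250, 750, 1250, 1750), 2000)
  # rates 2, 0.5, 3, 0 Hz over 10 s
  tr <- trains_tbl(list(`1` = seq(0.1, by = 0.5, length.out = 20),
                        `2` = seq(0.1, by = 2, length.out = 5),
                        `3` = seq(0.1, by = 1 / 3, length.out = 30),
                        `4` = numeric()), lay)
  act <- active_electrodes(tr, lay, 10)
  expect_equal(act$pct, 50)
  expect_equal(act$electrodes$active, c(TRUE, FALSE, TRUE, FALSE))
  # exactly 1.0 Hz is inactive ("above 1 Hz" is strict)
  tr1 <- trains_tbl(list(`1` = seq(0.5, by = 1, length.out = 10)), lay)
  expect_equal(active_electrodes(tr1, lay, 10)$electrodes$active[1], FALSE)
  # no spikes at all
  expect_equal(active_electrodes(tr1[0, ], lay, 10)$pct, 0)
})

test_that("functional integrity flips inclusively at 75% active electrodes", {
  mk <- function(n_active, ne) {
    lay <- channel_layout(seq(250, by = 500, length.out = ne), 500 * ne)
    ts <- purrr::map(seq_len(ne), function(e) {
      if (e <= n_active) seq(0.1, by = 0.45, length.out = 22) else numeric()
    })
    names(ts) <- seq_len(ne)
    list(trains = trains_tbl(ts, lay), lay = lay)
  }
  f <- function(n_active, ne) {
    x <- mk(n_active, ne)
    functional_integrity(x$trains, x$lay, 10)
  }
  expect_true(f(5, 6))   # 83.3% >= 75%
  expect_false(f(4, 6))  # 66.7%
  expect_true(f(3, 4))   # exactly 75%: inclusive boundary
  expect_false(f(2, 4))
})

test_that("morphological integrity uses spheroid-containing networks as denominator", {
  ann <- tibble::tibble(
    network_id = 1:11,
    contains_retinal_spheroid = c(rep(TRUE, 10), FALSE),
    axons_reach_target_well = c(rep(TRUE, 9), FALSE, TRUE)
  )
  mi <- morphological_integrity(ann)
  expect_equal(mi$pct, 90)
  # the spheroid-free network is outside the denominator
  expect_equal(morphological_integrity(ann[11, ])$pct %in% NA, TRUE)
  ann0 <- ann |> dplyr::mutate(axons_reach_target_well = FALSE)
  expect_equal(morphological_integrity(ann0)$pct, 0)
})

test_that("mean firing rate averages only active electrodes", {
  lay <- channel_layout(c(250, 750, 1250), 1500)
  # rates 14, 16, 0.2 Hz over 10 s
  tr <- trains_tbl(list(`1` = seq(0, by = 1 / 14, length.out = 140),
                        `2` = seq(0, by = 1 / 16, length.out = 160),
                        `3` = c(0.5, 5)), lay)
  expect_equal(mean_firing_rate(tr, lay, 10), 15)
  # single active electrode
  tr1 <- trains_tbl(list(`1` = seq(0, by = 1 / 14, length.out = 140)), lay)
  expect_equal(mean_firing_rate(tr1, lay, 10), 14)
  expect_true(is.na(mean_firing_rate(tr1[0, ], lay, 10)))
})

test_that("metrics are invariant to electrode order permutations", {
  lay <- channel_layout(c(250, 750, 1250, 1750), 2000)
  ts <- list(`1` = seq(0.1, by = 0.3, length.out = 33),
             `2` = numeric(),
             `3` = seq(0.1, by = 0.2, length.out = 50),
             `4` = seq(0.1, by = 0.9, length.out = 11))
  tr <- trains_tbl(ts, lay)
  perm <- c(3L, 1L, 4L, 2L)
  tr_p <- tr |> dplyr::mutate(electrode = perm[electrode])
  expect_equal(active_electrodes(tr, lay, 10)$pct,
               active_electrodes(tr_p, lay, 10)$pct)
  expect_equal(mean_firing_rate(tr, lay, 10), mean_firing_rate(tr_p, lay, 10))
})

test_that("electrode-disk intersection with a mask counts any positive pixel", {
  # 5 electrodes along y = 100 um; rays cross 4 of the 5 disks
  px_per_um <- 0.5
  mask <- matrix(FALSE, 120, 600)
  for (x_um in c(100, 200, 300, 400)) {
    xs <- round((x_um + c(-10:10)) * px_per_um)
    mask[cbind(round(100 * px_per_um), xs)] <- TRUE
  }
  xy <- cbind(x = c(100, 200, 300, 400, 500), y = rep(100, 5))
  res <- intersected_electrodes(mask, xy, px_per_um)
  expect_equal(res$pct, 80)
  expect_equal(res$electrodes$intersected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(intersected_electrodes(mask * 0, xy, px_per_um)$pct, 0)
  full <- matrix(TRUE, 120, 600)
  expect_equal(intersected_electrodes(full, xy, px_per_um)$pct, 100)
  expect_error(intersected_electrodes(mask, xy, NULL), "scale")
})
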