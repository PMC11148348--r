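#' Simulate an annotated cohort of two-node networks
#'
#' Builds `n_networks` network records with spike trains and annotation
#' flags such that a configured fraction of networks is morphologically
#' intact (axons reach the target well) and a configured fraction meets the
#' functional-integrity criterion (activity above threshold on at least 75%
#' of electrodes). Fractions are realised exactly: `round(fraction * n)`
#' networks get the property, assignment randomised per seed.
#'
#' @param n_networks Number of networks (>= 1).
#' @param morph_fraction Fraction of networks with axons reaching the
#'   target well.
#' @param func_fraction Fraction of networks that are functionally intact.
#' @param n_electrodes Electrodes per channel (default 6).
#' @param pitch_um Electrode pitch (default 500).
#' @param duration_s Recording duration per network (default 60).
#' @param active_rate_hz Firing rate of active electrodes (default 14, the
#'   typical per-electrode rate in these channel networks).
#' @param inactive_rate_hz Firing rate of inactive electrodes (default 0.2).
#' @param seed Integer seed; mandatory.
#' @return A list of class `network_cohort`; each element has `id`,
#'   `layout`, `trains`, `duration_s`, `div` and `annotations` (the five
#'   inclusion flags plus `contains_retinal_spheroid` and
#'   `axons_reach_target_well`).
#' @export
simulate_cohort <- function(n_networks, morph_fraction = 1, func_fraction = 1,
                            n_electrodes = 6, pitch_um = 500, duration_s = 60,
                            active_rate_hz = 14, inactive_rate_hz = 0.2,
                            seed = NULL) {
  check_number(n_networks, "n_networks", lower = 1)
  check_number(morph_fraction, "morph_fraction", lower = 0, upper = 1)
  check_number(func_fraction, "func_fraction", lower = 0, upper = 1)
  check_number(n_electrodes, "n_electrodes", lower = 1)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  n_networks <- as.integer(n_networks)
  ne <- as.integer(n_electrodes)
  layout <- channel_layout(seq(pitch_um / 2, by = pitch_um, length.out = ne),
                           channel_length_um = pitch_um * ne)
  n_morph <- round(morph_fraction * n_networks)
  n_func <- round(func_fraction * n_networks)
  n_active_hi <- as.integer(ceiling(0.75 * ne)) # >= 75% of electrodes
  n_active_lo <- max(0L, as.integer(floor(0.5 * ne))) # clearly below 75%

  with_sim_seed(seed, {
    morph_ids <- sample(n_networks, n_morph)
    func_ids <- sample(n_networks, n_func)
    records <- purrr::map(seq_len(n_networks), function(i) {
      k_active <- if (i %in% func_ids) n_active_hi else n_active_lo
      active_el <- sample(ne, k_active)
      trains <- purrr::map(seq_len(ne), function(e) {
        rate <- if (e %in% active_el) active_rate_hz else inactive_rate_hz
        n_sp <- rpois(1L, rate * duration_s)
        if (n_sp == 0L) return(NULL)
        tibble(electrode = e,
               position_um = layout$electrode_positions_um[e],
               time_s = sort(runif(n_sp, 0, duration_s)))
      }) |> purrr::list_rbind()
      list(
        id = i, layout = layout, trains = trains, duration_s = duration_s,
        div = 28L,
        annotations = list(
          spheroid_in_well = TRUE, axon_escaped = FALSE,
          channel_over_electrodes = TRUE, cross_network_growth = FALSE,
          reached_first_electrode = TRUE,
          contains_retinal_spheroid = TRUE,
          axons_reach_target_well = i %in% morph_ids
        )
      )
    })
    structure(records, class = "network_cohort")
  })
}

#' Summarise a cohort of network records
#'
#' Computes, per network, the active-electrode percentage, functional
#' integrity, morphological intactness and the mean firing rate over active
#' electrodes; cohort-level integrity percentages are attached as the
#' `"cohort"` attribute.
#'
#' @param cohort A `network_cohort` (e.g. from [simulate_cohort()]) or list
#'   of records with `layout`, `trains`, `duration_s`, `annotations`.
#' @param frac_threshold,rate_threshold_hz See [functional_integrity()].
#' @return Tibble with one row per network; attribute `cohort` holds
#'   `morphological_integrity_pct` and `functional_integrity_pct`.
#' @export
cohort_summary <- function(cohort, frac_threshold = 0.75, rate_threshold_hz = 1) {
  rows <- purrr::map(cohort, function(rec) {
    act <- active_electrodes(rec$trains, rec$layout, rec$duration_s,
                             rate_threshold_hz)
    tibble(
      network_id = rec$id,
      included = apply_inclusion(rec$annotations[
        inclusion_criteria$flag])$included,
      contains_retinal_spheroid = rec$annotations$contains_retinal_spheroid,
      axons_reach_target_well = rec$annotations$axons_reach_target_well,
      pct_active = act$pct,
      functional = act$pct / 100 >= frac_threshold,
      mean_rate_hz = mean_firing_rate(rec$trains, rec$layout, rec$duration_s,
                                      rate_threshold_hz)
    )
  }) |> purrr::list_rbind()
  morph <- morphological_integrity(rows)
  attr(rows, "cohort") <- tibble(
    morphological_integrity_pct = morph$pct,
    functional_integrity_pct = 100 * mean(rows$functional)
  )
  rows
}
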