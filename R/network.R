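# Cohort-level morphological and functional network metrics plus the
# five-point inclusion screen applied before any per-network analysis.

inclusion_criteria <- tibble::tribble(
  ~flag,                     ~pass_value, ~criterion,
  "spheroid_in_well",        TRUE,  "criterion 1: spheroids stayed in their respective well",
  "axon_escaped",            FALSE, "criterion 2: axon bundle did not escape from the microchannel",
  "channel_over_electrodes", TRUE,  "criterion 3: full width of the microchannel over the electrodes",
  "cross_network_growth",    FALSE, "criterion 4: no neuritic growth connecting to another network",
  "reached_first_electrode", TRUE,  "criterion 5: axon bundle reached the first electrode"
)

#' Apply the network inclusion criteria
#'
#' A network enters the analysis only if all five visual-inspection criteria
#' hold: (1) spheroids stayed in their wells, (2) the axon bundle did not
#' escape the microchannel, (3) the channel runs fully over the electrodes,
#' (4) no neuritic growth connects it to another network, and (5) the bundle
#' reached the first electrode. Missing flags are an error, never silently
#' defaulted.
#'
#' @param annotations Named list (or one-row data frame) with logical fields
#'   `spheroid_in_well`, `axon_escaped`, `channel_over_electrodes`,
#'   `cross_network_growth`, `reached_first_electrode`.
#' @return List with `included` (logical) and `reasons` (character vector of
#'   every violated criterion; empty when included).
#' @examples
#' apply_inclusion(list(
#'   spheroid_in_well = TRUE, axon_escaped = FALSE,
#'   channel_over_electrodes = TRUE, cross_network_growth = FALSE,
#'   reached_first_electrode = TRUE
#' ))
#' @export
apply_inclusion <- function(annotations) {
  ann <- as.list(annotations)
  missing <- setdiff(inclusion_criteria$flag, names(ann))
  if (length(missing) > 0) {
    abort(paste0("Missing inclusion flag(s): ", paste(missing, collapse = ", ")))
  }
  vals <- purrr::map_lgl(inclusion_criteria$flag, function(f) {
    v <- ann[[f]]
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      abort(sprintf("Inclusion flag `%s` must be TRUE or FALSE.", f))
    }
    v
  })
  violated <- vals != inclusion_criteria$pass_value
  list(included = !any(violated), reasons = inclusion_criteria$criterion[violated])
}

#' Electrodes intersected by labelled axons
#'
#' An electrode counts as intersected when at least one mask-positive pixel
#' lies within its disk (default diameter 30 um, the electrode size of the
#' standard MEA grid).
#'
#' @param mask Logical (or 0/1) matrix, rows = y, columns = x.
#' @param electrode_xy_um Two-column matrix or data frame of electrode centre
#'   coordinates (x, y) in micrometres, in the mask's coordinate frame.
#' @param px_per_um Pixels per micrometre of the mask. Required; missing
#'   scale metadata is an error.
#' @param electrode_diameter_um Electrode diameter in um (default 30).
#' @return List with `pct` (percentage of intersected electrodes) and
#'   `electrodes` (tibble: `electrode`, `x_um`, `y_um`, `intersected`).
#' @export
intersected_electrodes <- function(mask, electrode_xy_um, px_per_um,
                                   electrode_diameter_um = 30) {
  if (missing(px_per_um) || is.null(px_per_um)) {
    abort("`px_per_um` scale metadata is required.")
  }
  check_number(px_per_um, "px_per_um", lower = 0, strict_lower = TRUE)
  check_number(electrode_diameter_um, "electrode_diameter_um",
               lower = 0, strict_lower = TRUE)
  xy <- as.matrix(electrode_xy_um)
  if (ncol(xy) != 2L) abort("`electrode_xy_um` must have two columns (x, y).")
  m <- mask > 0
  r_px <- electrode_diameter_um / 2 * px_per_um
  nr <- nrow(m); nc <- ncol(m)
  hit <- purrr::map_lgl(seq_len(nrow(xy)), function(i) {
    cx <- xy[i, 1L] * px_per_um
    cy <- xy[i, 2L] * px_per_um
    xs <- max(1L, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
    ys <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
    if (length(xs) == 0L || length(ys) == 0L) return(FALSE)
    sub <- m[ys, xs, drop = FALSE]
    if (!any(sub)) return(FALSE)
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    any(sub & (dx^2 + dy^2 <= r_px^2))
  })
  list(
    pct = 100 * mean(hit),
    electrodes = tibble(electrode = seq_len(nrow(xy)),
                        x_um = xy[, 1L], y_um = xy[, 2L], intersected = hit)
  )
}

#' Active electrodes of a network
#'
#' An electrode is active when its firing rate is strictly above
#' `rate_threshold_hz` (the "above 1 Hz" reading is strict: a rate of
#' exactly 1 Hz is inactive).
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`).
#' @param layout The [channel_layout()].
#' @param duration_s Recording duration in seconds.
#' @param rate_threshold_hz Activity threshold in Hz (default 1).
#' @return List with `pct` (percentage of active electrodes) and
#'   `electrodes` (tibble: `electrode`, `rate_hz`, `active`).
#' @export
active_electrodes <- function(trains, layout, duration_s, rate_threshold_hz = 1) {
  rates <- electrode_rates(trains, layout, duration_s) |>
    mutate(active = .data$rate_hz > rate_threshold_hz)
  list(pct = 100 * mean(rates$active), electrodes = rates)
}

#' Functional integrity of one network
#'
#' A network is functionally intact when spontaneous activity above the rate
#' threshold is seen on at least `frac_threshold` of its electrodes
#' ("at least 75%" is inclusive: exactly 75% is intact).
#'
#' @inheritParams active_electrodes
#' @param frac_threshold Minimum active fraction (default 0.75).
#' @return Logical.
#' @export
functional_integrity <- function(trains, layout, duration_s,
                                 frac_threshold = 0.75, rate_threshold_hz = 1) {
  check_number(frac_threshold, "frac_threshold", lower = 0, upper = 1)
  act <- active_electrodes(trains, layout, duration_s, rate_threshold_hz)
  act$pct / 100 >= frac_threshold
}

#' Morphological integrity of a cohort
#'
#' A network is morphologically intact when labelled retinal axons reach the
#' target well. The cohort percentage divides intact networks by all
#' networks containing a retinal spheroid (not only networks passing the
#' inclusion screen).
#'
#' @param annotations Data frame with one row per network and logical
#'   columns `contains_retinal_spheroid` and `axons_reach_target_well`
#'   (plus optionally `network_id`).
#' @return List with `pct` (cohort percentage, `NA` if the denominator is
#'   empty) and `networks` (tibble with per-network `intact`).
#' @export
morphological_integrity <- function(annotations) {
  ann <- as_tibble(annotations)
  for (col in c("contains_retinal_spheroid", "axons_reach_target_well")) {
    if (!col %in% names(ann)) abort(sprintf("`annotations` must contain `%s`.", col))
  }
  ann <- ann |> mutate(intact = .data$axons_reach_target_well)
  denom <- ann |> filter(.data$contains_retinal_spheroid)
  pct <- if (nrow(denom) == 0L) NA_real_ else 100 * mean(denom$intact)
  list(pct = pct, networks = ann)
}

#' Mean firing rate over active electrodes
#'
#' Mean of the per-electrode rates, with inactive electrodes (rate not above
#' the threshold) excluded. Undefined (`NA`) when no electrode is active.
#'
#' @inheritParams active_electrodes
#' @return Rate in Hz, or `NA_real_`.
#' @examples
#' # rates 14, 16 and 0.2 Hz -> mean over the active pair = 15 Hz
#' @export
mean_firing_rate <- function(trains, layout, duration_s, rate_threshold_hz = 1) {
  rates <- electrode_rates(trains, layout, duration_s)
  act <- rates$rate_hz[rates$rate_hz > rate_threshold_hz]
  if (length(act) == 0L) return(NA_real_)
  mean(act)
}
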