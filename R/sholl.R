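# Concentric-shell (Sholl) intersection analysis of neurite masks.

# ordered pixels of a rasterised circle; consecutive duplicates removed
ring_pixels <- function(cx, cy, r_px) {
  n <- max(16L, ceiling(4 * pi * r_px))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- round(cx + r_px * cos(th))
  y <- round(cy + r_px * sin(th))
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  # the ring is circular: drop a trailing pixel equal to the first
  m <- length(x)
  if (m > 1L && x[m] == x[1L] && y[m] == y[1L]) {
    x <- x[-m]; y <- y[-m]
  }
  cbind(x = x, y = y)
}

# number of maximal connected runs of TRUE in a circular logical vector
circular_runs <- function(v) {
  if (length(v) == 0L || !any(v)) return(0L)
  if (all(v)) return(1L)
  starts <- sum(v & !c(v[length(v)], v[-length(v)]))
  as.integer(starts)
}

#' Sholl intersection profile of a neurite mask
#'
#' Draws concentric circles from the spheroid edge outwards at `step_um`
#' intervals and, for each circle, counts neurite intersections as the
#' number of maximal connected runs of mask-positive pixels along the
#' rasterised circle. Circles exceeding the image bounds truncate the
#' profile with a warning.
#'
#' @param mask Logical (or 0/1) matrix, rows = y, columns = x.
#' @param center_px Spheroid centre `(x, y)` in pixels (must lie inside the
#'   mask bounds).
#' @param edge_radius_um Spheroid edge radius in micrometres.
#' @param step_um Shell spacing in micrometres (default 25).
#' @param max_radius_um Largest shell distance from the edge (default: as
#'   far as the image allows).
#' @param px_per_um Pixels per micrometre.
#' @return A tibble of class `sholl_profile` with `distance_um` (from the
#'   spheroid edge), `radius_um` (from the centre) and `n_intersections`.
#' @export
sholl_profile <- function(mask, center_px, edge_radius_um, step_um = 25,
                          max_radius_um = NULL, px_per_um = 1) {
  check_number(px_per_um, "px_per_um", lower = 0, strict_lower = TRUE)
  check_number(step_um, "step_um", lower = 0, strict_lower = TRUE)
  check_number(edge_radius_um, "edge_radius_um", lower = 0)
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  cx <- center_px[1L]; cy <- center_px[2L]
  if (cx < 1 || cx > nc || cy < 1 || cy > nr) {
    abort("`center_px` must lie inside the mask bounds.")
  }
  if (is.null(max_radius_um)) {
    max_px <- max(nr, nc) # upper bound; truncation handles the rest
    max_radius_um <- max_px / px_per_um
  }
  dists <- seq(step_um, max_radius_um, by = step_um)
  counts <- integer(0)
  kept <- numeric(0)
  for (d in dists) {
    r_px <- (edge_radius_um + d) * px_per_um
    px <- ring_pixels(cx, cy, r_px)
    inside <- px[, "x"] >= 1 & px[, "x"] <= nc & px[, "y"] >= 1 & px[, "y"] <= nr
    if (!all(inside)) {
      warn(sprintf("Shell at %g um exceeds image bounds; profile truncated.", d))
      break
    }
    v <- m[cbind(px[, "y"], px[, "x"])]
    counts <- c(counts, circular_runs(v))
    kept <- c(kept, d)
  }
  out <- tibble(distance_um = kept,
                radius_um = edge_radius_um + kept,
                n_intersections = counts)
  structure(out, class = c("sholl_profile", class(out)),
            center_px = center_px, edge_radius_um = edge_radius_um,
            step_um = step_um, px_per_um = px_per_um)
}

#' Maximum intersection count beyond a distance cutoff
#'
#' Maximum of the profile counts over shells strictly farther than
#' `min_distance_um` from the spheroid edge; nearer shells are ignored to
#' suppress false-positive counts from dendritic outgrowth close to the
#' soma.
#'
#' @param profile A [sholl_profile()].
#' @param min_distance_um Distance cutoff in micrometres (default 300).
#' @return Maximum count, or `NA_integer_` (with a warning) when no shell
#'   lies beyond the cutoff.
#' @export
max_intersections <- function(profile, min_distance_um = 300) {
  keep <- profile$distance_um > min_distance_um
  if (!any(keep)) {
    warn("No shells beyond the distance cutoff; maximum undefined.")
    return(NA_integer_)
  }
  max(profile$n_intersections[keep])
}

#' Normalise maximum intersection counts to a reference spheroid size
#'
#' Each spheroid's maximum intersection count is divided by the mean count
#' of the reference group within the same experimental repetition. Spheroids
#' flagged `wall_adherent` or `multi_spheroid` are excluded before any mean
#' is formed.
#'
#' @param df Data frame with columns `group`, `repetition`, `max_count` and
#'   optionally logical `wall_adherent` / `multi_spheroid` exclusion flags.
#' @param reference_group Group label of the reference spheroid size
#'   (default `"250"`).
#' @return The filtered tibble with added columns `reference_mean` and
#'   `normalized`.
#' @export
normalize_max <- function(df, reference_group = "250") {
  d <- as_tibble(df)
  for (col in c("group", "repetition", "max_count")) {
    if (!col %in% names(d)) abort(sprintf("`df` must contain `%s`.", col))
  }
  for (flag in c("wall_adherent", "multi_spheroid")) {
    if (flag %in% names(d)) d <- d |> filter(!.data[[flag]])
  }
  refs <- d |>
    filter(.data$group == reference_group) |>
    group_by(.data$repetition) |>
    summarise(reference_mean = mean(.data$max_count), .groups = "drop")
  missing_rep <- setdiff(unique(d$repetition), refs$repetition)
  if (length(missing_rep) > 0) {
    abort(sprintf("Repetition(s) without reference group '%s': %s",
                  reference_group, paste(missing_rep, collapse = ", ")))
  }
  if (any(refs$reference_mean == 0)) {
    abort("Reference group mean is 0; normalisation undefined.")
  }
  d |>
    left_join(refs, by = "repetition") |>
    mutate(normalized = .data$max_count / .data$reference_mean)
}

#' Plot a Sholl profile
#'
#' @param object A [sholl_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sholl_profile
#' @export
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$distance_um, y = .data$n_intersections)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance from spheroid edge (um)", y = "intersections") +
    ggplot2::theme_minimal()
}
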