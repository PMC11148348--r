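#' Simulate a binary neurite mask around a spheroid
#'
#' Generates a filled disk (the spheroid body) plus `n_neurites` one-pixel
#' radial polylines of the given length, starting at the spheroid edge.
#' Ray angles are drawn uniformly unless supplied. Deterministic per seed.
#'
#' @param n_neurites Number of radial neurites (>= 0).
#' @param spheroid_radius_um Spheroid radius in micrometres.
#' @param length_um Neurite length in micrometres (from the spheroid edge).
#' @param px_per_um Pixels per micrometre (default 0.5).
#' @param seed Integer seed (required when angles are drawn).
#' @param angles_deg Optional fixed ray angles in degrees.
#' @param img_px Optional square image side in pixels; defaults to the
#'   smallest size that contains spheroid plus neurites. An explicit size
#'   too small for the requested length is an error.
#' @return List with `mask` (logical matrix, rows = y), `center_px` (x, y),
#'   `spheroid_radius_um`, `px_per_um` and `angles_deg`.
#' @export
simulate_neurite_mask <- function(n_neurites, spheroid_radius_um = 100,
                                  length_um = 500, px_per_um = 0.5,
                                  seed = NULL, angles_deg = NULL,
                                  img_px = NULL) {
  check_number(n_neurites, "n_neurites", lower = 0)
  check_number(spheroid_radius_um, "spheroid_radius_um", lower = 0, strict_lower = TRUE)
  check_number(length_um, "length_um", lower = 0)
  check_number(px_per_um, "px_per_um", lower = 0, strict_lower = TRUE)
  reach_px <- (spheroid_radius_um + length_um) * px_per_um
  need <- 2L * ceiling(reach_px) + 5L
  if (is.null(img_px)) {
    img_px <- need
  } else if (img_px < need) {
    abort("Requested neurite length exceeds the image bounds.")
  }
  cx <- (img_px + 1) / 2
  cy <- (img_px + 1) / 2

  if (is.null(angles_deg)) {
    if (n_neurites > 0 && is.null(seed)) {
      abort("`seed` is required when ray angles are drawn randomly.")
    }
    angles_deg <- if (n_neurites > 0) {
      with_sim_seed(seed, runif(n_neurites, 0, 360))
    } else {
      numeric(0)
    }
  } else if (length(angles_deg) != n_neurites) {
    abort("`angles_deg` must have one angle per neurite.")
  }

  mask <- matrix(FALSE, nrow = img_px, ncol = img_px)
  # filled spheroid disk
  r_px <- spheroid_radius_um * px_per_um
  ys <- max(1L, floor(cy - r_px)):min(img_px, ceiling(cy + r_px))
  xs <- max(1L, floor(cx - r_px)):min(img_px, ceiling(cx + r_px))
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  disk <- outer(dy2, dx2, `+`) <= r_px^2
  mask[ys, xs] <- mask[ys, xs] | disk
  # radial 1-px rays from the edge outwards, rasterised by rounding dense
  # samples of the continuous ray (shell circles rasterise the same way, so
  # every shell crossing shares a pixel with the ray)
  if (n_neurites > 0 && length_um > 0) {
    for (a in angles_deg * pi / 180) {
      tt <- seq(spheroid_radius_um, spheroid_radius_um + length_um,
                by = 0.4 / px_per_um)
      xr <- round(cx + tt * px_per_um * cos(a))
      yr <- round(cy + tt * px_per_um * sin(a))
      ok <- xr >= 1 & xr <= img_px & yr >= 1 & yr <= img_px
      mask[cbind(yr[ok], xr[ok])] <- TRUE
    }
  }
  list(mask = mask, center_px = c(cx, cy),
       spheroid_radius_um = spheroid_radius_um,
       px_per_um = px_per_um, angles_deg = angles_deg)
}
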