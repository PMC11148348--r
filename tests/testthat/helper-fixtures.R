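# shared fixtures, built in code

lay2 <- function(fs = 25000) channel_layout(c(250, 750), 1000, sampling_rate_hz = fs)
lay4 <- function(fs = 25000) channel_layout(c(250, 750, 1250, 1750), 2000, sampling_rate_hz = fs)

# alternating +/-1 baseline (MAD 1, sigma 1.4826) with dips at given 0-based samples
dip_trace <- function(n, dip_samples0, dip_value = -10) {
  x <- rep(c(1, -1), length.out = n)
  x[dip_samples0 + 1L] <- dip_value
  x
}

# spike-train tibble from a list of per-electrode time vectors
trains_tbl <- function(times_by_electrode, layout) {
  proto <- tibble::tibble(electrode = integer(), position_um = numeric(),
                          time_s = numeric())
  rows <- purrr::imap(times_by_electrode, function(ts, e) {
    e <- as.integer(e)
    if (length(ts) == 0) return(NULL)
    tibble::tibble(electrode = e,
                   position_um = layout$electrode_positions_um[e],
                   time_s = as.numeric(ts))
  })
  dplyr::bind_rows(c(list(proto), rows))
}

# radial segment rasterised by rounding dense samples (same convention as the
# mask generator), for constructing geometric oracles
draw_radial_segment <- function(mask, cx, cy, angle_deg, r0_px, r1_px) {
  a <- angle_deg * pi / 180
  tt <- seq(r0_px, r1_px, by = 0.4)
  xr <- round(cx + tt * cos(a))
  yr <- round(cy + tt * sin(a))
  ok <- xr >= 1 & xr <= ncol(mask) & yr >= 1 & yr <= nrow(mask)
  mask[cbind(yr[ok], xr[ok])] <- TRUE
  mask
}
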