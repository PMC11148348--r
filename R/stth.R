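#' Spike-time-triggered histogram (STTH)
#'
#' For every spike on the trigger electrode, collects the time differences of
#' all other electrodes' spikes within `+/- window_ms` into per-electrode
#' histograms. Positive lags mean the other electrode fired after the
#' trigger; with a proximal trigger, forward-propagating traffic piles mass
#' at positive lags that grow with electrode distance.
#'
#' @param trains Spike-train tibble (`electrode`, `time_s`).
#' @param layout The [channel_layout()].
#' @param trigger_electrode Electrode index (1-based, in layout order) whose
#'   spikes define time zero.
#' @param window_ms Half-width of the lag window in ms (default 5).
#' @param bin_ms Histogram bin width in ms (default 0.2).
#' @return A tibble of class `stth` with columns `electrode`, `position_um`,
#'   `lag_ms` (bin centre) and `count`; attributes `trigger_electrode`,
#'   `window_ms`, `bin_ms`, `n_trigger_spikes`.
#' @export
build_stth <- function(trains, layout, trigger_electrode, window_ms = 5,
                       bin_ms = 0.2) {
  stopifnot(inherits(layout, "channel_layout"))
  ne <- n_electrodes(layout)
  if (!(trigger_electrode %in% seq_len(ne))) {
    abort("`trigger_electrode` must be an electrode index of the layout.")
  }
  check_number(window_ms, "window_ms", lower = 0, strict_lower = TRUE)
  check_number(bin_ms, "bin_ms", lower = 0, strict_lower = TRUE)
  nb <- ceiling(window_ms / bin_ms)
  breaks <- seq(-nb * bin_ms, nb * bin_ms, by = bin_ms)
  mids <- (head(breaks, -1L) + tail(breaks, -1L)) / 2
  trig <- sort(trains$time_s[trains$electrode == trigger_electrode])
  others <- setdiff(seq_len(ne), trigger_electrode)
  w_s <- window_ms / 1000
  res <- purrr::map(others, function(e) {
    ts <- sort(trains$time_s[trains$electrode == e])
    counts <- integer(length(mids))
    if (length(trig) > 0 && length(ts) > 0) {
      lo <- findInterval(trig - w_s, ts) + 1L
      hi <- findInterval(trig + w_s, ts)
      diffs <- unlist(purrr::map(seq_along(trig), function(i) {
        if (hi[i] >= lo[i]) (ts[lo[i]:hi[i]] - trig[i]) * 1000 else numeric()
      }))
      if (length(diffs) > 0) {
        diffs <- diffs[diffs >= breaks[1L] & diffs <= breaks[length(breaks)]]
        counts <- as.integer(table(cut(diffs, breaks, include.lowest = TRUE)))
      }
    }
    tibble(
      electrode = e,
      position_um = layout$electrode_positions_um[e],
      lag_ms = mids, count = counts
    )
  }) |> purrr::list_rbind()
  structure(
    res,
    class = c("stth", class(res)),
    trigger_electrode = trigger_electrode,
    window_ms = window_ms, bin_ms = bin_ms,
    n_trigger_spikes = length(trig)
  )
}

#' Plot an STTH
#'
#' One panel per electrode, lag histogram as columns.
#'
#' @param object An `stth` from [build_stth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stth
#' @export
autoplot.stth <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$lag_ms, y = .data$count)
  ) +
    ggplot2::geom_col(width = attr(object, "bin_ms"), fill = "steelblue") +
    ggplot2::facet_wrap(~position_um, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "lag (ms)", y = "spike count",
      title = sprintf("STTH, trigger electrode %d",
                      attr(object, "trigger_electrode"))
    ) +
    ggplot2::theme_minimal()
}
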