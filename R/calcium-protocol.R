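#' Electrical stimulation protocol
#'
#' Two protocol kinds are supported. `continuous`: each cycle is a
#' `pre_window_s` spontaneous baseline followed by `stim_duration_s` of
#' continuous pulses at the given inter-stimulus interval (ISI); repeated
#' `n_cycles` times (defaults 15 s + 15 s, 6 cycles, ISI grid 4-256 ms).
#' `burst`: each cycle is a 200 ms baseline, a fixed train of `n_pulses`
#' pulses at `isi_ms`, and a recovery pause; repeated `n_cycles` times
#' (defaults 16 pulses at 5 ms ISI, 3 s recovery, 40 cycles).
#'
#' @param kind `"continuous"` or `"burst"`.
#' @param isi_ms Inter-stimulus interval in ms; the pulse rate is
#'   `1000 / isi_ms` Hz.
#' @param n_pulses Pulses per cycle (continuous: derived from
#'   `stim_duration_s` when `NULL`).
#' @param n_cycles Number of stimulation cycles.
#' @param pre_window_s Pre-stimulus baseline per cycle in seconds.
#' @param stim_duration_s Stimulation phase length (continuous only).
#' @param recovery_s Post-train recovery pause (burst only).
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol("continuous", isi_ms = 32)
#' stim_protocol("burst")
#' @export
stim_protocol <- function(kind = c("continuous", "burst"), isi_ms = NULL,
                          n_pulses = NULL, n_cycles = NULL,
                          pre_window_s = NULL, stim_duration_s = NULL,
                          recovery_s = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    isi_ms <- isi_ms %||% 32
    n_cycles <- n_cycles %||% 6
    pre_window_s <- pre_window_s %||% 15
    stim_duration_s <- stim_duration_s %||% 15
    check_number(isi_ms, "isi_ms", lower = 0, strict_lower = TRUE)
    n_pulses <- n_pulses %||% max(1L, floor(stim_duration_s * 1000 / isi_ms))
    recovery_s <- 0
    cycle_s <- pre_window_s + stim_duration_s
    stim_end_s <- pre_window_s + stim_duration_s
  } else {
    isi_ms <- isi_ms %||% 5
    n_pulses <- n_pulses %||% 16
    n_cycles <- n_cycles %||% 40
    pre_window_s <- pre_window_s %||% 0.2
    recovery_s <- recovery_s %||% 3
    check_number(isi_ms, "isi_ms", lower = 0, strict_lower = TRUE)
    stim_duration_s <- (n_pulses - 1L) * isi_ms / 1000
    cycle_s <- pre_window_s + stim_duration_s + recovery_s
    stim_end_s <- pre_window_s + stim_duration_s
  }
  check_number(n_pulses, "n_pulses", lower = 1)
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(pre_window_s, "pre_window_s", lower = 0, strict_lower = TRUE)
  last_pulse <- pre_window_s + (n_pulses - 1L) * isi_ms / 1000
  if (last_pulse >= cycle_s) {
    abort("Protocol pulses extend beyond the cycle duration.")
  }
  structure(
    list(kind = kind, isi_ms = isi_ms, rate_hz = 1000 / isi_ms,
         n_pulses = as.integer(n_pulses), n_cycles = as.integer(n_cycles),
         pre_window_s = pre_window_s, stim_duration_s = stim_duration_s,
         recovery_s = recovery_s, cycle_s = cycle_s, stim_end_s = stim_end_s),
    class = "stim_protocol"
  )
}

#' Cycle timing table of a protocol
#'
#' @param protocol A [stim_protocol()].
#' @return Tibble with `cycle`, `cycle_start_s`, `stim_on_s`, `stim_end_s`,
#'   `cycle_end_s` (absolute times over the concatenated cycles).
#' @export
protocol_cycles <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  start <- (seq_len(protocol$n_cycles) - 1L) * protocol$cycle_s
  tibble(
    cycle = seq_len(protocol$n_cycles),
    cycle_start_s = start,
    stim_on_s = start + protocol$pre_window_s,
    stim_end_s = start + protocol$stim_end_s,
    cycle_end_s = start + protocol$cycle_s
  )
}

# absolute pulse times over all cycles
protocol_pulses <- function(protocol) {
  cyc <- protocol_cycles(protocol)
  purrr::map(seq_len(nrow(cyc)), function(i) {
    tibble(
      cycle = cyc$cycle[i],
      pulse = seq_len(protocol$n_pulses),
      time_s = cyc$stim_on_s[i] +
        (seq_len(protocol$n_pulses) - 1L) * protocol$isi_ms / 1000
    )
  }) |> purrr::list_rbind()
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol:%s> ISI %.1f ms (%.2f Hz), %d pulses x %d cycles, pre %.2g s\n",
    x$kind, x$isi_ms, x$rate_hz, x$n_pulses, x$n_cycles, x$pre_window_s
  ))
  invisible(x)
}
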