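# internal argument checking helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  if (lo_bad || hi_bad) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# run `code` under a temporary, restored RNG state seeded with `seed`;
# all generator randomness flows through this single entry point
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) abort("A `seed` is required; implicit randomness is not allowed.")
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}
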