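# internal helpers: argument checks, seed derivation

abort_domain <- function(msg) rlang::abort(msg, class = "gc_domain_error")
abort_missing <- function(msg) rlang::abort(msg, class = "gc_missing_data")
abort_design <- function(msg) rlang::abort(msg, class = "gc_invalid_design")
abort_geometry <- function(msg) rlang::abort(msg, class = "gc_invalid_geometry")
abort_integrity <- function(msg) rlang::abort(msg, class = "gc_integrity_error")

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

check_gc_fraction <- function(true_gc) {
  check_scalar_number(true_gc, "true_gc")
  if (true_gc <= 0 || true_gc >= 1) {
    abort_domain("`true_gc` must lie strictly inside (0, 1)")
  }
  invisible(true_gc)
}

# Accepts a one-row schedule tibble or a list; returns list(solar_radiation, dew)
as_event <- function(event) {
  if (inherits(event, "data.frame")) {
    if (nrow(event) != 1L) abort_domain("`event` must be a single sampling event")
    event <- as.list(event)
  }
  if (is.null(event$solar_radiation) || is.null(event$dew)) {
    abort_domain("`event` must carry `solar_radiation` and `dew`")
  }
  if (event$solar_radiation < 0) abort_domain("`solar_radiation` must be >= 0")
  event
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed plus plot and event identifiers to a
#' 31-bit seed, so every plot-by-event sensor bundle is independently
#' reproducible. A pure integer hash: no RNG state is consumed.
#'
#' @param master Master seed (integer).
#' @param plot,event Plot and event indices (default 0).
#' @param salt Extra stream separator for multiple draws per (plot, event).
#' @return A single integer in `[1, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, plot = 3, event = 5)
derive_seed <- function(master, plot = 0, event = 0, salt = 0) {
  # multipliers kept small enough that the product stays exact in doubles
  s <- (master %% 2147483647) * 48271 +
    (plot %% 2147483647) * 69621 +
    (event %% 2147483647) * 16807 +
    (salt %% 2147483647) * 104729
  as.integer(s %% 2147483629) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
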