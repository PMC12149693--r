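# SNIP baseline estimation (Sensitive Nonlinear Iterative Peak clipping).

#' SNIP baseline of a spectrum
#'
#' Ascending-window SNIP: for window half-widths p = 1..p_max, each bin is
#' replaced by `min(v_i, (v_{i-p} + v_{i+p}) / 2)`. With `use_lls` the
#' clipping runs in the log-log-sqrt compressed domain
#' `v -> log(log(sqrt(v + 1) + 1) + 1)` (and is transformed back), which
#' protects small-amplitude peaks on a large dynamic range.
#'
#' @param spec A `pg_spectrum` (or bare numeric vector of bin values).
#' @param p_max Maximum clipping half-window in bins; choose about twice
#'   the broadest peak FWHM in bins. Must be >= 1 and less than half the
#'   number of bins.
#' @param use_lls Apply the LLS operator before clipping.
#' @return A `pg_baseline`: tibble `bin`, `value`, `baseline`, `net` plus
#'   the settings used.
#' @examples
#' sp <- spectrum(0:64, c(rep(10, 30), 10 + 100, rep(10, 33)))
#' b <- snip_baseline(sp, p_max = 4, use_lls = FALSE)
#' b$data$baseline[31]  # ~10, the flat level under the peak
#' @export
snip_baseline <- function(spec, p_max = 8, use_lls = TRUE) {
  v0 <- if (inherits(spec, "pg_spectrum")) spec$data$value else as.numeric(spec)
  n <- length(v0)
  if (p_max < 1 || p_max >= n / 2)
    abort_pg("p_max must be >= 1 and < half the number of bins", "pg_config_error")
  if (any(v0 < 0)) abort_pg("SNIP requires non-negative spectrum values",
                            "pg_validation_error")
  lls <- function(v) log(log(sqrt(v + 1) + 1) + 1)
  lls_inv <- function(u) (exp(exp(u) - 1) - 1)^2 - 1
  v <- if (use_lls) lls(v0) else v0
  for (p in seq_len(p_max)) {
    i <- (p + 1):(n - p)
    v[i] <- pmin(v[i], (v[i - p] + v[i + p]) / 2)
  }
  b <- if (use_lls) pmax(lls_inv(v), 0) else v
  b <- pmin(b, v0)  # numerical guard: baseline never exceeds the spectrum
  structure(list(
    data = tibble::tibble(bin = seq_len(n), value = v0, baseline = b,
                          net = v0 - b),
    p_max = p_max, use_lls = use_lls), class = "pg_baseline")
}

#' @export
print.pg_baseline <- function(x, ...) {
  cat(sprintf("<pg_baseline> %d bins, p_max = %d, LLS = %s\n",
              nrow(x$data), x$p_max, x$use_lls))
  invisible(x)
}
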