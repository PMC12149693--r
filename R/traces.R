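# Synthetic digitized scintillator traces and the experimental analysis
# chain: baseline restoration, EMG pulse fitting with model selection,
# quality filtering, raw-spectrum construction, dead-time correction and
# multi-line energy calibration.
#
# A trace is a 200 ns window sampled every 4 ns (50 samples); each window
# may contain up to 3 EMG-shaped pulses (pile-up) on a baseline with
# additive white noise.

#' Generate synthetic digitized traces
#'
#' Builds traces as baseline + sum of EMG pulses + white Gaussian noise.
#' The pulse specification doubles as the ground-truth ledger.
#'
#' @param events Tibble with one row per pulse: `trace_id`, `mu_ns` (pulse
#'   Gaussian centroid inside the window), `sigma_ns`, `tau_ns`, `area`
#'   (ADC*ns time-integral of the pulse). At most 3 pulses per trace.
#' @param n_traces Total number of traces (>= max trace_id; traces without
#'   events are pure baseline + noise).
#' @param noise_sigma White-noise sigma in ADC units.
#' @param baseline Constant baseline offset in ADC units.
#' @param window_ns,dt_ns Acquisition window and sampling interval.
#' @param t0_ns Acquisition timestamps per trace (recycled; defaults to
#'   trace index microseconds apart).
#' @param seed RNG seed for the noise.
#' @return A list with `traces` (tibble `trace_id`, `t0_ns`, `t_ns`, `adc`)
#'   and `events` (the ground-truth ledger).
#' @export
generate_traces <- function(events, n_traces = max(events$trace_id),
                            noise_sigma = 0, baseline = 0,
                            window_ns = 200, dt_ns = 4,
                            t0_ns = NULL, seed = NULL) {
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    stopifnot(all(c("trace_id", "mu_ns", "sigma_ns", "tau_ns", "area") %in%
                    names(events)))
    if (any(events$mu_ns < 0 | events$mu_ns > window_ns))
      abort_pg("pulse centroid outside the acquisition window", "pg_config_error")
    if (any(table(events$trace_id) > 3))
      abort_pg("at most 3 pulses per trace", "pg_config_error")
  }
  t <- seq(0, window_ns - dt_ns, by = dt_ns)
  if (is.null(t0_ns)) t0_ns <- (seq_len(n_traces) - 1) * 1e3
  t0_ns <- rep_len(t0_ns, n_traces)

  base <- tidyr::expand_grid(trace_id = seq_len(n_traces), t_ns = t)
  base$adc <- baseline
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      sel <- base$trace_id == e$trace_id
      base$adc[sel] <- base$adc[sel] +
        e$area * emg_density(base$t_ns[sel], e$mu_ns, e$sigma_ns, e$tau_ns)
    }
  }
  base$adc <- with_seed_(if (!is.null(seed)) stage_seed(seed, "traces") else NULL,
                         base$adc + rnorm(nrow(base), 0, noise_sigma))
  base$t0_ns <- t0_ns[base$trace_id]
  list(traces = base[, c("trace_id", "t0_ns", "t_ns", "adc")], events = events)
}

#' Baseline restoration
#'
#' Subtracts the median of the first `k` (pre-pulse) samples of each trace
#' from the whole trace, emulating a hardware baseline restorer.
#'
#' @param traces Trace tibble from [generate_traces()].
#' @param k Number of leading samples used for the median (default 5).
#' @return The trace tibble with restored `adc`.
#' @export
restore_baseline <- function(traces, k = 5) {
  n_per <- min(table(traces$trace_id))
  if (n_per < k)
    abort_pg(sprintf("traces have fewer than k = %d samples", k), "pg_config_error")
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(traces, .data$trace_id),
    adc = .data$adc - stats::median(.data$adc[seq_len(k)])))
}

# candidate pulse locations: local maxima above `floor`, greedily separated
# by >= min_sep samples, strongest first
.peak_candidates <- function(y, t, floor, max_n, min_sep = 3L) {
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > floor
  idx <- which(is_max)
  idx <- idx[order(-y[idx])]
  keep <- integer()
  for (i in idx) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
    if (length(keep) >= max_n) break
  }
  t[sort(keep)]
}

# fit a sum of m EMG pulses to one trace; returns list(par tibble, rss, ok)
.fit_m_pulses <- function(t, y, mu0, sigma0 = 4, tau0 = 10) {
  m <- length(mu0)
  start <- list()
  for (j in seq_len(m)) {
    a0 <- max(y[which.min(abs(t - mu0[j]))], 1e-3) * (2.5 * sigma0 + tau0)
    start[[paste0("area", j)]] <- a0
    start[[paste0("mu", j)]] <- mu0[j]
    start[[paste0("sg", j)]] <- sigma0
    start[[paste0("ta", j)]] <- tau0
  }
  model_fun <- function(par) {
    out <- numeric(length(t))
    for (j in seq_len(m))
      out <- out + par[[paste0("area", j)]] *
        emg_density(t, par[[paste0("mu", j)]],
                    max(par[[paste0("sg", j)]], 1e-3),
                    max(par[[paste0("ta", j)]], 1e-3))
    out
  }
  res_fun <- function(p) {
    par <- as.list(p); names(par) <- names(start)
    y - model_fun(par)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = res_fun,
                       lower = rep(c(0, min(t) - 20, 0.5, 0.5), m),
                       upper = rep(c(Inf, max(t) + 20, 40, 120), m),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.list(fit$par); names(p) <- names(start)
  rss <- sum(res_fun(fit$par)^2)
  pars <- purrr::map_dfr(seq_len(m), function(j) {
    apx <- emg_apex(p[[paste0("mu", j)]], p[[paste0("sg", j)]],
                    p[[paste0("ta", j)]])
    tibble::tibble(pulse = j,
                   area = p[[paste0("area", j)]],
                   mu_ns = p[[paste0("mu", j)]],
                   sigma_ns = p[[paste0("sg", j)]],
                   tau_ns = p[[paste0("ta", j)]],
                   amplitude = p[[paste0("area", j)]] * apx$height,
                   apex_ns = apx$location)
  })
  list(pars = pars, rss = rss)
}

#' Fit EMG pulses to traces
#'
#' Per trace, performs model selection over 0 to `max_peaks` EMG
#' components: candidate pulse locations are local maxima above an
#' amplitude floor (`amp_floor` times the noise sigma), each candidate
#' count is fitted by Levenberg-Marquardt least squares, and the fit
#' minimizing the small-sample information criterion (AICc) is kept.
#'
#' @param traces Baseline-restored trace tibble.
#' @param max_peaks Maximum number of pulses per trace (3, as in event
#'   windows that may pile up).
#' @param noise_sigma Known noise sigma; when `NULL`, estimated per trace
#'   from the first `k_noise` samples.
#' @param amp_floor Candidate threshold in units of noise sigma.
#' @param k_noise Leading samples used for the noise estimate.
#' @return A tibble with one row per fitted pulse (plus one `n_pulses = 0`
#'   row for pulse-free traces): `trace_id`, `t0_ns`, `n_pulses`, `pulse`,
#'   `area`, `amplitude`, `mu_ns`, `sigma_ns`, `tau_ns`, `apex_ns`,
#'   `adj_r_squared`, `degenerate`.
#' @export
fit_pulses <- function(traces, max_peaks = 3, noise_sigma = NULL,
                       amp_floor = 5, k_noise = 8) {
  by_trace <- split(traces, traces$trace_id)
  purrr::map_dfr(by_trace, function(tr) {
    t <- tr$t_ns; y <- tr$adc; n <- length(y)
    ns <- noise_sigma %||% max(stats::sd(y[seq_len(k_noise)]), 1e-9)
    floor_adc <- amp_floor * ns
    cand <- .peak_candidates(y, t, floor_adc, max_peaks)
    n_max <- length(cand)

    best <- list(m = 0L, pars = NULL,
                 rss = sum(y^2), aicc = n * log(max(sum(y^2), 1e-12) / n))
    if (n_max > 0) {
      for (m in seq_len(n_max)) {
        f <- .fit_m_pulses(t, y, cand[seq_len(m)])
        if (is.null(f)) next
        k <- 4 * m
        if (n - k - 1 <= 0) next
        aicc <- n * log(max(f$rss, 1e-12) / n) + 2 * k +
          2 * k * (k + 1) / (n - k - 1)
        if (aicc < best$aicc) best <- list(m = m, pars = f$pars,
                                           rss = f$rss, aicc = aicc)
      }
    }
    ss_tot <- sum((y - mean(y))^2)
    k <- 4 * best$m
    r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else 0
    adj_r2 <- if (n - k - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_
    if (best$m == 0L) {
      tibble::tibble(trace_id = tr$trace_id[1], t0_ns = tr$t0_ns[1],
                     n_pulses = 0L, pulse = NA_integer_, area = NA_real_,
                     amplitude = NA_real_, mu_ns = NA_real_,
                     sigma_ns = NA_real_, tau_ns = NA_real_,
                     apex_ns = NA_real_, adj_r_squared = adj_r2,
                     degenerate = n_max > 0L)
    } else {
      dplyr::mutate(best$pars, trace_id = tr$trace_id[1],
                    t0_ns = tr$t0_ns[1], n_pulses = best$m,
                    adj_r_squared = adj_r2, degenerate = FALSE)[
        , c("trace_id", "t0_ns", "n_pulses", "pulse", "area", "amplitude",
            "mu_ns", "sigma_ns", "tau_ns", "apex_ns", "adj_r_squared",
            "degenerate")]
    }
  })
}

#' Quality filter on pulse fits
#'
#' Pure predicate keeping pulses whose trace-level adjusted R-squared is at
#' least `r2_min`, whose relaxation time lies in `tau_range`, and (when a
#' gate is given) whose acquisition timestamp falls inside the time gate —
#' a generic stand-in for in-spill event selection.
#'
#' @param fits Pulse-fit tibble from [fit_pulses()].
#' @param r2_min Minimum adjusted R-squared (use `-Inf` to disable).
#' @param tau_range Length-2 numeric: allowed relaxation-time window (ns).
#' @param time_gate Optional length-2 numeric gate on `t0_ns`.
#' @return The accepted subset of `fits` (pulse rows only).
#' @export
quality_filter <- function(fits, r2_min = 0.9, tau_range = c(0.5, 60),
                           time_gate = NULL) {
  if (length(tau_range) != 2 || tau_range[2] <= tau_range[1])
    abort_pg("tau_range must be an increasing length-2 numeric", "pg_config_error")
  out <- dplyr::filter(fits, .data$n_pulses > 0,
                       .data$adj_r_squared >= r2_min,
                       .data$tau_ns >= tau_range[1],
                       .data$tau_ns <= tau_range[2])
  if (!is.null(time_gate))
    out <- dplyr::filter(out, .data$t0_ns >= time_gate[1],
                         .data$t0_ns <= time_gate[2])
  out
}

#' Build a raw channel spectrum from accepted pulse fits
#'
#' Histograms either the pulse areas or the pulse apex amplitudes into
#' `n_channels` uniform channels over `[0, max_value]`.
#'
#' @param fits Accepted pulse-fit tibble.
#' @param mode `"area"` or `"apex"`.
#' @param n_channels Number of channels.
#' @param max_value Upper edge of the last channel (default: just above the
#'   largest statistic).
#' @return A `pg_channel_spectrum`: tibble `channel`, `counts` plus channel
#'   width metadata.
#' @export
build_raw_spectrum <- function(fits, mode = c("area", "apex"),
                               n_channels = 1024, max_value = NULL) {
  mode <- match.arg(mode)
  x <- if (mode == "area") fits$area else fits$amplitude
  x <- x[is.finite(x)]
  max_value <- max_value %||% (if (length(x)) max(x) * 1.001 else 1)
  w <- max_value / n_channels
  idx <- pmin(pmax(floor(x / w) + 1L, 1L), n_channels)
  structure(list(
    data = tibble::tibble(channel = seq_len(n_channels),
                          counts = tabulate(idx, n_channels)),
    mode = mode, channel_width = w, max_value = max_value),
    class = "pg_channel_spectrum")
}

#' @export
print.pg_channel_spectrum <- function(x, ...) {
  cat(sprintf("<pg_channel_spectrum> %d channels (%s mode), %d counts\n",
              nrow(x$data), x$mode, sum(x$data$counts)))
  invisible(x)
}

#' Non-paralyzable dead-time correction
#'
#' True rate n = m / (1 - m * tau) for measured rate m and fixed
#' (non-extendable) dead time tau per recorded event.
#'
#' @param m Measured rate in 1/s (vectorised).
#' @param tau_dead Dead time per event in s.
#' @return Corrected (true) rate in 1/s.
#' @export
dead_time_correct <- function(m, tau_dead) {
  if (tau_dead < 0) abort_pg("dead time must be >= 0", "pg_config_error")
  if (any(m * tau_dead >= 1))
    abort_pg("measured rate saturates the dead-time model (m*tau >= 1)",
             "pg_saturation_error")
  m / (1 - m * tau_dead)
}

#' Multi-line energy calibration
#'
#' Least-squares linear (optionally quadratic) map from channel to energy,
#' anchored on known lines: typically the annihilation peak (0.511 MeV),
#' hydrogen neutron capture (2.22 MeV) and the carbon 4.44 MeV line with
#' its single and double escape peaks, plus any check source.
#'
#' @param anchors Data frame with columns `channel` and `energy_mev`
#'   (at least 2 distinct channels; 3 for quadratic).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return A `pg_calibration` with `gain` (MeV/channel), `offset` (MeV),
#'   residuals, and the underlying `lm` fit. `tidy()`/`glance()` methods
#'   are available; apply with [apply_calibration()].
#' @export
calibrate <- function(anchors, degree = 1) {
  anchors <- tibble::as_tibble(anchors)
  stopifnot(all(c("channel", "energy_mev") %in% names(anchors)))
  if (length(unique(anchors$channel)) < degree + 1)
    abort_pg("calibration needs more distinct anchor channels than the polynomial degree",
             "pg_validation_error")
  fit <- stats::lm(energy_mev ~ poly(channel, degree, raw = TRUE),
                   data = anchors)
  cf <- stats::coef(fit)
  structure(list(
    gain = unname(cf[2]), offset = unname(cf[1]),
    degree = degree, coef = unname(cf),
    anchors = anchors, residuals = unname(stats::residuals(fit)), fit = fit),
    class = "pg_calibration")
}

#' Apply an energy calibration to channels
#'
#' @param channels Channel values (vectorised).
#' @param cal A `pg_calibration`.
#' @return Energies in MeV.
#' @export
apply_calibration <- function(channels, cal) {
  stopifnot(inherits(cal, "pg_calibration"))
  drop(outer(channels, seq_len(cal$degree + 1) - 1, `^`) %*% cal$coef)
}

#' @export
print.pg_calibration <- function(x, ...) {
  cat(sprintf("<pg_calibration> E = %.6g + %.6g * ch%s (%d anchors, max |res| %.3g MeV)\n",
              x$offset, x$gain,
              if (x$degree > 1) " + ..." else "",
              nrow(x$anchors), max(abs(x$residuals))))
  invisible(x)
}

#' @method tidy pg_calibration
#' @export
tidy.pg_calibration <- function(x, ...) {
  dplyr::mutate(x$anchors, residual_mev = x$residuals)
}

#' @method glance pg_calibration
#' @export
glance.pg_calibration <- function(x, ...) {
  tibble::tibble(gain = x$gain, offset = x$offset, degree = x$degree,
                 n_anchors = nrow(x$anchors),
                 max_abs_residual = max(abs(x$residuals)))
}

#' Convert a channel spectrum to a calibrated energy spectrum
#'
#' @param chspec A `pg_channel_spectrum`.
#' @param cal A `pg_calibration`.
#' @param n_primaries Optional book-keeping for later normalization.
#' @return A `pg_spectrum` on the calibrated energy axis.
#' @export
calibrate_spectrum <- function(chspec, cal, n_primaries = NA_integer_) {
  stopifnot(inherits(chspec, "pg_channel_spectrum"))
  # calibration maps channel index -> MeV; channel i spans (i-1, i]
  edges_e <- apply_calibration(0:nrow(chspec$data), cal)
  if (is.unsorted(edges_e, strictly = TRUE))
    abort_pg("calibration is not monotone over the channel range",
             "pg_validation_error")
  spectrum(edges_e, chspec$data$counts, n_primaries = n_primaries)
}
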