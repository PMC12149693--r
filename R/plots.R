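# ggplot2 helpers for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Step-style spectrum on a log10 count axis (linear when values span less
#' than one decade).
#'
#' @param object A `pg_spectrum`.
#' @param log_y Force or suppress the log axis (default: auto).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_spectrum
#' @export
autoplot.pg_spectrum <- function(object, log_y = NULL, ...) {
  d <- tidy(object)
  ylab <- if (object$normalized) "counts / (primary × MeV)" else "counts"
  pos <- d$value[d$value > 0]
  log_y <- log_y %||% (length(pos) > 0 && max(pos) / min(pos) > 10)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$energy_mev, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Energy (MeV)", y = ylab) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
plot.pg_spectrum <- function(x, ...) print(autoplot(x, ...))

#' Plot a SNIP baseline estimate
#'
#' @param object A `pg_baseline`.
#' @param ... Unused.
#' @return A ggplot overlaying spectrum and clipped baseline.
#' @method autoplot pg_baseline
#' @export
autoplot.pg_baseline <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data, c("value", "baseline"),
                           names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Bin", y = "Counts", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot line yields versus beam energy
#'
#' @param yields Tidy yield table from [yield_curve()].
#' @return A ggplot with one panel-free series per line.
#' @export
plot_yield_curve <- function(yields) {
  ggplot2::ggplot(yields,
                  ggplot2::aes(x = .data$beam_energy_mev, y = .data$area,
                               colour = .data$line_id)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$area - .data$d_area,
                                        ymax = .data$area + .data$d_area),
                           width = 0) +
    ggplot2::labs(x = "Beam energy (MeV)", y = "Net line area",
                  colour = "Line") +
    ggplot2::theme_minimal()
}

#' Plot a digitized trace with its fitted pulses
#'
#' @param traces Trace tibble (one or more traces).
#' @param fits Optional pulse-fit tibble from [fit_pulses()].
#' @param trace_ids Which traces to show (default: first).
#' @return A ggplot.
#' @export
plot_trace <- function(traces, fits = NULL, trace_ids = NULL) {
  trace_ids <- trace_ids %||% traces$trace_id[1]
  d <- dplyr::filter(traces, .data$trace_id %in% trace_ids)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_ns, y = .data$adc)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~trace_id) +
    ggplot2::labs(x = "Time (ns)", y = "ADC") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    f <- dplyr::filter(fits, .data$trace_id %in% trace_ids, .data$n_pulses > 0)
    if (nrow(f)) {
      curves <- purrr::pmap_dfr(f, function(trace_id, area, mu_ns, sigma_ns,
                                            tau_ns, pulse, ...) {
        t <- seq(min(d$t_ns), max(d$t_ns), length.out = 200)
        tibble::tibble(trace_id = trace_id, pulse = pulse, t_ns = t,
                       adc = area * emg_density(t, mu_ns, sigma_ns, tau_ns))
      })
      p <- p + ggplot2::geom_line(
        data = curves,
        ggplot2::aes(group = .data$pulse), colour = "red", linewidth = 0.4)
    }
  }
  p
}

#' Plot an excitation-function fit over its data
#'
#' @param object A `pg_xsec_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pg_xsec_fit
#' @export
autoplot.pg_xsec_fit <- function(object, ...) {
  d <- object$data
  xx <- seq(min(d$energy_mev), max(d$energy_mev), length.out = 300)
  fitted <- tibble::tibble(energy_mev = xx,
                           sigma_mb = emg_eval(xx, object$curve))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$energy_mev,
                                       y = .data$sigma_mb)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitted, colour = "red") +
    ggplot2::labs(x = "Proton energy (MeV)", y = "Cross section (mb)") +
    ggplot2::theme_minimal()
  if ("dsigma_mb" %in% names(d))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$sigma_mb - .data$dsigma_mb,
                   ymax = .data$sigma_mb + .data$dsigma_mb), width = 0)
  p
}
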