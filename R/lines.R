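# Region-of-interest Gaussian line fitting and yield tabulation.

# sum of n_comp Gaussians (area parameterisation) + optional linear term
.gauss_mix <- function(x, par, n_comp, linear) {
  out <- numeric(length(x))
  for (j in seq_len(n_comp)) {
    a <- par[[paste0("area", j)]]
    mu <- par[[paste0("mu", j)]]
    sg <- max(par[[paste0("sg", j)]], 1e-9)
    out <- out + a / (sg * sqrt(2 * pi)) * exp(-(x - mu)^2 / (2 * sg^2))
  }
  if (linear) out <- out + par[["c0"]] + par[["c1"]] * (x - mean(x))
  out
}

#' Fit Gaussian components to spectral regions of interest
#'
#' For each region, fits a sum of `n_components` Gaussians (area, centroid,
#' sigma each; optional linear residual-background term) to the
#' baseline-subtracted spectrum by Levenberg-Marquardt least squares. Net
#' areas integrate the fitted Gaussians; uncertainties come from the fit
#' covariance.
#'
#' @param spec A `pg_spectrum`.
#' @param baseline Optional `pg_baseline` from [snip_baseline()]; when
#'   supplied its `net` values are fitted, otherwise the raw values.
#' @param regions Data frame with columns `lo_mev`, `hi_mev`,
#'   `n_components` and optionally `line_id` labels.
#' @param linear_term Include a linear residual term per region.
#' @param shared_sigma Constrain all components of a region to one width.
#' @return A tibble of line yields: `line_id`, `component`, `centroid_mev`,
#'   `sigma_mev`, `area`, `d_area`, `converged`. Areas are in the
#'   spectrum's value units integrated over MeV.
#' @export
fit_lines <- function(spec, baseline = NULL, regions, linear_term = FALSE,
                      shared_sigma = FALSE) {
  stopifnot(inherits(spec, "pg_spectrum"))
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("lo_mev", "hi_mev", "n_components") %in% names(regions)))
  if (!"line_id" %in% names(regions))
    regions$line_id <- sprintf("region_%d", seq_len(nrow(regions)))
  centers <- (spec$data$bin_lo + spec$data$bin_hi) / 2
  values <- if (!is.null(baseline)) baseline$data$net else spec$data$value
  bw <- spec$data$bin_hi - spec$data$bin_lo

  purrr::pmap_dfr(regions, function(lo_mev, hi_mev, n_components, line_id, ...) {
    sel <- centers >= lo_mev & centers < hi_mev
    if (!any(sel))
      abort_pg(sprintf("region [%g, %g] MeV outside spectrum support",
                       lo_mev, hi_mev), "pg_config_error")
    x <- centers[sel]; y <- values[sel]; w <- mean(bw[sel])
    m <- as.integer(n_components)
    fail_row <- tibble::tibble(
      line_id = line_id, component = seq_len(m), centroid_mev = NA_real_,
      sigma_mev = NA_real_, area = NA_real_, d_area = NA_real_,
      converged = FALSE)

    if (all(y == 0)) {
      return(dplyr::mutate(fail_row, centroid_mev = (lo_mev + hi_mev) / 2,
                           sigma_mev = (hi_mev - lo_mev) / 6, area = 0,
                           d_area = 0, converged = TRUE))
    }

    # starting values: split the region, centroid at local maxima
    mu0 <- x[order(-y)][seq_len(m)]
    mu0 <- sort(mu0)
    sg0 <- (hi_mev - lo_mev) / (4 * m)
    start <- list()
    for (j in seq_len(m)) {
      start[[paste0("area", j)]] <- max(y[which.min(abs(x - mu0[j]))], 1e-12) *
        sg0 * sqrt(2 * pi)
      start[[paste0("mu", j)]] <- mu0[j]
      start[[paste0("sg", j)]] <- sg0
    }
    if (linear_term) { start$c0 <- 0; start$c1 <- 0 }

    pnames <- names(start)
    res_fun <- function(p) {
      par <- as.list(p); names(par) <- pnames
      if (shared_sigma && m > 1)
        for (j in 2:m) par[[paste0("sg", j)]] <- par[["sg1"]]
      y - .gauss_mix(x, par, m, linear_term)
    }
    lower <- c(rep(c(0, lo_mev, w / 2), m),
               if (linear_term) c(-Inf, -Inf))
    upper <- c(rep(c(Inf, hi_mev, (hi_mev - lo_mev)), m),
               if (linear_term) c(Inf, Inf))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(start), fn = res_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) return(fail_row)

    p <- as.list(fit$par); names(p) <- pnames
    # covariance of the fitted parameters
    cv <- tryCatch({
      dof <- max(length(y) - length(fit$par), 1)
      s2 <- fit$deviance / dof
      s2 * solve(fit$hessian / 2)
    }, error = function(e) NULL)
    purrr::map_dfr(seq_len(m), function(j) {
      da <- if (!is.null(cv)) {
        i <- which(pnames == paste0("area", j))
        sqrt(max(cv[i, i], 0))
      } else NA_real_
      tibble::tibble(line_id = line_id, component = j,
                     centroid_mev = p[[paste0("mu", j)]],
                     sigma_mev = if (shared_sigma) p[["sg1"]] else
                       p[[paste0("sg", j)]],
                     area = p[[paste0("area", j)]], d_area = da,
                     converged = TRUE)
    })
  })
}

#' Default regions of interest around catalogue lines
#'
#' One region per requested line, spanning `n_sigma` expected detector
#' sigmas around the catalogue energy.
#'
#' @param catalogue Catalogue tibble.
#' @param det A `pg_detector` (used for the expected width).
#' @param line_ids Lines to include (default: all emittable lines).
#' @param n_sigma Half-width in expected sigmas (default 3).
#' @return A regions tibble for [fit_lines()].
#' @export
default_regions <- function(catalogue, det, line_ids = NULL, n_sigma = 3) {
  cat <- .validate_catalogue(catalogue)
  if (is.null(line_ids))
    line_ids <- cat$line_id[cat$single_photon_allowed]
  rows <- cat[match(line_ids, cat$line_id), ]
  sg <- fwhm_at(rows$energy_mev, det) / .const$fwhm_sd
  tibble::tibble(line_id = rows$line_id,
                 lo_mev = rows$energy_mev - n_sigma * sg,
                 hi_mev = rows$energy_mev + n_sigma * sg,
                 n_components = 1L)
}

#' Line yields as a function of beam energy
#'
#' Runs SNIP + region-of-interest fitting on a set of spectra tagged by
#' beam energy and tabulates the fitted yields per (line, energy).
#'
#' @param spectra Named list of `pg_spectrum` objects; names (or
#'   `beam_energies`) give the beam energy in MeV.
#' @param regions Regions tibble (see [fit_lines()], [default_regions()]).
#' @param beam_energies Numeric beam energies, parallel to `spectra`.
#' @param snip_p_max,snip_lls SNIP settings applied to each spectrum.
#' @param rebin Error by default when spectra have inconsistent binning;
#'   not implemented, flag reserved.
#' @return A tidy tibble: `line_id`, `beam_energy_mev`, `centroid_mev`,
#'   `sigma_mev`, `area`, `d_area`, `converged`.
#' @export
yield_curve <- function(spectra, regions,
                        beam_energies = as.numeric(names(spectra)),
                        snip_p_max = 8, snip_lls = TRUE, rebin = FALSE) {
  if (length(spectra) < 2)
    abort_pg("yield_curve needs spectra at >= 2 beam energies", "pg_config_error")
  if (anyNA(beam_energies) || length(beam_energies) != length(spectra))
    abort_pg("each spectrum needs a numeric beam energy", "pg_config_error")
  nb <- vapply(spectra, function(s) nrow(s$data), integer(1))
  if (length(unique(nb)) != 1) {
    if (!rebin) abort_pg("inconsistent binning across spectra", "pg_config_error")
    abort_pg("rebinning not implemented", "pg_config_error")
  }
  purrr::map2_dfr(spectra, beam_energies, function(sp, be) {
    b <- snip_baseline(sp, p_max = snip_p_max, use_lls = snip_lls)
    dplyr::mutate(fit_lines(sp, b, regions), beam_energy_mev = be)
  })[, c("line_id", "beam_energy_mev", "centroid_mev", "sigma_mev",
         "area", "d_area", "converged")]
}

#' Write a yield table to CSV
#' @param yields Tibble from [yield_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(yields, path) {
  utils::write.csv(yields, path, row.names = FALSE)
  invisible(path)
}
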