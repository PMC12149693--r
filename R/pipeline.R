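# End-to-end orchestration: simulate -> detect -> analyze, and the
# emulated-experiment chain on synthetic traces. A single global seed is
# expanded into independent per-stage streams (see stage_seed) so stages
# re-run in isolation reproduce their outputs.

#' Build a run configuration
#'
#' Either from a YAML file or from arguments. Unspecified fields take the
#' documented defaults (PMMA target, packaged catalogue, side-on detector
#' at 25 cm, 1024 bins over 0-10 MeV).
#'
#' @param path Optional YAML file with the same field names.
#' @param beam_energy_mev Beam energy in MeV.
#' @param n_primaries Number of primaries.
#' @param seed Global seed.
#' @param material `"PMMA"` or a `pg_material`.
#' @param catalogue Catalogue tibble or path to a catalogue YAML.
#' @param detector A `pg_detector` or named list of [detector_model()]
#'   arguments.
#' @param n_bins,e_max Spectrum binning.
#' @param method `"binomial"` (fast, identical trajectories) or
#'   `"bernoulli"` (per-primary accept-reject loop).
#' @return A `pg_run_config` list.
#' @export
run_config <- function(path = NULL, beam_energy_mev = 110.24,
                       n_primaries = 1e6, seed = 1, material = "PMMA",
                       catalogue = NULL, detector = NULL,
                       n_bins = 1024, e_max = 10,
                       method = c("binomial", "bernoulli")) {
  cfg <- list(beam_energy_mev = beam_energy_mev, n_primaries = n_primaries,
              seed = seed, material = material, catalogue = catalogue,
              detector = detector, n_bins = n_bins, e_max = e_max,
              method = match.arg(method))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y[!vapply(y, is.null, logical(1))])
  }
  if (is.character(cfg$material)) {
    if (!identical(toupper(cfg$material), "PMMA"))
      abort_pg("only the built-in PMMA material can be named by string",
               "pg_config_error")
    cfg$material <- pg_pmma()
  }
  if (is.null(cfg$catalogue)) cfg$catalogue <- default_catalogue()
  else if (is.character(cfg$catalogue)) cfg$catalogue <- load_catalogue(cfg$catalogue)
  if (is.null(cfg$detector)) cfg$detector <- detector_model()
  else if (!inherits(cfg$detector, "pg_detector"))
    cfg$detector <- do.call(detector_model, cfg$detector)
  structure(cfg, class = "pg_run_config")
}

#' Simulate a prompt-gamma spectrum end to end
#'
#' Transport -> accept-reject emission -> geometric acceptance -> deposit
#' sampling -> resolution broadening -> normalization. Deterministic given
#' the config seed; provenance (seed, config hash) is attached to the
#' result.
#'
#' @param config A `pg_run_config`.
#' @return A list: `spectrum` (normalized `pg_spectrum`), `raw_spectrum`,
#'   `photons` (emitted photon tibble), `counts` (stage-boundary tallies),
#'   `provenance`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "pg_run_config"))
  mat <- config$material
  edges <- default_bin_edges(config$n_bins, config$e_max)
  ctx <- emission_context(mat, config$catalogue, seed = config$seed)

  if (config$n_primaries == 0) {
    photons <- sample_emissions(
      tibble::tibble(primary_index = integer(), depth_cm = numeric(),
                     dx_cm = numeric(), ekin_mev = numeric(),
                     time_ns = numeric()), ctx, seed = config$seed)
    raw <- spectrum(edges, rep(0, config$n_bins), n_primaries = NA_integer_)
    return(list(spectrum = raw, raw_spectrum = raw, photons = photons,
                counts = list(photons = 0, accepted = 0, deposits = 0),
                provenance = .provenance(config)))
  }

  beam1 <- beam_spec(config$beam_energy_mev, 1, seed = config$seed)
  traj <- propagate(beam1, mat)

  photons <- if (config$method == "binomial") {
    sample_emission_counts(traj, config$n_primaries, ctx, seed = config$seed)
  } else {
    beamN <- beam_spec(config$beam_energy_mev, config$n_primaries,
                       seed = config$seed)
    sample_emissions(propagate(beamN, mat), ctx, seed = config$seed)
  }

  hit <- geometric_acceptance(photons, config$detector)
  dep <- deposit(photons$energy_mev[hit], config$detector, seed = config$seed)
  raw <- broaden_and_bin(dep, config$detector, edges,
                         n_primaries = config$n_primaries, seed = config$seed)
  list(spectrum = normalize_spectrum(raw), raw_spectrum = raw,
       photons = photons,
       counts = list(photons = nrow(photons), accepted = sum(hit),
                     deposits = sum(is.finite(dep))),
       provenance = .provenance(config))
}

.provenance <- function(config) {
  strip <- config
  strip$catalogue <- NULL; strip$material <- config$material$name
  list(seed = config$seed,
       config_hash = rlang::hash(config),
       settings = strip,
       package_version = as.character(utils::packageVersion("promptgamma")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Sweep beam energies and tabulate line yields
#'
#' Runs [run_simulation()] at each energy and quantifies the requested
#' lines on the normalized spectra (SNIP baseline + ROI Gaussian fits).
#'
#' @param energies Beam energies in MeV.
#' @param config Base `pg_run_config`; the energy field is overridden per
#'   run and the seed is varied per energy for independent streams.
#' @param line_ids Lines to quantify (default: carbon 4.44 and oxygen
#'   6.13 MeV).
#' @param snip_p_max SNIP half-window in bins.
#' @return A list: `yields` (tidy yield table), `spectra` (named list of
#'   normalized spectra).
#' @export
sweep_energies <- function(energies, config = run_config(),
                           line_ids = c("12C_2p_0p", "16O_3m_0p"),
                           snip_p_max = 8) {
  stopifnot(length(energies) >= 2)
  spectra <- purrr::imap(as.list(energies), function(e, i) {
    cfg <- config
    cfg$beam_energy_mev <- e
    cfg$seed <- stage_seed(config$seed, paste0("sweep", i))
    run_simulation(cfg)$spectrum
  })
  names(spectra) <- as.character(energies)
  regions <- default_regions(config$catalogue, config$detector, line_ids)
  yields <- yield_curve(spectra, regions, beam_energies = energies,
                        snip_p_max = snip_p_max)
  list(yields = yields, spectra = spectra)
}

#' Locate the strongest peaks of a channel spectrum
#'
#' SNIP-subtracts the channel histogram, then iteratively picks the highest
#' remaining local maximum, masking `min_sep` channels around each pick;
#' centroids are refined by a net-count-weighted mean over the mask window.
#'
#' @param chspec A `pg_channel_spectrum`.
#' @param n_peaks Number of peaks to return.
#' @param min_sep Mask half-width in channels.
#' @param p_max SNIP half-window (default `2 * min_sep`).
#' @return Tibble `channel` (refined centroid), `height`, sorted by channel.
#' @export
find_channel_peaks <- function(chspec, n_peaks, min_sep = 10,
                               p_max = 2 * min_sep) {
  stopifnot(inherits(chspec, "pg_channel_spectrum"))
  cnt <- chspec$data$counts
  net <- snip_baseline(cnt, p_max = min(p_max, floor(length(cnt) / 2) - 1),
                       use_lls = FALSE)$data$net
  # light smoothing stabilises the argmax against single-channel spikes
  sm <- stats::filter(net, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  picks <- integer(); work <- as.numeric(sm)
  for (i in seq_len(10 * n_peaks)) {
    if (length(picks) >= n_peaks) break
    j <- which.max(work)
    if (work[j] <= 0) break
    work[max(1, j - min_sep):min(length(net), j + min_sep)] <- -Inf
    if (length(picks) == 0 || min(abs(j - picks)) >= 2 * min_sep)
      picks <- c(picks, j)
  }
  found <- purrr::map_dfr(picks, function(j) {
    win <- max(1, j - min_sep):min(length(net), j + min_sep)
    wts <- pmax(net[win], 0)
    cen <- if (sum(wts) > 0) sum(win * wts) / sum(wts) else j
    tibble::tibble(channel = cen - 0.5, height = net[j])
  })
  dplyr::arrange(found, .data$channel)
}

#' Emulate the experimental acquisition and analysis chain
#'
#' Generates synthetic traces for events drawn from a set of spectral
#' lines, then runs the full experimental chain: baseline restoration, EMG
#' pulse fitting, quality filtering, raw-spectrum construction, anchor-peak
#' search, multi-line calibration and (optionally) dead-time correction.
#'
#' @param lines Numeric energies (MeV) of the lines present in the
#'   synthetic data; these are also the calibration anchors.
#' @param n_traces Number of acquisition windows.
#' @param gain_mev True MeV per unit pulse area of the synthetic
#'   electronics (recovered by the calibration, not given to it).
#' @param intensities Relative line intensities (recycled).
#' @param noise_sigma Trace noise sigma (ADC units).
#' @param area_jitter Relative sigma of the per-pulse area fluctuation
#'   (detector resolution surrogate).
#' @param sigma_ns,tau_ns Pulse shape parameters.
#' @param pileup_probs Probabilities of 1, 2, 3 pulses per trace.
#' @param n_channels Channels of the raw spectrum.
#' @param mode Spectrum statistic: `"area"` or `"apex"`.
#' @param r2_min,tau_range Quality-filter settings.
#' @param time_gate Optional gate on trace timestamps (ns).
#' @param tau_dead Dead time per recorded event (s), for rate correction.
#' @param seed Global seed.
#' @return A list: `spectrum` (calibrated `pg_spectrum`), `calibration`,
#'   `anchors`, `fits`, `accepted`, `truth` (generator ledger), `rates`
#'   (measured and dead-time-corrected), `counts` per stage.
#' @export
run_experiment_emulation <- function(lines = c(0.511, 2.22, 3.418, 3.929, 4.44),
                                     n_traces = 600, gain_mev = 0.001,
                                     intensities = 1, noise_sigma = 1.5,
                                     area_jitter = 0.01, sigma_ns = 4,
                                     tau_ns = 12,
                                     pileup_probs = c(0.8, 0.15, 0.05),
                                     n_channels = 1024,
                                     mode = c("area", "apex"),
                                     r2_min = 0.9, tau_range = c(1, 60),
                                     time_gate = NULL, tau_dead = 1e-6,
                                     seed = 1) {
  mode <- match.arg(mode)
  intensities <- rep_len(intensities, length(lines))

  events <- with_seed_(stage_seed(seed, "emulation_events"), {
    npulse <- sample(seq_along(pileup_probs), n_traces, replace = TRUE,
                     prob = pileup_probs)
    purrr::map_dfr(seq_len(n_traces), function(i) {
      k <- npulse[i]
      e <- sample(lines, k, replace = TRUE, prob = intensities)
      # first pulse early in the window; piled-up pulses trail it by
      # resolvable gaps (>= ~30 ns for the default 4/12 ns pulse shape)
      mu <- cumsum(c(runif(1, 25, 70), runif(k - 1, 30, 55)))[seq_len(k)]
      tibble::tibble(trace_id = i, mu_ns = mu, sigma_ns = sigma_ns,
                     tau_ns = tau_ns,
                     area = (e / gain_mev) * (1 + rnorm(k, 0, area_jitter)),
                     energy_mev = e)
    })
  })

  gen <- generate_traces(events[, c("trace_id", "mu_ns", "sigma_ns",
                                    "tau_ns", "area")],
                         n_traces = n_traces, noise_sigma = noise_sigma,
                         baseline = 40,
                         t0_ns = (seq_len(n_traces) - 1) * 1e6,
                         seed = stage_seed(seed, "emulation_noise"))
  restored <- restore_baseline(gen$traces)
  fits <- fit_pulses(restored, noise_sigma = noise_sigma)
  accepted <- quality_filter(fits, r2_min = r2_min, tau_range = tau_range,
                             time_gate = time_gate)
  if (nrow(accepted) == 0) {
    warning("time gate / quality filter excluded all events; empty spectrum")
    chspec <- build_raw_spectrum(fits[0, ], mode = mode,
                                 n_channels = n_channels, max_value = 1)
    return(list(spectrum = NULL, calibration = NULL, anchors = NULL,
                fits = fits, accepted = accepted, truth = events,
                rates = NULL,
                counts = list(traces = n_traces, pulses_true = nrow(events),
                              pulses_fit = sum(fits$n_pulses > 0),
                              accepted = 0)))
  }

  chspec <- build_raw_spectrum(accepted, mode = mode, n_channels = n_channels)
  # anchor peaks: rank-order match of found peaks to the known line set
  min_sep <- max(4, round(n_channels * 0.015))
  peaks <- find_channel_peaks(chspec, n_peaks = length(lines),
                              min_sep = min_sep)
  if (nrow(peaks) < length(lines)) {
    missing <- sort(lines)[seq(nrow(peaks) + 1, length(lines))]
    abort_pg(paste("calibration anchor peaks not found for energies:",
                   paste(missing, collapse = ", "), "MeV"),
             "pg_calibration_error")
  }
  anchors <- tibble::tibble(channel = peaks$channel,
                            energy_mev = sort(lines))
  cal <- calibrate(anchors)
  spec <- calibrate_spectrum(chspec, cal)

  span_s <- (max(accepted$t0_ns) - min(accepted$t0_ns) + 200) * 1e-9
  m_rate <- nrow(accepted) / span_s
  rates <- list(measured = m_rate,
                corrected = dead_time_correct(m_rate, tau_dead))

  list(spectrum = spec, calibration = cal, anchors = anchors, fits = fits,
       accepted = accepted, truth = events, rates = rates,
       counts = list(traces = n_traces, pulses_true = nrow(events),
                     pulses_fit = sum(fits$n_pulses > 0),
                     accepted = nrow(accepted)))
}

#' Export a photon list to CSV
#' @param photons Photon tibble from [sample_emissions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_photons <- function(photons, path) {
  utils::write.csv(
    photons[, c("energy_mev", "depth_cm", "dir_x", "dir_y", "dir_z",
                "line_id", "primary_index")], path, row.names = FALSE)
  invisible(path)
}

#' Export trajectories to CSV
#' @param trajectories Step tibble from [propagate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(
    trajectories[, c("primary_index", "depth_cm", "dx_cm", "ekin_mev")],
    path, row.names = FALSE)
  invisible(path)
}
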