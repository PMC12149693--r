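# Parametric detector response: geometric acceptance of a cylindrical
# scintillator face, branch sampling into full-energy / escape / continuum
# deposits, Gaussian resolution broadening, and spectrum normalization.
#
# The crystal is modeled parametrically (branch fractions + resolution), not
# by photon transport; absolute-efficiency realism is deliberately out of
# scope and all parameters are configuration.

#' Parametric detector model
#'
#' A cylindrical scintillator viewed side-on from the beam axis. Geometry
#' defaults follow a 3.8 cm diameter x 7.62 cm long crystal placed 25 cm
#' from the beam axis, perpendicular to it. The response to an accepted
#' photon of energy E is sampled from branch fractions: full-energy peak,
#' single escape (E - 0.511), double escape (E - 1.022), a uniform Compton
#' continuum, or no deposit; escapes are only offered above the pair
#' production threshold 1.022 MeV. Resolution is Gaussian with
#' FWHM(E) = a*sqrt(E) + b*E.
#'
#' @param distance_cm Beam-axis to crystal-face distance.
#' @param diameter_cm,length_cm Crystal dimensions.
#' @param axis_position_cm Depth (along the beam) under which the detector
#'   face is centred.
#' @param intrinsic_efficiency Probability that a geometrically accepted
#'   photon interacts at all (flat default; may be a function of E in MeV).
#' @param fractions Named numeric: `full`, `single_escape`, `double_escape`,
#'   `continuum`; must sum to <= 1, remainder escapes undetected.
#' @param res_a,res_b FWHM model coefficients (MeV^(1/2) and unitless):
#'   defaults give FWHM(0.662)/0.662 of about 4%, typical of CeBr3.
#' @return A `pg_detector` object.
#' @export
detector_model <- function(distance_cm = 25, diameter_cm = 3.8,
                           length_cm = 7.62, axis_position_cm = 2.5,
                           intrinsic_efficiency = 1,
                           fractions = c(full = 0.35, single_escape = 0.12,
                                         double_escape = 0.08, continuum = 0.30),
                           res_a = 0.028, res_b = 0.005) {
  fr <- fractions[c("full", "single_escape", "double_escape", "continuum")]
  if (anyNA(fr)) abort_pg("fractions must name full, single_escape, double_escape, continuum",
                          "pg_config_error")
  if (sum(fr) > 1 + 1e-12)
    abort_pg("branch fractions must sum to <= 1", "pg_config_error")
  stopifnot(distance_cm > 0, diameter_cm > 0, length_cm > 0)
  structure(list(distance_cm = distance_cm, diameter_cm = diameter_cm,
                 length_cm = length_cm, axis_position_cm = axis_position_cm,
                 intrinsic_efficiency = intrinsic_efficiency,
                 fractions = fr, res_a = res_a, res_b = res_b),
            class = "pg_detector")
}

#' Detector energy resolution
#'
#' @param E Energy in MeV.
#' @param det A `pg_detector`.
#' @return FWHM in MeV.
#' @export
fwhm_at <- function(E, det) det$res_a * sqrt(E) + det$res_b * E

#' Geometric acceptance test
#'
#' Deterministic ray-disk intersection: does a photon emitted at
#' `depth_cm` on the beam axis with the given direction hit the crystal
#' front face? The face is a disk of the crystal diameter centred at
#' (`axis_position_cm`, `distance_cm`, 0), normal to +y, with the beam
#' along +x.
#'
#' @param photons Photon tibble with `depth_cm`, `dir_x`, `dir_y`, `dir_z`.
#' @param det A `pg_detector`.
#' @return Logical vector: hit or miss per photon.
#' @export
geometric_acceptance <- function(photons, det) {
  t <- det$distance_cm / photons$dir_y           # parametric distance to plane
  ok <- is.finite(t) & t > 0
  px <- photons$depth_cm + t * photons$dir_x
  pz <- t * photons$dir_z
  r2 <- (px - det$axis_position_cm)^2 + pz^2
  ok & r2 <= (det$diameter_cm / 2)^2
}

#' Sample deposited energies for accepted photons
#'
#' Each photon deposits its full energy, the single- or double-escape
#' energy, a uniform draw from the Compton continuum (0, Compton edge], or
#' nothing, with the detector's branch fractions. Escape branches are only
#' offered above 1.022 MeV; their probability mass folds into the
#' full-energy branch below threshold. The intrinsic efficiency scales all
#' interacting branches.
#'
#' @param energies Photon energies in MeV (already geometrically accepted).
#' @param det A `pg_detector`.
#' @param seed Optional RNG seed.
#' @return Numeric vector of deposited energies, `NA` for no deposit.
#' @export
deposit <- function(energies, det, seed = NULL) {
  if (any(energies <= 0)) abort_pg("photon energies must be > 0", "pg_domain_error")
  with_seed_(if (!is.null(seed)) stage_seed(seed, "deposit") else NULL, {
    n <- length(energies)
    if (n == 0) return(numeric())
    eff <- if (is.function(det$intrinsic_efficiency))
      det$intrinsic_efficiency(energies) else rep(det$intrinsic_efficiency, n)
    fr <- det$fractions
    can_escape <- energies > 1.022
    p_full <- ifelse(can_escape, fr["full"],
                     fr["full"] + fr["single_escape"] + fr["double_escape"])
    p_se <- ifelse(can_escape, fr["single_escape"], 0)
    p_de <- ifelse(can_escape, fr["double_escape"], 0)
    p_cont <- rep(fr["continuum"], n)
    u <- runif(n) / eff   # u > sum(p) means no interaction / no deposit
    edge <- 2 * energies^2 / (.const$me + 2 * energies)  # Compton edge
    out <- rep(NA_real_, n)
    c1 <- u < p_full
    c2 <- !c1 & u < p_full + p_se
    c3 <- !c1 & !c2 & u < p_full + p_se + p_de
    c4 <- !c1 & !c2 & !c3 & u < p_full + p_se + p_de + p_cont
    out[c1] <- energies[c1]
    out[c2] <- energies[c2] - 0.511
    out[c3] <- energies[c3] - 1.022
    out[c4] <- runif(sum(c4), 0, edge[c4])
    out
  })
}

#' Construct a binned spectrum
#'
#' @param bin_edges Strictly increasing bin edges in MeV (left-closed,
#'   right-open bins).
#' @param counts Per-bin contents (length `length(bin_edges) - 1`).
#' @param n_primaries Number of simulated primaries behind the counts.
#' @param normalized Whether `counts` are already in
#'   counts / (primary * MeV).
#' @return A `pg_spectrum` object.
#' @export
spectrum <- function(bin_edges, counts, n_primaries = NA_integer_,
                     normalized = FALSE) {
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE))
    abort_pg("bin edges must be strictly increasing", "pg_config_error")
  if (length(counts) != length(bin_edges) - 1)
    abort_pg("counts length must match bins", "pg_config_error")
  if (any(counts < 0)) abort_pg("counts must be >= 0", "pg_config_error")
  structure(list(
    data = tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                          bin_hi = bin_edges[-1], value = as.numeric(counts)),
    n_primaries = n_primaries, normalized = isTRUE(normalized)),
    class = "pg_spectrum")
}

#' Default 1024-bin energy axis over 0-10 MeV
#' @param n_bins Number of bins.
#' @param e_max Upper edge in MeV.
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function(n_bins = 1024, e_max = 10) {
  seq(0, e_max, length.out = n_bins + 1)
}

#' @export
print.pg_spectrum <- function(x, ...) {
  cat(sprintf("<pg_spectrum> %d bins over [%g, %g] MeV, %s, n_primaries = %s\n",
              nrow(x$data), min(x$data$bin_lo), max(x$data$bin_hi),
              if (x$normalized) "normalized (counts/primary/MeV)" else "raw counts",
              format(x$n_primaries)))
  invisible(x)
}

#' @method tidy pg_spectrum
#' @export
tidy.pg_spectrum <- function(x, ...) {
  dplyr::mutate(x$data, energy_mev = (.data$bin_lo + .data$bin_hi) / 2)
}

#' Smear deposits with the detector resolution and histogram them
#'
#' Each deposited energy is broadened by a Gaussian with
#' sigma = FWHM(E)/2.3548 and binned on the supplied edges. Total counts are
#' preserved up to edge clipping.
#'
#' @param deposits Deposited energies in MeV (`NA`s dropped).
#' @param det A `pg_detector`.
#' @param bin_edges Bin edges in MeV.
#' @param n_primaries Book-keeping: number of primaries simulated.
#' @param seed Optional RNG seed.
#' @return A raw-counts `pg_spectrum`.
#' @export
broaden_and_bin <- function(deposits, det, bin_edges = default_bin_edges(),
                            n_primaries = NA_integer_, seed = NULL) {
  if (length(bin_edges) < 2) abort_pg("empty bin edges", "pg_config_error")
  deposits <- deposits[is.finite(deposits)]
  with_seed_(if (!is.null(seed)) stage_seed(seed, "broaden") else NULL, {
    if (length(deposits)) {
      sd <- pmax(fwhm_at(deposits, det) / .const$fwhm_sd, 1e-12)
      smeared <- rnorm(length(deposits), deposits, sd)
    } else smeared <- numeric()
    nb <- length(bin_edges) - 1L
    idx <- findInterval(smeared, bin_edges)   # left-closed, right-open
    h <- tabulate(idx[idx >= 1L & idx <= nb & smeared < bin_edges[nb + 1L]], nb)
    spectrum(bin_edges, h, n_primaries = n_primaries, normalized = FALSE)
  })
}

#' Normalize a spectrum to counts per primary per MeV
#'
#' Divides each bin by the number of simulated primaries and by the bin
#' width in MeV.
#'
#' @param spec A raw-counts `pg_spectrum` with known `n_primaries`.
#' @return A normalized `pg_spectrum`.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "pg_spectrum"))
  if (spec$normalized) abort_pg("spectrum already normalized", "pg_state_error")
  if (is.na(spec$n_primaries) || spec$n_primaries <= 0)
    abort_pg("normalization requires n_primaries > 0", "pg_state_error")
  w <- spec$data$bin_hi - spec$data$bin_lo
  spectrum(c(spec$data$bin_lo, spec$data$bin_hi[nrow(spec$data)]),
           spec$data$value / (spec$n_primaries * w),
           n_primaries = spec$n_primaries, normalized = TRUE)
}

#' Write / read a spectrum as CSV + JSON header
#'
#' The CSV holds `bin_lo_mev`, `bin_hi_mev`, `value`; a sibling `.json`
#' records `n_primaries` and the `normalized` flag so the spectrum
#' round-trips exactly.
#'
#' @param spec A `pg_spectrum`.
#' @param path CSV output path (header written next to it as `path.json`).
#' @return `path` invisibly / the restored `pg_spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "pg_spectrum"))
  utils::write.csv(
    data.frame(bin_lo_mev = spec$data$bin_lo, bin_hi_mev = spec$data$bin_hi,
               value = spec$data$value), path, row.names = FALSE)
  jsonlite::write_json(
    list(n_primaries = spec$n_primaries, normalized = spec$normalized),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  np <- hdr$n_primaries
  spectrum(c(d$bin_lo_mev, d$bin_hi_mev[nrow(d)]), d$value,
           n_primaries = if (is.null(np) || is.na(np)) NA_integer_ else np,
           normalized = isTRUE(hdr$normalized))
}
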