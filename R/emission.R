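# Accept-reject prompt-gamma emission along proton trajectories.
#
# For every transport step and every catalogue line, the mean free path is
# lambda = 1 / (n * sigma_PG(E_kin)) with n the number density of the
# line's target element; the step emits a photon of the line energy with
# cumulative probability p = 1 - exp(-dx / lambda). One Bernoulli trial per
# (step, line); emission does not perturb the transport.

#' Emission context for the accept-reject sampler
#'
#' @param mat A `pg_material`.
#' @param catalogue A catalogue tibble (see [default_catalogue()]).
#'   Lines whose target element is absent from the material are inert.
#' @param seed RNG seed; required by [sample_emissions()] unless one is
#'   passed there directly.
#' @return A `pg_emission_context`.
#' @export
emission_context <- function(mat, catalogue = default_catalogue(), seed = NULL) {
  stopifnot(inherits(mat, "pg_material"))
  catalogue <- .validate_catalogue(catalogue)
  nd <- number_densities(mat)
  cat2 <- dplyr::left_join(catalogue, nd, by = c(target_symbol = "symbol"))
  cat2$n_cm3[is.na(cat2$n_cm3)] <- 0  # inert: element not in material
  structure(list(material = mat, catalogue = cat2, seed = seed),
            class = "pg_emission_context")
}

#' Per-step emission probability of one line
#'
#' p = 1 - exp(-dx * n * sigma_PG(ekin)), with sigma in cm^2
#' (1 mb = 1e-27 cm^2) and n the target-element number density in cm^-3.
#'
#' @param dx Step length in cm (vectorised; must be positive).
#' @param ekin Proton kinetic energy at the step start, MeV (vectorised).
#' @param curve Catalogue row carrying the EMG cross-section parameters.
#' @param mat A `pg_material`; the number density is taken for
#'   `curve$target_symbol`.
#' @return Probability in [0, 1); 0 below the reaction threshold.
#' @export
emission_probability <- function(dx, ekin, curve, mat) {
  if (any(dx < 0)) abort_pg("step length must be non-negative", "pg_domain_error")
  nd <- number_densities(mat)
  n <- nd$n_cm3[match(curve$target_symbol, nd$symbol)]
  if (is.na(n)) n <- 0
  sigma_cm2 <- emg_eval(ekin, curve) * .const$mb_cm2
  -expm1(-dx * n * sigma_cm2)
}

#' Expected thin-target photon yield per primary
#'
#' Closed-form first-order yield n * sigma_PG(ekin) * thickness for a target
#' thin enough that the proton energy is effectively constant across it;
#' the analytic check target for [sample_emissions()].
#'
#' @param ekin Proton kinetic energy, MeV.
#' @param thickness Target thickness, cm.
#' @param curve Catalogue row with the cross-section parameters.
#' @param mat A `pg_material`.
#' @param warn_thick Warn if the energy loss over `thickness` exceeds 1% of
#'   `ekin` (thin-target condition violated).
#' @return Expected photons per primary.
#' @export
thin_target_yield <- function(ekin, thickness, curve, mat, warn_thick = TRUE) {
  if (warn_thick && thickness > 0) {
    eloss <- thickness * .bethe(ekin, mat)
    if (eloss > 0.01 * ekin)
      warning("thin-target condition violated: energy loss ",
              signif(eloss, 3), " MeV exceeds 1% of ekin")
  }
  nd <- number_densities(mat)
  n <- nd$n_cm3[match(curve$target_symbol, nd$symbol)]
  if (is.na(n)) n <- 0
  n * emg_eval(ekin, curve) * .const$mb_cm2 * thickness
}

# isotropic unit vectors, n x 3
.isotropic_dirs <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Sample prompt-gamma emissions along trajectories
#'
#' One Bernoulli trial per (step, line) at the per-step cumulative
#' probability; accepted trials add a photon with exactly the line energy,
#' the step's depth as origin, and an isotropically sampled direction.
#' Lines flagged `single_photon_allowed = FALSE` are never emitted.
#' Secondary-process lines (`secondary = TRUE`) are injected per primary as
#' Poisson counts at their configured `yield_per_primary`, with origin depth
#' sampled uniformly along the primary's path.
#'
#' @param trajectories Step tibble from [propagate()].
#' @param context A `pg_emission_context`.
#' @param seed Optional seed overriding `context$seed`.
#' @param strict Require a seed (error when none is supplied).
#' @return A tibble of photons: `energy_mev`, `depth_cm`, `dir_x`, `dir_y`,
#'   `dir_z`, `line_id`, `primary_index`, `time_ns`.
#' @export
sample_emissions <- function(trajectories, context, seed = NULL, strict = TRUE) {
  stopifnot(inherits(context, "pg_emission_context"))
  seed <- seed %||% context$seed
  if (is.null(seed) && strict)
    abort_pg("sample_emissions requires a seed in strict mode", "pg_config_error")

  cat <- context$catalogue
  prim <- dplyr::filter(cat, !.data$secondary, .data$single_photon_allowed,
                        .data$A > 0, .data$n_cm3 > 0)
  secd <- dplyr::filter(cat, .data$secondary, .data$single_photon_allowed,
                        .data$yield_per_primary > 0)

  with_seed_(if (!is.null(seed)) stage_seed(seed, "emission") else NULL, {
    photons <- purrr::map_dfr(seq_len(nrow(prim)), function(i) {
      cv <- prim[i, ]
      sigma_cm2 <- emg_eval(trajectories$ekin_mev, cv) * .const$mb_cm2
      p <- -expm1(-trajectories$dx_cm * cv$n_cm3 * sigma_cm2)
      hit <- runif(length(p)) < p
      if (!any(hit)) return(NULL)
      tibble::tibble(
        energy_mev = cv$energy_mev,
        depth_cm = trajectories$depth_cm[hit] + trajectories$dx_cm[hit] / 2,
        line_id = cv$line_id,
        primary_index = trajectories$primary_index[hit],
        time_ns = trajectories$time_ns[hit])
    })

    if (nrow(secd) > 0 && nrow(trajectories) > 0) {
      paths <- dplyr::summarise(
        dplyr::group_by(trajectories, .data$primary_index),
        range_cm = sum(.data$dx_cm), .groups = "drop")
      sec_ph <- purrr::map_dfr(seq_len(nrow(secd)), function(i) {
        cv <- secd[i, ]
        k <- stats::rpois(nrow(paths), cv$yield_per_primary)
        if (sum(k) == 0) return(NULL)
        idx <- rep(seq_len(nrow(paths)), k)
        tibble::tibble(
          energy_mev = cv$energy_mev,
          depth_cm = runif(length(idx), 0, paths$range_cm[idx]),
          line_id = cv$line_id,
          primary_index = paths$primary_index[idx],
          time_ns = NA_real_)
      })
      photons <- dplyr::bind_rows(photons, sec_ph)
    }

    if (is.null(photons) || nrow(photons) == 0) {
      return(tibble::tibble(energy_mev = numeric(), depth_cm = numeric(),
                            dir_x = numeric(), dir_y = numeric(),
                            dir_z = numeric(), line_id = character(),
                            primary_index = integer(), time_ns = numeric()))
    }
    dirs <- .isotropic_dirs(nrow(photons))
    dplyr::arrange(
      dplyr::mutate(photons, dir_x = dirs[, 1], dir_y = dirs[, 2],
                    dir_z = dirs[, 3]),
      .data$primary_index, .data$depth_cm)[
      , c("energy_mev", "depth_cm", "dir_x", "dir_y", "dir_z", "line_id",
          "primary_index", "time_ns")]
  })
}

#' Expected line yields per primary along a trajectory
#'
#' Deterministic companion of [sample_emissions()]: sums the per-step
#' emission probabilities over one representative trajectory, giving the
#' expected number of photons per primary for each active line (the
#' binomial-sum oracle for the Monte-Carlo sampler).
#'
#' @param trajectory Step tibble for a single primary.
#' @param context A `pg_emission_context`.
#' @return A tibble with `line_id`, `energy_mev`, `expected_per_primary`.
#' @export
expected_yields <- function(trajectory, context) {
  stopifnot(inherits(context, "pg_emission_context"))
  cat <- context$catalogue
  prim <- dplyr::filter(cat, !.data$secondary, .data$single_photon_allowed,
                        .data$A > 0, .data$n_cm3 > 0)
  purrr::map_dfr(seq_len(nrow(prim)), function(i) {
    cv <- prim[i, ]
    sigma_cm2 <- emg_eval(trajectory$ekin_mev, cv) * .const$mb_cm2
    p <- -expm1(-trajectory$dx_cm * cv$n_cm3 * sigma_cm2)
    tibble::tibble(line_id = cv$line_id, energy_mev = cv$energy_mev,
                   expected_per_primary = sum(p))
  })
}

#' Fast equivalent of `sample_emissions` for identical trajectories
#'
#' When transport is deterministic every primary follows the same stepped
#' trajectory, so the number of emissions of a line at a given step across
#' `n_primaries` independent primaries is Binomial(n_primaries, p_step).
#' This samples those binomial counts directly instead of looping over
#' primaries, which is distribution-identical for line counts and origin
#' depths and orders of magnitude faster at large `n_primaries`.
#'
#' @param trajectory Step tibble for a single primary (as from
#'   `propagate()` with `n_primaries = 1`).
#' @param n_primaries Number of primaries to emulate.
#' @param context A `pg_emission_context`.
#' @param seed RNG seed (required).
#' @return Photon tibble in the same shape as [sample_emissions()]
#'   (`primary_index` is NA: individual primaries are not tracked).
#' @export
sample_emission_counts <- function(trajectory, n_primaries, context, seed) {
  stopifnot(inherits(context, "pg_emission_context"), n_primaries >= 0)
  cat <- context$catalogue
  prim <- dplyr::filter(cat, !.data$secondary, .data$single_photon_allowed,
                        .data$A > 0, .data$n_cm3 > 0)
  secd <- dplyr::filter(cat, .data$secondary, .data$single_photon_allowed,
                        .data$yield_per_primary > 0)
  range_cm <- sum(trajectory$dx_cm)

  with_seed_(stage_seed(seed, "emission"), {
    photons <- purrr::map_dfr(seq_len(nrow(prim)), function(i) {
      cv <- prim[i, ]
      sigma_cm2 <- emg_eval(trajectory$ekin_mev, cv) * .const$mb_cm2
      p <- -expm1(-trajectory$dx_cm * cv$n_cm3 * sigma_cm2)
      k <- rbinom(length(p), n_primaries, p)
      tot <- sum(k)
      if (tot == 0) return(NULL)
      idx <- rep(seq_along(p), k)
      tibble::tibble(
        energy_mev = cv$energy_mev,
        depth_cm = trajectory$depth_cm[idx] + trajectory$dx_cm[idx] / 2,
        line_id = cv$line_id,
        primary_index = NA_integer_,
        time_ns = trajectory$time_ns[idx])
    })
    if (nrow(secd) > 0) {
      sec_ph <- purrr::map_dfr(seq_len(nrow(secd)), function(i) {
        cv <- secd[i, ]
        tot <- stats::rpois(1, cv$yield_per_primary * n_primaries)
        if (tot == 0) return(NULL)
        tibble::tibble(
          energy_mev = cv$energy_mev,
          depth_cm = runif(tot, 0, range_cm),
          line_id = cv$line_id,
          primary_index = NA_integer_,
          time_ns = NA_real_)
      })
      photons <- dplyr::bind_rows(photons, sec_ph)
    }
    if (is.null(photons) || nrow(photons) == 0) {
      return(tibble::tibble(energy_mev = numeric(), depth_cm = numeric(),
                            dir_x = numeric(), dir_y = numeric(),
                            dir_z = numeric(), line_id = character(),
                            primary_index = integer(), time_ns = numeric()))
    }
    dirs <- .isotropic_dirs(nrow(photons))
    dplyr::mutate(photons, dir_x = dirs[, 1], dir_y = dirs[, 2],
                  dir_z = dirs[, 3])[
      , c("energy_mev", "depth_cm", "dir_x", "dir_y", "dir_z", "line_id",
          "primary_index", "time_ns")]
  })
}
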