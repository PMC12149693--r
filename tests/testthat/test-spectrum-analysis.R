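test_that("SNIP reproduces a literal reference implementation", {
  set.seed(33)
  v <- 50 + 10 * sin(seq(0, 3, length.out = 64)) + rpois(64, 4)
  v[30] <- v[30] + 400
  got <- snip_baseline(v, p_max = 4, use_lls = FALSE)$data$baseline
  want <- oracle_snip(v, 4)
  expect_equal(got, pmin(want, v), tolerance = 1e-12)
})

test_that("SNIP leaves flats and ramps alone and clips isolated peaks", {
  flat <- rep(25, 64)
  b <- snip_baseline(flat, p_max = 6, use_lls = FALSE)
  expect_equal(b$data$baseline, flat)
  ramp <- seq(1, 64)
  expect_equal(snip_baseline(ramp, p_max = 6, use_lls = FALSE)$data$baseline,
               as.numeric(ramp))
  # a one-bin delta on a flat background returns to the flat level
  B <- 40
  spike <- rep(B, 64); spike[32] <- B + 500
  for (lls in c(FALSE, TRUE)) {
    bb <- snip_baseline(spike, p_max = 3, use_lls = lls)
    expect_lt(abs(bb$data$baseline[32] - B) / B, 0.01)
  }
  expect_error(snip_baseline(spike, p_max = 40), class = "pg_config_error")
})

test_that("SNIP without LLS commutes with additive constants", {
  set.seed(44)
  v <- rpois(128, 30) + 100 * exp(-(seq_len(128) - 60)^2 / 8)
  b1 <- snip_baseline(v, p_max = 8, use_lls = FALSE)$data$baseline
  b2 <- snip_baseline(v + 17, p_max = 8, use_lls = FALSE)$data$baseline
  expect_equal(b2, b1 + 17, tolerance = 1e-12)
})

test_that("baseline never exceeds the spectrum", {
  set.seed(55)
  for (i in 1:5) {
    v <- rpois(256, 20) + 300 * exp(-(seq_len(256) - sample(50:200, 1))^2 / 30)
    for (lls in c(TRUE, FALSE)) {
      b <- snip_baseline(v, p_max = sample(2:20, 1), use_lls = lls)
      expect_true(all(b$data$baseline <= b$data$value + 1e-9))
      expect_true(all(b$data$baseline >= 0))
    }
  }
})

test_that("a noiseless Gaussian line refits its area within 1%", {
  edges <- seq(0, 10, length.out = 1001)
  mid <- (edges[-1] + edges[-1001]) / 2
  area0 <- 123; mu0 <- 4.44; sg0 <- 0.05
  v <- area0 / (sg0 * sqrt(2 * pi)) * exp(-(mid - mu0)^2 / (2 * sg0^2))
  sp <- spectrum(edges, v)
  fits <- fit_lines(sp, regions = tibble::tibble(lo_mev = 4.1, hi_mev = 4.8,
                                                 n_components = 1))
  expect_lt(abs(fits$area - area0) / area0, 0.01)
  expect_lt(abs(fits$centroid_mev - mu0), 1e-3)
  expect_lt(abs(fits$sigma_mev - sg0) / sg0, 0.01)
})

test_that("net areas are stable under bin refinement", {
  area0 <- 50; mu0 <- 6.13; sg0 <- 0.06
  areas <- vapply(c(500, 1000, 2000), function(nb) {
    edges <- seq(0, 10, length.out = nb + 1)
    mid <- (edges[-1] + edges[-(nb + 1)]) / 2
    v <- area0 / (sg0 * sqrt(2 * pi)) * exp(-(mid - mu0)^2 / (2 * sg0^2))
    fit_lines(spectrum(edges, v),
              regions = tibble::tibble(lo_mev = 5.8, hi_mev = 6.45,
                                       n_components = 1))$area
  }, numeric(1))
  expect_lt(max(abs(areas - areas[1])) / areas[1], 0.02)
})

test_that("overlapping doublets resolve with two components", {
  sg0 <- 0.08; sep <- 1.5 * sg0
  mu1 <- 4.40; mu2 <- mu1 + sep
  edges <- seq(4, 5, length.out = 257)
  mid <- (edges[-1] + edges[-257]) / 2
  clean <- 200 / (sg0 * sqrt(2 * pi)) * exp(-(mid - mu1)^2 / (2 * sg0^2)) +
    150 / (sg0 * sqrt(2 * pi)) * exp(-(mid - mu2)^2 / (2 * sg0^2))
  errs <- withr::with_seed(66, {
    purrr::map_dfr(1:100, function(i) {
      noisy <- pmax(clean + rnorm(length(mid), 0, 10), 0)
      f <- fit_lines(spectrum(edges, noisy),
                     regions = tibble::tibble(lo_mev = 4.1, hi_mev = 4.9,
                                              n_components = 2))
      f <- dplyr::arrange(f, centroid_mev)
      tibble::tibble(e1 = abs(f$centroid_mev[1] - mu1),
                     e2 = abs(f$centroid_mev[2] - mu2))
    })
  })
  expect_lt(stats::median(errs$e1), 0.2 * sg0)
  expect_lt(stats::median(errs$e2), 0.2 * sg0)
})

test_that("empty regions yield zero net area and out-of-support regions error", {
  sp <- spectrum(seq(0, 10, length.out = 101), rep(0, 100))
  f <- fit_lines(sp, regions = tibble::tibble(lo_mev = 2, hi_mev = 3,
                                              n_components = 1))
  expect_equal(f$area, 0)
  expect_true(f$converged)
  expect_error(fit_lines(sp, regions = tibble::tibble(
    lo_mev = 20, hi_mev = 30, n_components = 1)), class = "pg_config_error")
})

test_that("yield curves are consistent and respond to disabled lines", {
  det <- detector_model()
  cat <- default_catalogue()
  regions <- default_regions(cat, det, c("12C_2p_0p", "16O_3m_0p"))
  mk <- function(seed) {
    cfg <- run_config(beam_energy_mev = 110.24, n_primaries = 3e6, seed = seed)
    run_simulation(cfg)$spectrum
  }
  sp <- mk(42)
  ys <- yield_curve(list(sp, sp), regions, beam_energies = c(100, 110))
  a <- dplyr::filter(ys, beam_energy_mev == 100)
  b <- dplyr::filter(ys, beam_energy_mev == 110)
  expect_equal(a$area, b$area)   # identical spectra, identical yields
  # with the oxygen line disabled the oxygen ROI integrates to ~0
  cat_nox <- cat
  cat_nox$A[cat_nox$line_id == "16O_3m_0p"] <- 0
  cfg2 <- run_config(beam_energy_mev = 110.24, n_primaries = 3e6, seed = 43,
                     catalogue = cat_nox)
  sp2 <- run_simulation(cfg2)$spectrum
  y2 <- yield_curve(list(sp, sp2), regions, beam_energies = c(110, 110.01))
  ox <- dplyr::filter(y2, line_id == "16O_3m_0p")
  expect_gt(ox$area[1], 0)
  # the disabled-line area is consistent with zero at its uncertainty
  expect_lt(ox$area[2], max(3 * ox$d_area[2], 0.05 * ox$area[1], na.rm = TRUE))
  # inconsistent binning across spectra is refused
  sp_small <- spectrum(seq(0, 10, length.out = 65), rep(1, 64))
  expect_error(yield_curve(list(sp, sp_small), regions,
                           beam_energies = c(1, 2)),
               class = "pg_config_error")
})
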