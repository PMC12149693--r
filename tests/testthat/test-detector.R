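test_that("geometric acceptance resolves aimed and averted photons", {
  det <- detector_model()
  aimed <- tibble::tibble(depth_cm = det$axis_position_cm,
                          dir_x = 0, dir_y = 1, dir_z = 0)
  away <- tibble::tibble(depth_cm = det$axis_position_cm,
                         dir_x = 0, dir_y = -1, dir_z = 0)
  expect_true(geometric_acceptance(aimed, det))
  expect_false(geometric_acceptance(away, det))
})

test_that("isotropic acceptance fraction matches the analytic solid angle", {
  det <- detector_model()
  n <- 1e5
  ph <- withr::with_seed(31, {
    z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    tibble::tibble(depth_cm = det$axis_position_cm,
                   dir_x = r * cos(phi), dir_y = r * sin(phi), dir_z = z)
  })
  frac <- mean(geometric_acceptance(ph, det))
  # point on the axis below the disk centre: Omega = 2 pi (1 - D/sqrt(D^2+r^2))
  r_d <- det$diameter_cm / 2; D <- det$distance_cm
  p <- (1 - D / sqrt(D^2 + r_d^2)) / 2
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("deposit branch logic honours fractions and the pair threshold", {
  det_full <- detector_model(fractions = c(full = 1, single_escape = 0,
                                           double_escape = 0, continuum = 0))
  e <- rep(4.44, 1000)
  expect_equal(deposit(e, det_full, seed = 1), e)
  # below 1.022 MeV the escape branches are folded into the full peak
  det <- detector_model()
  d662 <- deposit(rep(0.662, 5000), det, seed = 2)
  d662 <- d662[is.finite(d662)]
  expect_false(any(abs(d662 - (0.662 - 0.511)) < 1e-9))
  expect_false(any(d662 < 0))
  expect_error(deposit(c(1, -1), det), class = "pg_domain_error")
  expect_error(detector_model(fractions = c(full = 0.9, single_escape = 0.2,
                                            double_escape = 0, continuum = 0)),
               class = "pg_config_error")
})

test_that("deposit branch frequencies match configured fractions", {
  det <- detector_model(fractions = c(full = 0.4, single_escape = 0.15,
                                      double_escape = 0.1, continuum = 0.2))
  n <- 1e5
  e0 <- 4.44
  d <- deposit(rep(e0, n), det, seed = 3)
  p_none <- 1 - 0.4 - 0.15 - 0.1 - 0.2
  shares <- c(full = mean(abs(d - e0) < 1e-9, na.rm = TRUE) * mean(is.finite(d)),
              se = mean(abs(d - (e0 - 0.511)) < 1e-9, na.rm = TRUE) *
                mean(is.finite(d)),
              de = mean(abs(d - (e0 - 1.022)) < 1e-9, na.rm = TRUE) *
                mean(is.finite(d)),
              none = mean(!is.finite(d)))
  want <- c(0.4, 0.15, 0.1, p_none)
  for (i in seq_along(want)) {
    se_i <- sqrt(want[i] * (1 - want[i]) / n)
    expect_lt(abs(shares[i] - want[i]), 3 * se_i)
  }
})

test_that("broadening preserves counts and reduces to plain binning at zero width", {
  det0 <- detector_model(res_a = 1e-13, res_b = 1e-13)
  dep <- c(1.001, 2.502, 2.504, 7.2)
  sp <- broaden_and_bin(dep, det0, bin_edges = seq(0, 10, by = 0.01),
                        seed = 4)
  expect_equal(sum(sp$data$value), length(dep))
  expect_equal(sp$data$value[sp$data$bin_lo == 1.00], 1)
  expect_equal(sp$data$value[sp$data$bin_lo == 2.50], 2)
  det <- detector_model()
  sp2 <- broaden_and_bin(rep(4.44, 5000), det, seed = 5)
  expect_equal(sum(sp2$data$value), 5000)  # edges span +-6 sigma easily
  expect_error(broaden_and_bin(1, det, bin_edges = numeric()),
               class = "pg_config_error")
})

test_that("a broadened line refits to the configured resolution width", {
  det <- detector_model()
  sp <- broaden_and_bin(rep(4.44, 2e4), det, seed = 6)
  fits <- fit_lines(sp, regions = tibble::tibble(
    lo_mev = 4.2, hi_mev = 4.7, n_components = 1, line_id = "c44"))
  want_sigma <- fwhm_at(4.44, det) / (2 * sqrt(2 * log(2)))
  expect_lt(abs(fits$sigma_mev - want_sigma) / want_sigma, 0.05)
  expect_lt(abs(fits$centroid_mev - 4.44), 0.01)
})

test_that("a monoenergetic 4.44 MeV source shows full, single and double escape peaks", {
  det <- detector_model(fractions = c(full = 0.4, single_escape = 0.25,
                                      double_escape = 0.2, continuum = 0.1))
  dep <- deposit(rep(4.44, 5e4), det, seed = 7)
  sp <- broaden_and_bin(dep, det, seed = 8)
  b <- snip_baseline(sp, p_max = 12, use_lls = TRUE)
  fits <- fit_lines(sp, b, tibble::tibble(
    lo_mev = c(4.25, 3.75, 3.25), hi_mev = c(4.65, 4.1, 3.6),
    n_components = 1, line_id = c("full", "se", "de")))
  expect_equal(fits$centroid_mev, c(4.44, 3.929, 3.418), tolerance = 0.01)
  expect_true(all(fits$area > 0))
})

test_that("normalization divides by primaries and bin width and guards state", {
  sp <- spectrum(seq(0, 10, by = 0.01), c(1000, rep(0, 999)),
                 n_primaries = 1e6)
  nm <- normalize_spectrum(sp)
  expect_equal(nm$data$value[1], 0.1)
  expect_true(nm$normalized)
  expect_error(normalize_spectrum(nm), class = "pg_state_error")
  # conservation identity: sum(value * width) * n_primaries = total counts
  sp2 <- spectrum(seq(0, 10, by = 0.5), rpois(20, 50), n_primaries = 1234)
  nm2 <- normalize_spectrum(sp2)
  expect_equal(sum(nm2$data$value * (nm2$data$bin_hi - nm2$data$bin_lo)) * 1234,
               sum(sp2$data$value), tolerance = 1e-9)
  # all-zero spectrum stays zero
  z <- normalize_spectrum(spectrum(0:10, rep(0, 10), n_primaries = 10))
  expect_true(all(z$data$value == 0))
})

test_that("spectra round-trip through CSV with their metadata", {
  sp <- spectrum(seq(0, 10, length.out = 101), rpois(100, 5),
                 n_primaries = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$data, sp$data)
  expect_equal(back$n_primaries, sp$n_primaries)
  expect_equal(back$normalized, sp$normalized)
})
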