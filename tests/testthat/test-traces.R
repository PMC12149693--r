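one_pulse_events <- function(area = 500, mu = 60, sigma = 4, tau = 12,
                             trace_id = 1) {
  tibble::tibble(trace_id = trace_id, mu_ns = mu, sigma_ns = sigma,
                 tau_ns = tau, area = area)
}

test_that("trace generation reproduces the analytic pulse shape", {
  gen0 <- generate_traces(one_pulse_events()[0, ], n_traces = 2)
  expect_true(all(gen0$traces$adc == 0))
  gen <- generate_traces(one_pulse_events(), n_traces = 1)
  t <- gen$traces$t_ns
  expect_length(t, 50)
  expect_equal(gen$traces$adc, 500 * emg_density(t, 60, 4, 12),
               tolerance = 1e-12)
  # ledger area vs numerical integral of the noiseless trace
  riemann <- sum(gen$traces$adc) * 4
  expect_lt(abs(riemann - 500) / 500, 0.005)
  expect_error(generate_traces(one_pulse_events(mu = 300)),
               class = "pg_config_error")
  four <- dplyr::bind_rows(purrr::map(1:4, ~ one_pulse_events(mu = 40 + 30 * .x)))
  four$trace_id <- 1
  expect_error(generate_traces(four), class = "pg_config_error")
})

test_that("baseline restoration removes constant offsets exactly", {
  gen <- generate_traces(one_pulse_events(), n_traces = 1, baseline = 37.5)
  fixed <- restore_baseline(gen$traces)
  expect_equal(fixed$adc, 500 * emg_density(fixed$t_ns, 60, 4, 12),
               tolerance = 1e-9)
  # already-zero baseline unchanged
  gen0 <- generate_traces(one_pulse_events(), n_traces = 1)
  expect_equal(restore_baseline(gen0$traces)$adc, gen0$traces$adc)
  expect_error(restore_baseline(gen0$traces, k = 100), class = "pg_config_error")
})

test_that("the median baseline estimator is unbiased within sigma/sqrt(k)", {
  sigma <- 3; k <- 5
  gen <- generate_traces(one_pulse_events()[0, ], n_traces = 1000,
                         noise_sigma = sigma, baseline = 10, seed = 11)
  fixed <- restore_baseline(gen$traces, k = k)
  resid <- dplyr::summarise(dplyr::group_by(fixed, trace_id),
                            bias = mean(adc[seq_len(k)]))$bias
  expect_lt(abs(mean(resid)), sigma / sqrt(k))
})

test_that("a noiseless single pulse is recovered within 1%", {
  gen <- generate_traces(one_pulse_events(), n_traces = 1)
  fit <- fit_pulses(gen$traces, noise_sigma = 0.5)
  expect_equal(fit$n_pulses, 1L)
  expect_lt(abs(fit$area - 500) / 500, 0.01)
  truth_amp <- 500 * emg_density(promptgamma:::emg_apex(60, 4, 12)$location,
                                 60, 4, 12)
  expect_lt(abs(fit$amplitude - truth_amp) / truth_amp, 0.01)
  expect_gt(fit$adj_r_squared, 0.999)
})

test_that("well-separated pile-up pulses are both recovered at SNR 20", {
  sigma_t <- 4; noise <- 1
  apex_h <- promptgamma:::emg_apex(0, sigma_t, 12)$height
  area <- 20 * noise / apex_h   # SNR 20 in amplitude
  res <- withr::with_seed(77, {
    purrr::map_dfr(1:100, function(i) {
      mu1 <- runif(1, 40, 70)
      ev <- tibble::tibble(trace_id = 1, mu_ns = c(mu1, mu1 + 40),
                           sigma_ns = sigma_t, tau_ns = 12, area = area)
      gen <- generate_traces(ev, n_traces = 1, noise_sigma = noise,
                             seed = 5000 + i)
      fit <- fit_pulses(gen$traces, noise_sigma = noise)
      tibble::tibble(n = fit$n_pulses[1],
                     err = if (fit$n_pulses[1] == 2)
                       max(abs(fit$area - area) / area) else NA_real_)
    })
  })
  expect_gte(mean(res$n == 2), 0.9)
  expect_lt(stats::median(res$err, na.rm = TRUE), 0.05)
})

test_that("pure-noise traces select zero pulses almost always", {
  gen <- generate_traces(one_pulse_events()[0, ], n_traces = 500,
                         noise_sigma = 2, seed = 13)
  fits <- fit_pulses(gen$traces, noise_sigma = 2, amp_floor = 5)
  expect_gte(mean(fits$n_pulses == 0), 0.95)
})

test_that("the quality filter is a pure threshold predicate", {
  fits <- tibble::tibble(trace_id = 1:4, t0_ns = c(0, 10, 20, 30),
                         n_pulses = 1L, pulse = 1L, area = 1,
                         amplitude = 1, mu_ns = 50, sigma_ns = 4,
                         tau_ns = c(5, 80, 10, 10),
                         apex_ns = 55,
                         adj_r_squared = c(0.99, 0.99, 0.5, 0.99),
                         degenerate = FALSE)
  expect_equal(nrow(quality_filter(fits, r2_min = -Inf,
                                   tau_range = c(-Inf, Inf))), 4)
  expect_equal(nrow(quality_filter(fits, r2_min = 1 + 1e-9,
                                   tau_range = c(-Inf, Inf))), 0)
  kept <- quality_filter(fits, r2_min = 0.9, tau_range = c(1, 60))
  expect_equal(kept$trace_id, c(1, 4))
  gated <- quality_filter(fits, r2_min = -Inf, tau_range = c(-Inf, Inf),
                          time_gate = c(5, 25))
  expect_equal(gated$trace_id, c(2, 3))
  expect_error(quality_filter(fits, tau_range = c(2, 2)),
               class = "pg_config_error")
})

test_that("quality thresholds separate clean from corrupted traces", {
  # labeled fixture, 50/50: clean scintillator pulses (tau = 12 ns) vs
  # corrupted traces - electronic glitches with an unphysical decay
  # constant (tau = 2 ns) and noise bursts that fit poorly. Thresholds were
  # chosen on an independent training split (different seeds).
  n_each <- 60
  gen_clean <- generate_traces(
    tibble::tibble(trace_id = 1:n_each, mu_ns = 60, sigma_ns = 4,
                   tau_ns = 12, area = 600),
    n_traces = n_each, noise_sigma = 1.5, seed = 121)
  gen_glitch <- generate_traces(
    tibble::tibble(trace_id = 1:(n_each / 2), mu_ns = 60, sigma_ns = 1,
                   tau_ns = 2, area = 250),
    n_traces = n_each / 2, noise_sigma = 1.5, seed = 122)
  gen_burst <- generate_traces(
    tibble::tibble(trace_id = 1:(n_each / 2), mu_ns = 60, sigma_ns = 4,
                   tau_ns = 12, area = 250),
    n_traces = n_each / 2, noise_sigma = 8, seed = 123)
  gen_glitch$traces$trace_id <- gen_glitch$traces$trace_id + n_each
  gen_burst$traces$trace_id <- gen_burst$traces$trace_id + 2 * n_each
  all_traces <- dplyr::bind_rows(gen_clean$traces, gen_glitch$traces,
                                 gen_burst$traces)
  fits <- fit_pulses(all_traces, noise_sigma = 1.5)
  kept <- quality_filter(fits, r2_min = 0.9, tau_range = c(8, 20))
  is_clean <- kept$trace_id <= n_each
  expect_gte(mean(is_clean), 0.9)           # precision for "clean"
  expect_gte(sum(is_clean), 0.8 * n_each)   # and most clean traces survive
})

test_that("raw spectra conserve counts and area/apex modes are proportional", {
  fits <- tibble::tibble(trace_id = 1, t0_ns = 0, n_pulses = 1L, pulse = 1L,
                         area = 500, amplitude = 18, mu_ns = 50,
                         sigma_ns = 4, tau_ns = 12, apex_ns = 55,
                         adj_r_squared = 0.999, degenerate = FALSE)
  sp1 <- build_raw_spectrum(fits, "area", n_channels = 128)
  expect_equal(sum(sp1$data$counts), 1)
  expect_equal(sum(sp1$data$counts > 0), 1)
  # a pure single-line fixture: area and apex spectra peak in channels whose
  # ratio equals the mean area/apex ratio of the fits
  ev <- tibble::tibble(trace_id = 1:200, mu_ns = 60, sigma_ns = 4,
                       tau_ns = 12, area = 600)
  gen <- generate_traces(ev, n_traces = 200, noise_sigma = 1, seed = 23)
  f <- fit_pulses(gen$traces, noise_sigma = 1)
  f <- dplyr::filter(f, n_pulses == 1)
  expect_equal(sum(build_raw_spectrum(f, "area")$data$counts), nrow(f))
  max_val <- 1.2 * max(f$area, f$amplitude)
  spa <- build_raw_spectrum(f, "area", n_channels = 2048, max_value = max_val)
  spx <- build_raw_spectrum(f, "apex", n_channels = 2048, max_value = max_val)
  ch_a <- sum(spa$data$channel * spa$data$counts) / sum(spa$data$counts)
  ch_x <- sum(spx$data$channel * spx$data$counts) / sum(spx$data$counts)
  expect_lt(abs(ch_a / ch_x - mean(f$area / f$amplitude)) /
              mean(f$area / f$amplitude), 0.02)
  expect_error(build_raw_spectrum(f, "volume"))
})

test_that("non-paralyzable dead-time correction inverts the saturation map", {
  expect_equal(dead_time_correct(123, 0), 123)
  expect_equal(dead_time_correct(100, 1e-3), 100 / 0.9, tolerance = 1e-15)
  # exact algebraic inverse of n -> n / (1 + n tau) across seven decades
  n_true <- 10^seq(0, 4, length.out = 25)
  tau <- 2e-5
  m <- oracle_measured_rate(n_true, tau)
  expect_equal(dead_time_correct(m, tau), n_true, tolerance = 1e-12)
  # correction factor strictly increasing in m
  f <- dead_time_correct(seq(10, 1000, by = 10), 1e-4) /
    seq(10, 1000, by = 10)
  expect_true(all(diff(f) > 0))
  expect_error(dead_time_correct(2000, 1e-3), class = "pg_saturation_error")
})

test_that("linear calibrations interpolate anchors and survive jitter", {
  two <- data.frame(channel = c(100, 900), energy_mev = c(0.511, 4.44))
  cal <- calibrate(two)
  expect_equal(apply_calibration(c(100, 900), cal), c(0.511, 4.44),
               tolerance = 1e-12)
  expect_equal(max(abs(cal$residuals)), 0)
  # perfectly linear synthetic gain across the standard anchor set
  energies <- c(0.511, 0.662, 2.22, 3.418, 3.929, 4.44)
  gain <- 0.005; offset <- 0.02
  anchors <- data.frame(channel = (energies - offset) / gain,
                        energy_mev = energies)
  cal2 <- calibrate(anchors)
  expect_equal(cal2$gain, gain, tolerance = 1e-9)
  expect_equal(cal2$offset, offset, tolerance = 1e-9)
  # jittered channels: gain recovered within 1% (median over 200 repeats)
  errs <- withr::with_seed(42, {
    vapply(1:200, function(i) {
      a <- anchors
      a$channel <- a$channel + rnorm(nrow(a), 0, 0.5)
      abs(calibrate(a)$gain - gain) / gain
    }, numeric(1))
  })
  expect_lt(stats::median(errs), 0.01)
  expect_error(calibrate(data.frame(channel = c(5, 5),
                                    energy_mev = c(1, 2))),
               class = "pg_validation_error")
})
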