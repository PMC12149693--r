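# Independent oracles, coded separately from the package implementation.

# Bethe stopping power, re-derived from scratch: explicit per-element loop,
# classical constants, no shared code with promptgamma internals.
oracle_bethe_mev_cm <- function(E_mev, density, elements, I_ev) {
  re <- 2.8179403262e-13        # classical electron radius, cm
  mec2 <- 0.51099895            # MeV
  NA_ <- 6.02214076e23
  mpc2 <- 938.27208816
  gamma <- (E_mev + mpc2) / mpc2
  beta2 <- 1 - gamma^-2
  wmax <- 2 * mec2 * beta2 * gamma^2 /
    (1 + 2 * gamma * mec2 / mpc2 + (mec2 / mpc2)^2)
  I_mev <- I_ev * 1e-6
  total <- 0
  for (i in seq_len(nrow(elements))) {
    n_e <- density * elements$mass_fraction[i] * NA_ / elements$A[i] *
      elements$Z[i]                    # electrons / cm^3
    pref <- 4 * pi * re^2 * mec2 * n_e / beta2
    total <- total + pref *
      (log(sqrt(2 * mec2 * beta2 * gamma^2 * wmax) / I_mev) - beta2 / 1)
  }
  total
}

# EMG by brute-force quadrature of the defining convolution:
# integral over t >= 0 of Gaussian(x - t; mu, sigma) * exp(-t/tau)/tau dt.
# The Gaussian factor concentrates the mass near t = x - mu, so integrate
# over that window (integrate() misses the bump on [0, Inf) in the far tail).
oracle_emg_quadrature <- function(x, mu, sigma, tau) {
  vapply(x, function(xx) {
    lo <- max(0, xx - mu - 12 * sigma)
    hi <- xx - mu + 12 * sigma
    if (hi <= lo) return(0)
    stats::integrate(function(t) stats::dnorm(xx - t, mu, sigma) *
                       exp(-t / tau) / tau,
                     lo, hi, rel.tol = 1e-10)$value
  }, numeric(1))
}

# SNIP reference: literal transcription of the ascending clip on a plain
# vector, no LLS, no vectorised shortcuts.
oracle_snip <- function(v, p_max) {
  n <- length(v)
  for (p in 1:p_max) {
    w <- v
    for (i in (p + 1):(n - p)) {
      m <- (v[i - p] + v[i + p]) / 2
      if (m < v[i]) w[i] <- m
    }
    v <- w
  }
  v
}

# forward non-paralyzable dead-time map (true rate -> measured rate)
oracle_measured_rate <- function(n_true, tau) n_true / (1 + n_true * tau)

# toy PMMA-like composition table shared by material tests
pmma_elements <- function() {
  data.frame(symbol = c("H", "C", "O"), Z = c(1, 6, 8),
             A = c(1.008, 12.011, 15.999),
             mass_fraction = c(0.080538, 0.599848, 0.319614))
}

# single-step trajectory helper
one_step_traj <- function(ekin, dx, n = 1L) {
  tidyr::expand_grid(primary_index = seq_len(n),
                     tibble::tibble(depth_cm = 0, dx_cm = dx,
                                    ekin_mev = ekin, time_ns = 0))
}
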