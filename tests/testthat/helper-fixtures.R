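# shared fixtures, built in code

make_debye_spectrum <- function(R_inf = 100, R = 500, tau0 = 1e-4,
                                frequencies = default_frequencies()) {
  z <- R_inf + R / (1 + 1i * 2 * pi * frequencies * tau0)
  impedance_spectrum(frequencies, z)
}

# DRT built directly from a Gaussian-sum curve (no inversion involved)
make_gauss_drt <- function(params, grid = relaxation_grid(), R_inf = 100,
                           noise_sd = 0, seed = NULL) {
  x <- grid$log_centers
  y <- numeric(length(x))
  for (k in seq_len(nrow(params))) {
    y <- y + params$a[k] *
      exp(-(x - log(params$mu[k]))^2 / (2 * params$sigma[k]^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
  }
  drt_result(grid, y * grid$bin_width_logtau, R_inf = R_inf)
}

# quadrature of the log-normal density a/tau * exp(-ln^2(tau/mu)/(2 s^2))
# over tau in (0, Inf), done in x = ln tau
lognormal_area <- function(a, mu, sigma) {
  stats::integrate(function(x) a * exp(-(x - log(mu))^2 / (2 * sigma^2)),
                   log(mu) - 15 * sigma, log(mu) + 15 * sigma,
                   rel.tol = 1e-10)$value
}

quiet_solve <- function(...) suppressMessages(solve_drt(...))
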