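test_that("every element has Z(0) = R and vanishes at high frequency", {
  els <- list(debye_element(500, 1e-4),
              rq_element(800, q = 0.8, tau0 = 1e-3),
              lognormal_element(300, 1e-5, 0.4),
              warburg_element(1000, 2))
  for (el in els) {
    expect_equal(element_impedance(el, 0), complex(real = el$R),
                 tolerance = 1e-9)
    expect_lt(Mod(element_impedance(el, 1e12)), 0.02 * el$R)
  }
})

test_that("an RQ element with q = 1 degenerates to a Debye element", {
  f <- default_frequencies(60)
  tau0 <- 2e-4
  R <- 700
  z_rq <- element_impedance(rq_element(R, q = 1, Q = tau0 / R), f)
  z_db <- element_impedance(debye_element(R, tau0), f)
  expect_lt(max(abs(z_rq - z_db)), 1e-12 * R)
})

test_that("a narrow log-normal element approaches its Debye limit", {
  f <- default_frequencies(40)
  z_ln <- element_impedance(lognormal_element(500, 1e-5, 0.01), f)
  z_db <- element_impedance(debye_element(500, 1e-5), f)
  expect_lt(max(abs(z_ln - z_db) / abs(z_db)), 0.001)
})

test_that("log-normal quadrature agrees with a dense trapezoid rule", {
  el <- lognormal_element(400, 3e-6, 0.5)
  f <- c(100, 1e3, 1e4, 1e5)
  z <- element_impedance(el, f)
  x <- seq(log(3e-6) - 10 * 0.5, log(3e-6) + 10 * 0.5, length.out = 1e5)
  dx <- x[2] - x[1]
  phi <- exp(-(x - log(3e-6))^2 / (2 * 0.5^2)) / (0.5 * sqrt(2 * pi))
  z_ref <- vapply(2 * pi * f, function(w)
    sum(phi / (1 + 1i * w * exp(x))) * dx * 400, complex(1))
  expect_lt(max(abs(z - z_ref) / abs(z_ref)), 1e-6)
})

test_that("the analytic Cole-Cole distribution is symmetric, normalized and Fredholm-consistent", {
  el <- rq_element(1000, q = 0.8, tau0 = 1e-3)
  x0 <- log(el$tau0)
  for (d in c(0.3, 1, 2.5)) {
    expect_equal(cole_cole_G(x0 + d, x0, 0.8), cole_cole_G(x0 - d, x0, 0.8))
  }
  norm <- integrate(function(x) cole_cole_G(x, x0, 0.8), x0 - 80, x0 + 80,
                    rel.tol = 1e-10)$value
  expect_equal(norm, 1, tolerance = 1e-6)
  # pushing G through the relaxation kernel reproduces the RQ impedance
  f <- default_frequencies(50)
  z_ref <- element_impedance(el, f)
  z_fwd <- vapply(2 * pi * f, function(w) {
    re <- integrate(function(x) cole_cole_G(x, x0, 0.8) / (1 + (w * exp(x))^2),
                    x0 - 80, x0 + 80, rel.tol = 1e-10)$value
    im <- integrate(function(x) -cole_cole_G(x, x0, 0.8) * w * exp(x) /
                      (1 + (w * exp(x))^2),
                    x0 - 80, x0 + 80, rel.tol = 1e-10)$value
    1000 * complex(real = re, imaginary = im)
  }, complex(1))
  expect_lt(max(abs(z_fwd - z_ref) / abs(z_ref)), 0.001)
  expect_error(cole_cole_drt(rq_element(100, q = 1, Q = 1e-6),
                             relaxation_grid()), "degenerate")
})

test_that("compartment time constants evaluate the printed formulas", {
  cell <- cell_model(r_cell = 50e-6, C_m = 1e-2, sigma_c = 0.5,
                     sigma_0 = 0.1)
  expect_equal(beta_time_constant(cell), 5e-5 * 1e-2 * (2 + 5))
  expect_equal(beta_time_constant(cell), 3.5e-6)

  # series double-layer capacitance limits
  c_inf <- cell_model(C_m = 1e-2, C_dl = 1e6)
  expect_equal(series_membrane_capacitance(c_inf), 1e-2, tolerance = 1e-6)
  c_eq <- cell_model(C_m = 1e-2, C_dl = 1e-2)
  expect_equal(series_membrane_capacitance(c_eq), 5e-3)

  # counterion diffusion time scales with the square of the radius
  t1 <- alpha_time_constant(cell_model(r_cell = 10e-6))
  t2 <- alpha_time_constant(cell_model(r_cell = 20e-6))
  expect_equal(t2 / t1, 4)
})

test_that("starch dilution follows the insulating-sphere mixture rule", {
  expect_equal(starch_effective_conductivity(0.5, 0), 0.5)
  expect_equal(starch_effective_conductivity(1, 0.75), 0.25 / 1.375)
  p <- seq(0, 0.9, by = 0.1)
  eff <- vapply(p, starch_effective_conductivity, 1, sigma_c = 0.5)
  expect_true(all(diff(eff) < 0))
  expect_error(starch_effective_conductivity(0.5, 1), "\\[0, 1\\)")
  # starch at 75% lengthens the membrane polarization time severalfold
  cell <- cell_model(starch_fraction = 0.75)
  ratio <- beta_time_constant(cell, use_starch = TRUE) /
    beta_time_constant(cell)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 10)
})

test_that("spectrum generation is deterministic given a seed", {
  pm0 <- potato_model(noise_sigma = 0)
  s0 <- generate_spectrum(pm0)
  z_ref <- rep(complex(real = pm0$R_inf), 300)
  for (el in c(pm0$tissue_elements, pm0$electrode_elements)) {
    z_ref <- z_ref + element_impedance(el, s0$frequencies)
  }
  expect_equal(s0$impedance, z_ref)

  pm <- potato_model(noise_sigma = 0.005, seed = 5)
  s1 <- generate_spectrum(pm)
  s2 <- generate_spectrum(pm)
  expect_identical(s1$impedance, s2$impedance)
  s3 <- generate_spectrum(pm, seed = 6)
  expect_false(identical(s3$impedance, s1$impedance))
  expect_error(generate_spectrum(potato_model(noise_sigma = 0.005)),
               "seed")
})

test_that("the paired dataset has the designed size and null behaviour", {
  levels <- c(60, 100, 200, 300, 400, 500, 750, 1000)
  ds <- generate_ep_dataset(potato_model(0.001), levels, replicates = 3,
                            effect_profile = ep_profile_null(levels),
                            seed = 2)
  expect_length(ds, 24)
  expect_equal(sort(unique(vapply(ds, `[[`, 1, "field"))), levels)
  # null multipliers: identical ground truth, same model pre and post
  for (rec in ds[c(1, 12, 24)]) {
    expect_equal(rec$truth$pre, rec$truth$post)
  }
})

test_that("effect profiles act on the intended elements only", {
  levels <- 100
  ds <- generate_ep_dataset(potato_model(0.001), levels, replicates = 1,
                            effect_profile = ep_profile_reversible(levels),
                            seed = 3)
  tr <- ds[[1]]$truth
  beta <- grepl("^beta", tr$pre$label)
  expect_equal(tr$post$R, tr$pre$R)   # DC content untouched
  expect_equal(tr$post$mu[beta] / tr$pre$mu[beta],
               rep(exp(-0.4), sum(beta)))
  expect_equal(tr$post$mu[!beta], tr$pre$mu[!beta])

  ds_i <- generate_ep_dataset(potato_model(0.001), levels, replicates = 1,
                              effect_profile = ep_profile_irreversible(levels),
                              seed = 3)
  tr_i <- ds_i[[1]]$truth
  shrunk <- tr_i$pre$label %in% c("alpha", "beta1", "beta2", "beta3", "starch")
  expect_equal(tr_i$post$R[shrunk] / tr_i$pre$R[shrunk],
               rep(0.3, sum(shrunk)))
  expect_equal(tr_i$post$R[!shrunk], tr_i$pre$R[!shrunk])
  expect_error(
    generate_ep_dataset(potato_model(0.001), c(100, 200), 1,
                        ep_profile_null(100), seed = 1),
    "missing levels")
})
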