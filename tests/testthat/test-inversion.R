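test_that("kernel entries match the closed-form Debye kernel", {
  # single bin at tau0; frequencies chosen so omega*tau = 0-ish and 1
  g <- relaxation_grid(1e-4 * exp(-0.05), 1e-4 * exp(0.05), M = 10)
  tau <- g$centers[5]
  A <- build_kernel(g, c(1e-9, 1 / (2 * pi * tau)), include_R_inf = FALSE)
  expect_equal(A[1, 5], 1, tolerance = 1e-10)        # DC limit: (1, 0)
  expect_equal(A[3, 5], 0, tolerance = 1e-8)
  expect_equal(A[2, 5], 0.5, tolerance = 1e-12)      # omega*tau = 1: (1-j)/2
  expect_equal(A[4, 5], -0.5, tolerance = 1e-12)

  g <- relaxation_grid()
  f <- default_frequencies()
  A <- build_kernel(g, f)
  ref_re <- outer(2 * pi * f, g$centers,
                  function(w, t) Re(1 / (1 + 1i * w * t)))
  ref_im <- outer(2 * pi * f, g$centers,
                  function(w, t) Im(1 / (1 + 1i * w * t)))
  expect_lt(max(abs(A[1:300, 1:120] - ref_re)), 1e-14)
  expect_lt(max(abs(A[301:600, 1:120] - ref_im)), 1e-14)
  expect_equal(A[, 121], c(rep(1, 300), rep(0, 300)))
})

test_that("noiseless Debye spectrum inverts to a single mode with the right mass", {
  s <- make_debye_spectrum(R_inf = 100, R = 500, tau0 = 1e-4)
  drt <- quiet_solve(s)
  expect_true(all(drt$weights >= 0))
  expect_equal(drt$R_inf, 100, tolerance = 0.01)
  expect_equal(drt$R_p, 500, tolerance = 0.01)
  xbar <- sum(drt$grid$log_centers * drt$weights) / sum(drt$weights)
  expect_lt(abs(xbar - log(1e-4)), 0.05)
  # conservation: R_p equals the reconstruction's DC limit minus R_inf
  z0 <- reconstruct_impedance(drt, 0)$impedance
  expect_equal(Re(z0) - drt$R_inf, drt$R_p, tolerance = 1e-9)
})

test_that("a pure resistor inverts to an empty distribution", {
  f <- default_frequencies(100)
  s <- impedance_spectrum(f, rep(440 + 0i, 100))
  drt <- quiet_solve(s)
  expect_lt(drt$R_p, 1)
  expect_equal(drt$R_inf, 440, tolerance = 0.01)
})

test_that("RQ spectrum inverts to the analytic Cole-Cole distribution", {
  el <- rq_element(1000, q = 0.8, tau0 = 1e-4)
  f <- default_frequencies()
  s <- impedance_spectrum(f, 150 + element_impedance(el, f))
  drt <- quiet_solve(s)
  expect_equal(drt$R_inf, 150, tolerance = 0.01)
  expect_equal(drt$R_p, 1000, tolerance = 0.01)
  ref <- cole_cole_drt(el, drt$grid)
  x <- drt$grid$log_centers
  Gv <- drt_curve(ref)
  m <- sum(x * Gv) / sum(Gv)
  sd_eq <- sqrt(sum((x - m)^2 * Gv) / sum(Gv))
  central <- abs(x - m) <= 2 * sd_eq
  l2 <- sqrt(sum((drt_curve(drt) - Gv)[central]^2) / sum(Gv[central]^2))
  expect_lt(l2, 0.10)
})

test_that("reconstruction obeys the Debye half-power point and the DC limit", {
  g <- relaxation_grid(1e-5, 1e-3, M = 21)
  w <- rep(0, 21)
  j <- 11
  w[j] <- 500
  d <- drt_result(g, w, R_inf = 100)
  tau0 <- g$centers[j]
  z <- reconstruct_impedance(d, 1 / (2 * pi * tau0))$impedance
  expect_equal(z, 100 + 500 * (1 - 1i) / 2, tolerance = 1e-12)
  expect_equal(reconstruct_impedance(d, 0)$impedance, 600 + 0i)
})

test_that("solve then reconstruct is self-consistent on noiseless input", {
  s <- make_debye_spectrum()
  drt <- quiet_solve(s)
  rec <- reconstruct_impedance(drt, s$frequencies)
  expect_lt(max(abs(rec$impedance - s$impedance) / abs(s$impedance)), 0.01)
})

test_that("solution is invariant under input row permutation", {
  s <- make_debye_spectrum()
  set.seed(4)
  ord <- sample.int(length(s$frequencies))
  s2 <- impedance_spectrum(s$frequencies[ord], s$impedance[ord])
  d1 <- quiet_solve(s)
  d2 <- quiet_solve(s2)
  expect_equal(d1$weights, d2$weights)
  expect_equal(d1$R_inf, d2$R_inf)
})

test_that("roughness is non-increasing in lambda", {
  set.seed(11)
  f <- default_frequencies()
  z <- 100 + 500 / (1 + 1i * 2 * pi * f * 1e-4)
  zn <- complex(real = Re(z) * (1 + rnorm(300, 0, 0.01)),
                imaginary = Im(z) * (1 + rnorm(300, 0, 0.01)))
  s <- impedance_spectrum(f, zn)
  rough <- vapply(c(1e-3, 1e-2, 1e-1, 1, 10), function(lam) {
    d <- quiet_solve(s, inversion_settings(lambda_reg = lam))
    sqrt(sum(diff(d$weights)^2))
  }, 1)
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("lambda selection by GCV behaves on clean and degenerate inputs", {
  s <- make_debye_spectrum()
  tl <- tune_lambda(s, candidate_lambdas = c(1e-3, 0.1, 10))
  expect_lte(tl$lambda, 0.1)   # clean data need little smoothing
  expect_equal(nrow(tl$diagnostics), 3)
  expect_true(all(diff(tl$diagnostics$roughness) <= 1e-8))
  single <- tune_lambda(s, candidate_lambdas = 0.1)
  expect_identical(single$lambda, 0.1)
})

test_that("out-of-band spectra and underdetermined exact fits warn", {
  g <- relaxation_grid(1e-4, 1e-3, M = 30)
  f <- default_frequencies(50)
  s <- make_debye_spectrum(frequencies = f)
  expect_warning(suppressMessages(solve_drt(s, inversion_settings(grid = g))),
                 "two decades")
  f8 <- default_frequencies(10)
  s8 <- make_debye_spectrum(frequencies = f8)
  expect_warning(
    suppressMessages(solve_drt(s8, inversion_settings(lambda_reg = 0))),
    "underdetermined")
})
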