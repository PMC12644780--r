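test_that("a single-Gaussian DRT is recovered to 0.5%", {
  drt <- make_gauss_drt(data.frame(a = 300, mu = 1e-5, sigma = 0.5))
  m <- fit_gaussians(drt, 1, seed = 1)
  expect_equal(m$components$a, 300, tolerance = 0.005)
  expect_equal(m$components$mu, 1e-5, tolerance = 0.005)
  expect_equal(m$components$sigma, 0.5, tolerance = 0.005)
})

test_that("two well-separated Gaussians are recovered, ordered by decreasing mu", {
  drt <- make_gauss_drt(data.frame(a = c(200, 300), mu = c(1e-6, 1e-4),
                                   sigma = c(0.4, 0.4)))
  m <- fit_gaussians(drt, 2, seed = 1)
  expect_equal(m$components$mu, c(1e-4, 1e-6), tolerance = 0.02)
  expect_equal(m$components$a, c(300, 200), tolerance = 0.02)
  expect_equal(m$components$sigma, c(0.4, 0.4), tolerance = 0.02)
  expect_true(all(diff(m$components$mu) < 0))
})

test_that("a flat zero curve has no mass support", {
  d <- drt_result(relaxation_grid(), rep(0, 120), R_inf = 50)
  expect_error(fit_gaussians(d, 1), "mass support")
})

test_that("component resistances follow the log-normal area identity", {
  expect_equal(gaussian_component(1, 1e-5, 1)$R_pk, sqrt(2 * pi))
  # quadrature of the log-normal density over tau in (0, Inf)
  expect_equal(lognormal_area(2, 1e-5, 0.5), 2 * 0.5 * sqrt(2 * pi),
               tolerance = 1e-6)
  drt <- make_gauss_drt(data.frame(a = c(100, 250), mu = c(3e-6, 2e-4),
                                   sigma = c(0.3, 0.5)), R_inf = 100)
  m <- fit_gaussians(drt, 2, seed = 2)
  cr <- component_resistances(m)
  for (k in 1:2) {
    area <- lognormal_area(m$components$a[k], m$components$mu[k],
                           m$components$sigma[k])
    expect_equal(cr$R_pk[k], area, tolerance = 1e-6)
  }
  expect_equal(cr$R_0, m$R_inf + sum(cr$R_pk))
})

test_that("DC additivity matches the mixture impedance at zero frequency", {
  drt <- make_gauss_drt(data.frame(a = c(150, 300), mu = c(2e-6, 5e-5),
                                   sigma = c(0.35, 0.45)), R_inf = 120)
  m <- fit_gaussians(drt, 2, seed = 3)
  z0 <- decomposition_impedance(m, 0)$impedance
  expect_equal(Re(z0), m$R_0, tolerance = 0.005)
  expect_equal(Im(z0), 0)
  # and a model with R_inf = 100 and total component mass 900 has R_0 = 1000
  fake <- m
  fake$R_inf <- 100
  fake$components$a <- fake$components$a *
    900 / sum(fake$components$R_pk)
  fake$components$R_pk <- fake$components$a * fake$components$sigma * sqrt(2 * pi)
  expect_equal(component_resistances(fake)$R_0, 1000)
})

test_that("the F statistic follows the printed formula and its edge cases", {
  r <- f_test(10, 5, 120, 5)
  expect_equal(r$F, (10 - 5) / 5 * (120 - 16) / 3)
  expect_equal(r$F, 104 / 3)
  expect_equal(r$df1, 3L)
  expect_equal(r$df2, 104)

  r0 <- f_test(7, 7, 50, 2)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)

  expect_error(f_test(5, 0, 50, 2), "positive")
  expect_error(f_test(3, 5, 50, 2), ">= rss_k")
  expect_error(f_test(10, 5, 10, 3), "degrees of freedom")
})

test_that("fit residual is non-increasing in K on the same curve", {
  drt <- make_gauss_drt(data.frame(a = c(250, 200, 300),
                                   mu = c(3e-7, 1.2e-6, 4.5e-6),
                                   sigma = c(0.3, 0.35, 0.4)),
                        noise_sd = 5, seed = 9)
  rss <- vapply(1:4, function(K)
    fit_gaussians(drt, K, seed = K)$rss, 1)
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
})

test_that("select_K recovers the generating component count", {
  params3 <- data.frame(a = c(250, 200, 300), mu = c(3e-7, 1.2e-6, 4.5e-6),
                        sigma = c(0.3, 0.35, 0.4))
  hits <- 0
  for (s in 1:5) {
    drt <- make_gauss_drt(params3, noise_sd = 5, seed = s)
    sel <- suppressWarnings(select_K(drt, 1:5, tail_cutoff = 6e-6, seed = s))
    hits <- hits + (sel$K == 3)
  }
  expect_gte(hits, 4)

  drt1 <- make_gauss_drt(data.frame(a = 300, mu = 1e-6, sigma = 0.4),
                         noise_sd = 5, seed = 1)
  sel1 <- suppressWarnings(select_K(drt1, 1:3, tail_cutoff = 6e-6, seed = 1))
  expect_equal(sel1$K, 1L)

  expect_error(select_K(drt1, 1:3, tail_cutoff = 1e-8), "tail window")
})

test_that("six-component curves are recovered within the stated bands", {
  # direct Gaussian-sum DRTs with >= 0.5 ln-unit separations
  truth <- tissue_truth(potato_model())
  params <- data.frame(a = truth$R / (truth$sigma * sqrt(2 * pi)),
                       mu = truth$mu, sigma = truth$sigma)
  ok <- 0
  for (s in 1:5) {
    drt <- make_gauss_drt(params, R_inf = 150, noise_sd = 2, seed = s)
    m <- fit_gaussians(drt, 6, seed = s, n_starts = 8)
    mu_ratio <- m$components$mu / truth$mu
    rpk_err <- abs(m$components$R_pk / truth$R - 1)
    ok <- ok + (all(mu_ratio <= 1.25 & mu_ratio >= 0.8) &&
                  all(rpk_err <= 0.10))
  }
  expect_gte(ok, 4)
})
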