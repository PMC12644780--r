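#' Dispersion elements
#'
#' Canonical building blocks of a tissue/electrode impedance model. Each
#' element has a polarization resistance R (its DC limit; every element
#' satisfies Z(0) = R and Z tends to 0 as frequency grows):
#'
#' * `debye_element(R, tau0)`: \eqn{Z = R/(1 + j\omega\tau_0)}, a single
#'   first-order relaxation.
#' * `rq_element(R, q, Q | tau0)`: resistance in parallel with a
#'   constant-phase element, \eqn{Z = R/(1 + RQ(j\omega)^q)} — the
#'   Cole-Cole frequency response, characteristic time
#'   \eqn{\tau_0 = (RQ)^{1/q}}.
#' * `lognormal_element(R, mu, sigma)`: continuum of Debye relaxations
#'   with log-normal distribution (Gaussian in \eqn{\ln\tau}, location
#'   `mu` seconds, spread `sigma`).
#' * `warburg_element(R, tau_d)`: finite-length diffusion,
#'   \eqn{Z = R\,\tanh\sqrt{j\omega\tau_d}/\sqrt{j\omega\tau_d}}.
#'
#' @param R polarization resistance, ohms (> 0).
#' @param tau0,mu,tau_d characteristic times, seconds.
#' @param sigma spread in natural-log tau (> 0).
#' @param q CPE exponent in (0, 1]; `q = 1` reduces to a Debye element.
#' @param Q CPE magnitude (S s^q); give either `Q` or `tau0`.
#' @param label optional role label used by the electroporation effect
#'   profiles (e.g. `"alpha"`, `"beta"`, `"starch"`).
#' @return list of class `dispersion_element`.
#' @name dispersion_element
NULL

.new_element <- function(kind, R, params, label = NULL) {
  if (!is.finite(R) || R <= 0) stop("element R must be positive")
  structure(c(list(kind = kind, R = R, label = label), params),
            class = "dispersion_element")
}

#' @rdname dispersion_element
#' @export
debye_element <- function(R, tau0, label = NULL) {
  stopifnot(tau0 > 0)
  .new_element("debye", R, list(tau0 = tau0), label)
}

#' @rdname dispersion_element
#' @export
rq_element <- function(R, q, Q = NULL, tau0 = NULL, label = NULL) {
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]")
  if (is.null(Q) && is.null(tau0)) stop("give either Q or tau0")
  if (is.null(Q)) Q <- tau0^q / R
  .new_element("rq", R, list(q = q, Q = Q, tau0 = (R * Q)^(1 / q)), label)
}

#' @rdname dispersion_element
#' @export
lognormal_element <- function(R, mu, sigma, label = NULL) {
  stopifnot(mu > 0, sigma > 0)
  .new_element("lognormal", R, list(mu = mu, sigma = sigma), label)
}

#' @rdname dispersion_element
#' @export
warburg_element <- function(R, tau_d, label = NULL) {
  stopifnot(tau_d > 0)
  .new_element("warburg_finite", R, list(tau_d = tau_d), label)
}

#' @export
print.dispersion_element <- function(x, ...) {
  p <- x[setdiff(names(x), c("kind", "R", "label"))]
  cat("<dispersion_element> ", x$kind,
      if (!is.null(x$label)) paste0(" [", x$label, "]"),
      ": R=", format(x$R, digits = 4), " ohm, ",
      paste(names(p), sapply(p, format, digits = 4),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Impedance of a dispersion element
#'
#' Vectorized over frequency. The log-normal element is integrated by
#' adaptive quadrature on the log-tau axis (relative tolerance 1e-8).
#'
#' @param element a [dispersion_element].
#' @param frequencies Hz (zero allowed).
#' @return complex vector of impedances, ohms.
#' @export
element_impedance <- function(element, frequencies) {
  stopifnot(inherits(element, "dispersion_element"))
  w <- 2 * pi * frequencies
  switch(
    element$kind,
    debye = element$R / (1 + 1i * w * element$tau0),
    rq = {
      jw_q <- ifelse(w == 0, 0 + 0i, (1i * w)^element$q)
      element$R / (1 + element$R * element$Q * jw_q)
    },
    lognormal = {
      m <- log(element$mu); s <- element$sigma
      norm <- s * sqrt(2 * pi)
      vapply(w, function(wi) {
        if (wi == 0) return(complex(real = element$R))
        re <- stats::integrate(function(x)
          exp(-(x - m)^2 / (2 * s^2)) / (1 + (wi * exp(x))^2) / norm,
          m - 14 * s, m + 14 * s, rel.tol = 1e-8,
          stop.on.error = TRUE)$value
        im <- stats::integrate(function(x)
          -exp(-(x - m)^2 / (2 * s^2)) * wi * exp(x) /
            (1 + (wi * exp(x))^2) / norm,
          m - 14 * s, m + 14 * s, rel.tol = 1e-8,
          stop.on.error = TRUE)$value
        element$R * complex(real = re, imaginary = im)
      }, complex(1))
    },
    warburg_finite = {
      s <- sqrt(1i * w * element$tau_d)
      z <- ifelse(w == 0, complex(real = 1), tanh(s) / s)
      element$R * z
    },
    stop("unknown element kind: ", element$kind))
}

#' Analytic DRT of a Cole-Cole (RQ) element
#'
#' The distribution of relaxation times of
#' \eqn{Z = R/(1 + RQ(j\omega)^q)} is closed-form on the log axis:
#' \deqn{G(x) = \frac{1}{2\pi}\,
#'   \frac{\sin(\pi(1-q))}{\cosh(q(x - x_0)) - \cos(\pi(1-q))},}
#' with \eqn{x_0 = \ln\tau_0}, \eqn{\tau_0 = (RQ)^{1/q}} — a symmetric
#' bell in \eqn{\ln\tau} that integrates to 1. The returned DRT carries
#' per-bin masses \eqn{R\,G(x_j)\Delta x}. (This closed form is
#' validated against forward quadrature of the relaxation integral in
#' the test suite.)
#'
#' @param element an RQ [dispersion_element] with `q < 1`.
#' @param grid a [relaxation_grid()].
#' @return a [drt_result()] with `R_inf = 0`.
#' @export
cole_cole_drt <- function(element, grid) {
  stopifnot(inherits(element, "dispersion_element"),
            inherits(grid, "relaxation_grid"))
  if (element$kind != "rq") stop("cole_cole_drt needs an rq element")
  q <- element$q
  if (q >= 1) stop("q = 1 is a degenerate delta distribution; use a Debye element")
  x0 <- log(element$tau0)
  G <- cole_cole_G(grid$log_centers, x0, q)
  drt_result(grid, element$R * G * grid$bin_width_logtau, R_inf = 0)
}

#' @rdname cole_cole_drt
#' @param x natural-log relaxation times.
#' @param x0 natural log of the characteristic time.
#' @param q CPE exponent in (0, 1).
#' @export
cole_cole_G <- function(x, x0, q) {
  (1 / (2 * pi)) * sin(pi * (1 - q)) /
    (cosh(q * (x - x0)) - cos(pi * (1 - q)))
}

#' Single-cell model
#'
#' Parameters of an isolated spherical cell used by the compartment
#' time-constant formulas: radius, membrane and double-layer
#' capacitances per area, intracellular and bulk conductivities, surface
#' counterion mobility, temperature, and the intracellular volume
#' fraction occupied by (insulating) starch granules.
#'
#' @param r_cell radius, m.
#' @param C_m membrane capacitance, F/m^2.
#' @param C_dl double-layer capacitance at the membrane surface, F/m^2.
#' @param sigma_c intracellular conductivity, S/m.
#' @param sigma_0 bulk medium conductivity, S/m.
#' @param u counterion generalized mobility (velocity per unit force),
#'   s/kg, so that \eqn{D = u k T} is the surface diffusion coefficient.
#' @param T_K temperature, K.
#' @param starch_fraction intracellular volume fraction of starch, [0, 1).
#' @return list of class `cell_model`.
#' @export
cell_model <- function(r_cell = 50e-6, C_m = 1e-2, C_dl = 2e-2,
                       sigma_c = 0.5, sigma_0 = 0.1, u = 2.5e11,
                       T_K = 293.15, starch_fraction = 0) {
  vals <- c(r_cell, C_m, C_dl, sigma_c, sigma_0, u, T_K)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical cell parameters must be positive")
  }
  if (starch_fraction < 0 || starch_fraction >= 1) {
    stop("starch_fraction must be in [0, 1)")
  }
  structure(list(r_cell = r_cell, C_m = C_m, C_dl = C_dl,
                 sigma_c = sigma_c, sigma_0 = sigma_0, u = u, T_K = T_K,
                 starch_fraction = starch_fraction),
            class = "cell_model")
}

#' Membrane capacitance in series with the double layer
#'
#' \eqn{C_m / (1 + C_m/C_{dl})}: the double layer acts as a capacitance
#' in series with the membrane at beta-dispersion time scales. Tends to
#' \eqn{C_m} as \eqn{C_{dl} \to \infty}; equals \eqn{C_m/2} when the two
#' are equal.
#'
#' @param cell a [cell_model()].
#' @return capacitance, F/m^2.
#' @export
series_membrane_capacitance <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  cell$C_m / (1 + cell$C_m / cell$C_dl)
}

#' Effective cytoplasm conductivity with starch granules
#'
#' Maxwell-Garnett dilution for insulating spherical inclusions at
#' volume fraction p: \eqn{\sigma_{eff} = \sigma_c (1-p)/(1+p/2)},
#' strictly decreasing in p with \eqn{\sigma_{eff}(0) = \sigma_c}.
#'
#' @param sigma_c cytoplasm conductivity, S/m.
#' @param starch_fraction p in [0, 1).
#' @return effective conductivity, S/m.
#' @export
starch_effective_conductivity <- function(sigma_c, starch_fraction) {
  if (starch_fraction < 0 || starch_fraction >= 1) {
    stop("starch_fraction must be in [0, 1)")
  }
  sigma_c * (1 - starch_fraction) / (1 + starch_fraction / 2)
}

#' Compartment time constants
#'
#' `beta_time_constant`: interfacial (Maxwell-Wagner) polarization of an
#' isolated spherical cell,
#' \eqn{\tau_\beta = r\,C\,(1/\sigma_c + 1/(2\sigma_0))}, where C is the
#' membrane capacitance — optionally the series combination with the
#' double layer — and \eqn{\sigma_c} optionally the starch-corrected
#' effective cytoplasm conductivity.
#'
#' `alpha_time_constant`: lateral diffusion of the counterion atmosphere
#' on a spherical particle, \eqn{\tau_\alpha = r^2/(2ukT)} with k the
#' Boltzmann constant.
#'
#' @param cell a [cell_model()].
#' @param use_double_layer replace \eqn{C_m} with
#'   [series_membrane_capacitance()]? (default FALSE)
#' @param use_starch replace \eqn{\sigma_c} with the starch-corrected
#'   effective conductivity? (default FALSE)
#' @return time constant, seconds.
#' @export
beta_time_constant <- function(cell, use_double_layer = FALSE,
                               use_starch = FALSE) {
  stopifnot(inherits(cell, "cell_model"))
  C <- if (use_double_layer) series_membrane_capacitance(cell) else cell$C_m
  sc <- if (use_starch) {
    starch_effective_conductivity(cell$sigma_c, cell$starch_fraction)
  } else cell$sigma_c
  cell$r_cell * C * (1 / sc + 1 / (2 * cell$sigma_0))
}

#' @rdname beta_time_constant
#' @export
alpha_time_constant <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  cell$r_cell^2 / (2 * cell$u * .k_B * cell$T_K)
}
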