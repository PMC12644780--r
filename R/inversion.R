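#' Inversion settings
#'
#' Settings for the regularized DRT inversion. The defaults (M = 120 bins
#' on \eqn{[10^{-7}, 10^{-1.5}]} s, \eqn{\lambda = 0.1}) are appropriate
#' for 300-point tissue spectra acquired between 20 Hz and 400 kHz.
#'
#' @param lambda_reg nonnegative smoothness penalty weight.
#' @param grid a [relaxation_grid()].
#' @param fit_R_inf if `TRUE` (default) the series resistance
#'   \eqn{R_\infty} is estimated as an extra nonnegative regression
#'   column (excluded from the roughness penalty); if `FALSE` it is fixed
#'   at `R_inf_fixed` and subtracted from the data.
#' @param part_weighting relative weight of imaginary-part residuals
#'   versus real-part residuals (default 1: joint fit, equal weight).
#' @param R_inf_fixed fixed series resistance (ohms) when
#'   `fit_R_inf = FALSE`.
#' @return Object of class `inversion_settings`.
#' @export
inversion_settings <- function(lambda_reg = 0.1, grid = relaxation_grid(),
                               fit_R_inf = TRUE, part_weighting = 1,
                               R_inf_fixed = 0) {
  if (!is.finite(lambda_reg) || lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (part_weighting <= 0) stop("part_weighting must be > 0")
  stopifnot(inherits(grid, "relaxation_grid"))
  structure(list(lambda_reg = lambda_reg, grid = grid,
                 fit_R_inf = fit_R_inf, part_weighting = part_weighting,
                 R_inf_fixed = R_inf_fixed),
            class = "inversion_settings")
}

#' Discretized Debye kernel
#'
#' Real-valued design operator of the discretized Fredholm problem
#' \eqn{Z(\omega) = R_\infty + \sum_j w_j / (1 + j\omega\tau_j)}.
#' The first N rows hold \eqn{\mathrm{Re}[1/(1+j\omega_i\tau_j)]}, the
#' last N rows \eqn{\mathrm{Im}[1/(1+j\omega_i\tau_j)]}; the final column
#' is the \eqn{R_\infty} regressor (1 on real rows, 0 on imaginary rows).
#' Each bin is evaluated at its log-midpoint (the bin width is absorbed
#' into the weight).
#'
#' @param grid a [relaxation_grid()].
#' @param frequencies Hz.
#' @param include_R_inf append the \eqn{R_\infty} column? (default TRUE)
#' @return matrix of dimension `2N x (M+1)` (or `2N x M`).
#' @export
build_kernel <- function(grid, frequencies, include_R_inf = TRUE) {
  stopifnot(inherits(grid, "relaxation_grid"))
  w <- 2 * pi * frequencies
  wt <- outer(w, grid$centers)          # omega_i * tau_j
  denom <- 1 + wt^2
  A_re <- 1 / denom
  A_im <- -wt / denom
  A <- rbind(A_re, A_im)
  if (include_R_inf) {
    A <- cbind(A, c(rep(1, length(w)), rep(0, length(w))))
  }
  A
}

# First-difference roughness operator on the weight columns; the R_inf
# column (if present) is never penalized.
.roughness_operator <- function(M, n_col) {
  D <- matrix(0, M - 1, n_col)
  idx <- seq_len(M - 1)
  D[cbind(idx, idx)] <- -1
  D[cbind(idx, idx + 1)] <- 1
  D
}

#' Solve the regularized DRT inversion
#'
#' Estimates nonnegative per-bin masses \eqn{w_j} (and \eqn{R_\infty})
#' minimizing
#' \deqn{\|Z_{meas} - Z_{model}\|^2 + \lambda \|D_1 w\|^2, \quad w \ge 0,}
#' with real and imaginary parts stacked and \eqn{D_1} the
#' first-difference operator on the log-tau grid. The problem is convex
#' and solved deterministically by Lawson-Hanson nonnegative least
#' squares on the augmented system; no seed is involved.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param settings an [inversion_settings()].
#' @return A [drt_result()]. A warning is raised when the spectrum band
#'   does not cover the grid's characteristic frequencies within two
#'   decades, or when `lambda_reg = 0` with more unknowns than equations.
#' @examples
#' f <- default_frequencies(100)
#' z <- 100 + 500 / (1 + 1i * 2 * pi * f * 1e-4)
#' drt <- solve_drt(impedance_spectrum(f, z))
#' dc_resistance(drt)
#' @export
solve_drt <- function(spectrum, settings = inversion_settings()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(settings, "inversion_settings"))
  grid <- settings$grid
  f <- spectrum$frequencies
  # band coverage check: grid characteristic band, expanded 2 decades
  f_lo <- 1 / (2 * pi * grid$tau_sup) / 100
  f_hi <- 1 / (2 * pi * grid$tau_inf) * 100
  if (min(f) < f_lo || max(f) > f_hi) {
    warning("spectrum frequencies extend beyond the relaxation grid's ",
            "sensitive band expanded by two decades")
  }
  N <- length(f)
  M <- grid$M
  if (settings$lambda_reg == 0 && M + settings$fit_R_inf > 2 * N) {
    warning("lambda_reg = 0 with more unknowns than equations: ",
            "exact fit is underdetermined on this grid")
  }
  A <- build_kernel(grid, f, include_R_inf = settings$fit_R_inf)
  z <- spectrum$impedance
  if (!settings$fit_R_inf) z <- z - settings$R_inf_fixed
  b <- c(Re(z), Im(z))
  pw <- settings$part_weighting
  if (pw != 1) {
    sc <- c(rep(1, N), rep(pw, N))
    A <- A * sc
    b <- b * sc
  }
  n_col <- ncol(A)
  D <- .roughness_operator(M, n_col)
  Aaug <- rbind(A, sqrt(settings$lambda_reg) * D)
  baug <- c(b, rep(0, M - 1))
  sol <- tryCatch(
    pracma::lsqnonneg(Aaug, baug),
    error = function(e) stop("NNLS solver failed: ", conditionMessage(e)))
  x <- sol$x
  weights <- x[seq_len(M)]
  R_inf <- if (settings$fit_R_inf) x[M + 1] else settings$R_inf_fixed
  resid <- b - A %*% x
  res <- drt_result(grid, weights, R_inf = R_inf,
                    lambda_reg = settings$lambda_reg,
                    residual_norm = sqrt(sum(resid^2)))
  message(sprintf(
    "solve_drt: N=%d M=%d lambda=%g residual=%.4g R_inf=%.4g R_p=%.4g",
    N, M, settings$lambda_reg, res$residual_norm, res$R_inf, res$R_p))
  res
}

#' Reconstruct an impedance spectrum from a DRT
#'
#' Forward evaluation \eqn{Z(\omega) = R_\infty + \sum_j w_j /
#' (1 + j\omega\tau_j)}. At \eqn{\omega \to 0} this tends to
#' \eqn{R_\infty + R_p}; at \eqn{\omega \to \infty} to \eqn{R_\infty}.
#'
#' @param drt a [drt_result()].
#' @param frequencies Hz (zero allowed: DC limit).
#' @return an [impedance_spectrum()] (built without the positivity
#'   warning path: reconstruction is exact arithmetic).
#' @export
reconstruct_impedance <- function(drt, frequencies) {
  stopifnot(inherits(drt, "drt_result"))
  w <- 2 * pi * frequencies
  jwt <- outer(1i * w, drt$grid$centers)
  z <- drt$R_inf + as.vector((1 / (1 + jwt)) %*% drt$weights)
  structure(list(frequencies = frequencies, impedance = z,
                 meta = list(reconstructed = TRUE, R_inf = drt$R_inf,
                             R_p = drt$R_p)),
            class = "impedance_spectrum")
}

#' Choose the regularization weight by generalized cross-validation
#'
#' Solves the inversion for each candidate \eqn{\lambda} and scores it by
#' GCV, \eqn{n\|r\|^2/(n - \mathrm{df}_\lambda)^2}, with the effective
#' degrees of freedom taken as the trace of the ridge hat matrix
#' restricted to the active (positive) set of the NNLS solution.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param settings an [inversion_settings()] (its `lambda_reg` is ignored).
#' @param candidate_lambdas numeric vector of candidates (length >= 1; a
#'   single candidate is returned unconditionally).
#' @return list with `lambda` (chosen), `diagnostics` (data.frame of
#'   lambda, gcv, residual, roughness, df), and `drt` (the solution at
#'   the chosen lambda).
#' @export
tune_lambda <- function(spectrum, settings = inversion_settings(),
                        candidate_lambdas = 10^seq(-3, 1, by = 1)) {
  stopifnot(length(candidate_lambdas) >= 1, all(candidate_lambdas >= 0))
  candidate_lambdas <- sort(candidate_lambdas)
  grid <- settings$grid
  M <- grid$M
  A <- build_kernel(grid, spectrum$frequencies,
                    include_R_inf = settings$fit_R_inf)
  n_col <- ncol(A)
  D <- .roughness_operator(M, n_col)
  rows <- lapply(candidate_lambdas, function(lam) {
    s <- settings
    s$lambda_reg <- lam
    drt <- suppressMessages(suppressWarnings(solve_drt(spectrum, s)))
    x <- c(drt$weights, if (settings$fit_R_inf) drt$R_inf)
    active <- which(x > 1e-10 * max(x, 1e-300))
    if (settings$fit_R_inf) active <- union(active, n_col)
    Aa <- A[, active, drop = FALSE]
    Da <- D[, active, drop = FALSE]
    H <- Aa %*% solve(crossprod(Aa) + lam * crossprod(Da) +
                        1e-12 * diag(length(active)), t(Aa))
    df <- sum(diag(H))
    n <- nrow(A)
    resid <- drt$residual_norm
    gcv <- n * resid^2 / (n - df)^2
    data.frame(lambda = lam, gcv = gcv, residual = resid,
               roughness = sqrt(sum(diff(drt$weights)^2)),
               df = df)
  })
  diag_df <- do.call(rbind, rows)
  best <- if (nrow(diag_df) == 1) 1 else which.min(diag_df$gcv)
  s <- settings
  s$lambda_reg <- diag_df$lambda[best]
  list(lambda = diag_df$lambda[best], diagnostics = diag_df,
       drt = suppressMessages(suppressWarnings(solve_drt(spectrum, s))))
}
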