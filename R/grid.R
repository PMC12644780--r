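#' Relaxation-time grid
#'
#' A bounded log-spaced grid of relaxation times on which the distribution
#' of relaxation times (DRT) is discretized as M step functions. All
#' internal log axes use the natural logarithm (base-10 appears only in
#' axis labels), so that the change of variables
#' \eqn{G(x) = \tau g(\tau)}, \eqn{x = \ln\tau} is exact.
#'
#' @param tau_inf,tau_sup domain bounds in seconds, `0 < tau_inf < tau_sup`.
#' @param M number of bins (at least 10). Bin centers are the log-midpoints
#'   of M equal intervals in \eqn{\ln\tau}.
#' @return Object of class `relaxation_grid` with elements `tau_inf`,
#'   `tau_sup`, `M`, `centers` (seconds), `log_centers` (natural log),
#'   `bin_width_logtau`.
#' @export
relaxation_grid <- function(tau_inf = 1e-7, tau_sup = 10^-1.5, M = 120) {
  if (!(tau_inf > 0 && tau_sup > tau_inf)) {
    stop("need 0 < tau_inf < tau_sup")
  }
  if (M < 10) stop("M must be at least 10")
  dx <- (log(tau_sup) - log(tau_inf)) / M
  x <- log(tau_inf) + (seq_len(M) - 0.5) * dx
  structure(list(tau_inf = tau_inf, tau_sup = tau_sup, M = as.integer(M),
                 centers = exp(x), log_centers = x, bin_width_logtau = dx),
            class = "relaxation_grid")
}

#' @export
print.relaxation_grid <- function(x, ...) {
  cat("<relaxation_grid> M=", x$M, " bins, tau in [",
      format(x$tau_inf, digits = 4), ", ", format(x$tau_sup, digits = 4),
      "] s, dx=", format(x$bin_width_logtau, digits = 4), " (ln tau)\n",
      sep = "")
  invisible(x)
}

#' DRT result object
#'
#' The discretized distribution of relaxation times. Bin j carries the
#' nonnegative mass \eqn{w_j = R_p G(x_j) \Delta x} in ohms; the
#' polarization resistance is the total mass, \eqn{R_p = \sum_j w_j}, and
#' the DC resistance is \eqn{R_0 = R_\infty + R_p}.
#'
#' @param grid a [relaxation_grid()].
#' @param weights nonnegative per-bin mass in ohms, length `grid$M`.
#' @param R_inf high-frequency series resistance in ohms, nonnegative.
#' @param lambda_reg regularization weight used in the inversion (NA if
#'   the DRT was built analytically).
#' @param residual_norm fit residual norm in ohms (NA if not fitted).
#' @return Object of class `drt_result`.
#' @export
drt_result <- function(grid, weights, R_inf = 0, lambda_reg = NA_real_,
                       residual_norm = NA_real_) {
  stopifnot(inherits(grid, "relaxation_grid"))
  weights <- as.numeric(weights)
  if (length(weights) != grid$M) {
    stop("weights length must equal grid$M = ", grid$M)
  }
  if (any(!is.finite(weights)) || any(weights < -1e-12)) {
    stop("weights must be finite and nonnegative")
  }
  weights[weights < 0] <- 0
  if (!is.finite(R_inf) || R_inf < 0) stop("R_inf must be nonnegative")
  structure(list(grid = grid, weights = weights, R_inf = R_inf,
                 R_p = sum(weights), lambda_reg = lambda_reg,
                 residual_norm = residual_norm),
            class = "drt_result")
}

#' @export
print.drt_result <- function(x, ...) {
  cat("<drt_result> M=", x$grid$M, " bins\n", sep = "")
  cat("  R_inf = ", format(x$R_inf, digits = 6), " ohm, R_p = ",
      format(x$R_p, digits = 6), " ohm, R_0 = ",
      format(x$R_inf + x$R_p, digits = 6), " ohm\n", sep = "")
  if (is.finite(x$lambda_reg)) {
    cat("  lambda = ", format(x$lambda_reg), ", residual norm = ",
        format(x$residual_norm, digits = 4), " ohm\n", sep = "")
  }
  invisible(x)
}

#' DC resistance of a DRT
#'
#' \eqn{R_0 = R_\infty + R_p}, the model-extrapolated steady-state
#' resistance.
#'
#' @param drt a [drt_result()].
#' @return DC resistance in ohms.
#' @export
dc_resistance <- function(drt) {
  stopifnot(inherits(drt, "drt_result"))
  drt$R_inf + drt$R_p
}

#' Per-bin DRT curve
#'
#' The curve fitted by the Gaussian decomposition:
#' \eqn{y(x_j) = R_p G(x_j) = w_j / \Delta x} (ohms per natural-log-tau
#' unit).
#'
#' @param drt a [drt_result()].
#' @return numeric vector of length `grid$M`.
#' @export
drt_curve <- function(drt) {
  stopifnot(inherits(drt, "drt_result"))
  drt$weights / drt$grid$bin_width_logtau
}

#' Write / read a DRT as CSV
#'
#' Columns `tau_s` (bin centers, seconds) and `weight_ohm` (per-bin mass).
#' `R_inf`, the regularization weight and the residual norm are stored in
#' `#`-prefixed header lines so the file round-trips.
#'
#' @param drt a [drt_result()].
#' @param path CSV path.
#' @return `path` invisibly (`write_drt`); a [drt_result()] (`read_drt`).
#' @export
write_drt <- function(drt, path) {
  stopifnot(inherits(drt, "drt_result"))
  hdr <- c(
    paste0("# R_inf_ohm: ", format(drt$R_inf, digits = 15)),
    paste0("# lambda_reg: ", format(drt$lambda_reg, digits = 15)),
    paste0("# residual_norm_ohm: ", format(drt$residual_norm, digits = 15)),
    paste0("# tau_inf_s: ", format(drt$grid$tau_inf, digits = 15)),
    paste0("# tau_sup_s: ", format(drt$grid$tau_sup, digits = 15)),
    paste0("# M: ", drt$grid$M))
  body <- paste(format(drt$grid$centers, digits = 15, scientific = TRUE),
                format(drt$weights, digits = 15, scientific = TRUE),
                sep = ",")
  tryCatch(
    writeLines(c(hdr, "tau_s,weight_ohm", body), path),
    error = function(e) stop("failed to write DRT to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' @rdname write_drt
#' @export
read_drt <- function(path) {
  if (!file.exists(path)) stop("DRT file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("DRT file ", path, " missing header '", key, "'")
    v <- trimws(sub(paste0("^# ", key, ": *"), "", ln[1]))
    if (v %in% c("NA", "NaN")) NA_real_ else as.numeric(v)
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (!all(c("tau_s", "weight_ohm") %in% names(df))) {
    stop("DRT file ", path, " must have columns tau_s, weight_ohm")
  }
  grid <- relaxation_grid(getv("tau_inf_s"), getv("tau_sup_s"), getv("M"))
  drt_result(grid, df$weight_ohm, R_inf = getv("R_inf_ohm"),
             lambda_reg = getv("lambda_reg"),
             residual_norm = getv("residual_norm_ohm"))
}
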