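#' Split a DRT into tissue and electrode parts
#'
#' In a 2-electrode measurement the electrode-polarization processes
#' (double layer / charge transfer, then ionic diffusion) relax much more
#' slowly than the tissue dispersions, so the DRT can be partitioned by a
#' relaxation-time threshold: mass at \eqn{\tau <} `tau_max` is tissue,
#' mass above is electrode. The cut is hard, at the bin boundary nearest
#' `tau_max`; the series resistance \eqn{R_\infty} is assigned wholly to
#' the tissue part.
#'
#' @param drt a [drt_result()].
#' @param tau_max split point in seconds; must lie inside the grid range.
#' @param method label recorded in the result: `"manual"` (default) or
#'   `"valley"` (when `tau_max` came from [suggest_tau_max()]).
#' @return Object of class `separation_result`: `tau_max`, `tissue_drt`,
#'   `electrode_drt` (complementary [drt_result()]s on the same grid),
#'   `tissue_R0` and `method`. The two parts reproduce the input weights
#'   bin by bin.
#' @export
split_drt <- function(drt, tau_max, method = c("manual", "valley")) {
  stopifnot(inherits(drt, "drt_result"))
  method <- match.arg(method)
  g <- drt$grid
  if (tau_max < g$tau_inf || tau_max > g$tau_sup) {
    stop("tau_max = ", tau_max, " s is outside the grid range [",
         g$tau_inf, ", ", g$tau_sup, "] s")
  }
  edges <- log(g$tau_inf) + (0:g$M) * g$bin_width_logtau
  cut_edge <- edges[which.min(abs(edges - log(tau_max)))]
  tissue_w <- ifelse(g$log_centers < cut_edge, drt$weights, 0)
  elec_w <- drt$weights - tissue_w
  tissue <- drt_result(g, tissue_w, R_inf = drt$R_inf,
                       lambda_reg = drt$lambda_reg)
  electrode <- drt_result(g, elec_w, R_inf = 0,
                          lambda_reg = drt$lambda_reg)
  structure(list(tau_max = tau_max, tissue_drt = tissue,
                 electrode_drt = electrode,
                 tissue_R0 = tissue$R_inf + tissue$R_p,
                 method = method),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("<separation_result> tau_max = ", format(x$tau_max, digits = 4),
      " s (", x$method, ")\n", sep = "")
  cat("  tissue:    R_0 = ", format(x$tissue_R0, digits = 5), " ohm (R_p = ",
      format(x$tissue_drt$R_p, digits = 5), ")\n", sep = "")
  cat("  electrode: R_p = ", format(x$electrode_drt$R_p, digits = 5),
      " ohm\n", sep = "")
  invisible(x)
}

#' Suggest a tissue/electrode split point
#'
#' Returns the relaxation time of the deepest interior local minimum of
#' the smoothed DRT curve inside a search window (the "valley" between
#' the tissue and electrode clusters). When the curve is monotone in the
#' window, the log-midpoint of the window is returned with a warning.
#'
#' @param drt a [drt_result()].
#' @param search_window `c(tau_lo, tau_hi)` in seconds, inside the grid.
#' @param smooth_bins moving-average width in bins (default 5).
#' @return split time in seconds.
#' @export
suggest_tau_max <- function(drt, search_window = c(1e-5, 1e-2),
                            smooth_bins = 5) {
  stopifnot(inherits(drt, "drt_result"), length(search_window) == 2)
  g <- drt$grid
  if (search_window[1] < g$tau_inf || search_window[2] > g$tau_sup) {
    stop("search window must lie inside the grid range")
  }
  y <- drt_curve(drt)
  ys <- as.numeric(stats::filter(y, rep(1 / smooth_bins, smooth_bins),
                                 sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  idx <- which(g$centers >= search_window[1] & g$centers <= search_window[2])
  if (length(idx) < 3) {
    warning("search window too narrow; returning its log-midpoint")
    return(exp(mean(log(search_window))))
  }
  yw <- ys[idx]
  n <- length(yw)
  interior <- 2:(n - 1)
  is_min <- yw[interior] <= yw[interior - 1] & yw[interior] <= yw[interior + 1]
  mins <- interior[is_min]
  if (!length(mins)) {
    warning("no interior minimum in the search window; ",
            "returning its log-midpoint")
    return(exp(mean(log(search_window))))
  }
  g$centers[idx[mins[which.min(yw[mins])]]]
}

#' Rescale a DRT by a geometry factor
#'
#' Multiplies all weights and \eqn{R_\infty} by a positive factor, e.g.
#' the empirical cell-constant correction that maps a 4-electrode DRT
#' onto a 2-electrode one. The grid is unchanged, and the reconstructed
#' impedance scales exactly linearly.
#'
#' @param drt a [drt_result()].
#' @param factor positive dimensionless factor.
#' @return a [drt_result()].
#' @export
geometry_rescale <- function(drt, factor) {
  stopifnot(inherits(drt, "drt_result"))
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  drt_result(drt$grid, drt$weights * factor, R_inf = drt$R_inf * factor,
             lambda_reg = drt$lambda_reg,
             residual_norm = drt$residual_norm)
}

#' Gaussian-model electrode removal
#'
#' Alternative to the hard cut of [split_drt()] for systems where the
#' electrode charge-transfer peak overlaps the tissue response: fit K
#' Gaussians to the full DRT, drop components with \eqn{\mu \ge}
#' `tau_max`, and rebuild the tissue DRT from the retained components.
#'
#' @param drt a [drt_result()].
#' @param tau_max threshold in seconds.
#' @param K total number of Gaussians fitted to the full DRT.
#' @param ... passed to [fit_gaussians()].
#' @return a `separation_result` whose `tissue_drt` is the Gaussian
#'   reconstruction (method `"gaussian"`); `electrode_drt` holds the
#'   complement of the input weights.
#' @export
split_drt_gaussian <- function(drt, tau_max, K, ...) {
  stopifnot(inherits(drt, "drt_result"))
  model <- fit_gaussians(drt, K, ...)
  keep <- model$components$mu < tau_max
  if (!any(keep)) stop("no component below tau_max = ", tau_max, " s")
  kept <- model
  kept$components <- model$components[keep, , drop = FALSE]
  kept$K <- sum(keep)
  kept$R_0 <- drt$R_inf + sum(kept$components$R_pk)
  g <- drt$grid
  tissue_w <- decomposition_curve(kept, g$log_centers) * g$bin_width_logtau
  tissue <- drt_result(g, tissue_w, R_inf = drt$R_inf,
                       lambda_reg = drt$lambda_reg)
  electrode <- drt_result(g, pmax(drt$weights - tissue_w, 0), R_inf = 0,
                          lambda_reg = drt$lambda_reg)
  structure(list(tau_max = tau_max, tissue_drt = tissue,
                 electrode_drt = electrode,
                 tissue_R0 = tissue$R_inf + tissue$R_p,
                 method = "gaussian", model = kept),
            class = "separation_result")
}
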