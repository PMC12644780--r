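#' Gaussian component of a DRT decomposition
#'
#' A single Gaussian in natural-log relaxation time, equivalently a
#' log-normal dispersion in tau:
#' \deqn{p(\tau) = \frac{a}{\tau} \exp\!\left(-\frac{\ln^2(\tau/\mu)}
#'   {2\sigma^2}\right),}
#' whose integral over tau (the component's DC-resistance contribution
#' when the fitted curve is \eqn{R_p G(x)}) is
#' \eqn{R_{pk} = a\,\sigma\sqrt{2\pi}}.
#'
#' @param a peak amplitude (ohms per natural-log-tau unit), positive.
#' @param mu location (mean relaxation time), seconds.
#' @param sigma spread in natural-log tau, positive.
#' @return list of class `gaussian_component` with `a`, `mu`, `sigma` and
#'   the derived `R_pk`.
#' @export
gaussian_component <- function(a, mu, sigma) {
  if (!(a > 0 && mu > 0 && sigma > 0)) stop("need a > 0, mu > 0, sigma > 0")
  structure(list(a = a, mu = mu, sigma = sigma,
                 R_pk = a * sigma * sqrt(2 * pi)),
            class = "gaussian_component")
}

# sum of K Gaussians in x = ln tau; theta = c(a, m = ln mu, s)
.gauss_sum <- function(theta, x, K) {
  a <- theta[seq_len(K)]
  m <- theta[K + seq_len(K)]
  s <- theta[2 * K + seq_len(K)]
  y <- numeric(length(x))
  for (k in seq_len(K)) {
    y <- y + a[k] * exp(-(x - m[k])^2 / (2 * s[k]^2))
  }
  y
}

# width estimate at a peak from the half-maximum crossings of a curve
.peak_width <- function(x, y, i) {
  half <- y[i] / 2
  lo <- i; while (lo > 1 && y[lo] > half) lo <- lo - 1
  hi <- i; while (hi < length(y) && y[hi] > half) hi <- hi + 1
  w <- (x[hi] - x[lo]) / 2.3548   # FWHM -> sd
  min(max(w, 0.1), 1.5)
}

# greedy init: peel off K Gaussians from the residual curve, largest
# residual peak first
.greedy_init <- function(x, y, K) {
  r <- y
  a0 <- m0 <- s0 <- numeric(K)
  for (k in seq_len(K)) {
    i <- which.max(r)
    a0[k] <- max(r[i], 1e-3 * max(y))
    m0[k] <- x[i]
    s0[k] <- .peak_width(x, pmax(r, 0), i)
    r <- r - a0[k] * exp(-(x - m0[k])^2 / (2 * s0[k]^2))
  }
  c(a0, m0, s0)
}

# initial parameter sets: greedy residual peeling, K largest local
# maxima, mass quantiles, and seed-jittered variants
.gauss_inits <- function(x, y, K, n_starts, dx) {
  inits <- list(.greedy_init(x, y, K))
  # (i) K largest local maxima of the (lightly smoothed) curve
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_peak <- c(FALSE, ys[2:(n - 1)] >= ys[1:(n - 2)] &
                 ys[2:(n - 1)] >= ys[3:n], FALSE)
  pk <- which(is_peak & ys > 0.005 * max(ys))
  if (length(pk) >= K) {
    pk <- pk[order(ys[pk], decreasing = TRUE)][seq_len(K)]
    m0 <- x[pk]
    s0 <- vapply(pk, function(i) .peak_width(x, ys, i), 1)
    inits[[length(inits) + 1]] <-
      c(pmax(ys[pk], 0.05 * max(ys)), m0, s0)
  }
  # (ii) quantiles of the cumulative mass
  cy <- cumsum(y)
  cy <- cy / cy[length(cy)]
  qs <- (seq_len(K) - 0.5) / K
  m0 <- vapply(qs, function(q) x[which.min(abs(cy - q))], 1)
  inits[[length(inits) + 1]] <-
    c(pmax(stats::approx(x, y, xout = m0, rule = 2)$y, 0.05 * max(y)),
      m0, rep(0.4, K))
  # jittered copies up to n_starts
  base_n <- length(inits)
  i <- 0
  while (length(inits) < n_starts) {
    i <- i + 1
    src <- inits[[(i - 1) %% base_n + 1]]
    th <- src
    th[K + seq_len(K)] <- th[K + seq_len(K)] + stats::rnorm(K, 0, 0.25)
    th[seq_len(K)] <- th[seq_len(K)] * exp(stats::rnorm(K, 0, 0.2))
    th[2 * K + seq_len(K)] <- pmin(pmax(th[2 * K + seq_len(K)] *
                                          exp(stats::rnorm(K, 0, 0.2)), 0.06), 2.9)
    inits[[length(inits) + 1]] <- th
  }
  inits
}

#' Fit a sum of Gaussians to a DRT curve
#'
#' Least-squares fit of \eqn{\sum_k a_k \exp(-(x - \ln\mu_k)^2 /
#' (2\sigma_k^2))} to the per-bin curve \eqn{R_p G(x) = w_j/\Delta x} on
#' the (optionally tau-windowed) grid, by bounded Levenberg-Marquardt
#' with multi-start initialization (largest local maxima and cumulative
#' mass quantiles, plus seed-controlled jitter; best residual wins).
#'
#' @param drt a [drt_result()].
#' @param K number of Gaussian components, >= 1.
#' @param tau_window optional `c(tau_lo, tau_hi)` in seconds restricting
#'   the bins entering the fit.
#' @param n_starts multi-start budget (default 6).
#' @param seed optional integer controlling the start jitter; the fit is
#'   deterministic given a seed.
#' @return Object of class `decomposition_model`: a data frame
#'   `components` (columns `a`, `mu`, `sigma`, `R_pk`) ordered by
#'   decreasing `mu`, plus `R_inf`, `R_0 = R_inf + sum(R_pk)`, `K`,
#'   `rss` (residual sum of squares on the fitted curve) and `n` (number
#'   of tau bins in the fit).
#' @export
fit_gaussians <- function(drt, K, tau_window = NULL, n_starts = 6,
                          seed = NULL) {
  stopifnot(inherits(drt, "drt_result"), K >= 1)
  x <- drt$grid$log_centers
  y <- drt_curve(drt)
  if (!is.null(tau_window)) {
    stopifnot(length(tau_window) == 2, tau_window[1] < tau_window[2])
    keep <- drt$grid$centers >= tau_window[1] &
      drt$grid$centers <= tau_window[2]
    x <- x[keep]
    y <- y[keep]
  }
  n <- length(x)
  support <- sum(y > 1e-9 * max(max(y), 1e-300))
  if (max(y) <= 0 || support < 3 * K + 1) {
    stop("insufficient mass support for K = ", K,
         " Gaussians (need at least ", 3 * K + 1,
         " bins with nonzero mass, have ", support, ")")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lower <- c(rep(0, K), rep(min(x), K), rep(0.05, K))
  upper <- c(rep(Inf, K), rep(max(x), K), rep(3, K))
  resid_fn <- function(theta) y - .gauss_sum(theta, x, K)
  inits <- .gauss_inits(x, y, K, n_starts, drt$grid$bin_width_logtau)
  best <- NULL
  for (th0 in inits) {
    th0 <- pmin(pmax(th0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    stop("Gaussian fit failed to converge for K = ", K,
         " after ", length(inits), " starts")
  }
  th <- best$par
  a <- th[seq_len(K)]
  m <- th[K + seq_len(K)]
  s <- th[2 * K + seq_len(K)]
  ord <- order(m, decreasing = TRUE)   # mu_1 > mu_2 > ... > mu_K
  comps <- data.frame(a = a[ord], mu = exp(m[ord]), sigma = s[ord])
  comps$R_pk <- comps$a * comps$sigma * sqrt(2 * pi)
  structure(list(components = comps, R_inf = drt$R_inf,
                 R_0 = drt$R_inf + sum(comps$R_pk), K = as.integer(K),
                 rss = best$rss, n = n,
                 tau_window = tau_window),
            class = "decomposition_model")
}

#' @export
print.decomposition_model <- function(x, ...) {
  cat("<decomposition_model> K=", x$K, " Gaussians, n=", x$n, " bins, rss=",
      format(x$rss, digits = 4), "\n", sep = "")
  cat("  R_inf = ", format(x$R_inf, digits = 5), " ohm, R_0 = ",
      format(x$R_0, digits = 5), " ohm\n", sep = "")
  df <- x$components
  df$mu <- signif(df$mu, 4)
  df$a <- signif(df$a, 4)
  df$sigma <- signif(df$sigma, 3)
  df$R_pk <- signif(df$R_pk, 4)
  print(df, row.names = TRUE)
  invisible(x)
}

#' Component DC-resistance contributions
#'
#' Recomputes \eqn{R_{pk} = a_k \sigma_k \sqrt{2\pi}} for each component
#' and the total DC resistance \eqn{R_0 = R_\infty + \sum_k R_{pk}}.
#'
#' @param model a [fit_gaussians()] result.
#' @return list with `R_pk` (vector, ordered as the components) and `R_0`.
#' @export
component_resistances <- function(model) {
  stopifnot(inherits(model, "decomposition_model"))
  R_pk <- model$components$a * model$components$sigma * sqrt(2 * pi)
  list(R_pk = R_pk, R_0 = model$R_inf + sum(R_pk))
}

#' Evaluate the Gaussian-sum curve of a decomposition
#'
#' @param model a [fit_gaussians()] result.
#' @param x natural-log-tau values.
#' @return curve values (ohms per natural-log-tau unit).
#' @export
decomposition_curve <- function(model, x) {
  stopifnot(inherits(model, "decomposition_model"))
  c_ <- model$components
  .gauss_sum(c(c_$a, log(c_$mu), c_$sigma), x, nrow(c_))
}

#' Impedance of a Gaussian decomposition
#'
#' Forward evaluation of the log-normal mixture model,
#' \eqn{Z(\omega) = R_\infty + \sum_k \int p_k(\tau)/(1+j\omega\tau)
#' \,d\tau}, by adaptive quadrature on the log-tau axis. At
#' \eqn{\omega = 0} this reproduces \eqn{R_0} (DC additivity).
#'
#' @param model a [fit_gaussians()] result.
#' @param frequencies Hz (zero allowed).
#' @return an `impedance_spectrum`.
#' @export
decomposition_impedance <- function(model, frequencies) {
  stopifnot(inherits(model, "decomposition_model"))
  w <- 2 * pi * frequencies
  c_ <- model$components
  z <- vapply(w, function(wi) {
    tot <- 0 + 0i
    for (k in seq_len(nrow(c_))) {
      m <- log(c_$mu[k]); s <- c_$sigma[k]; a <- c_$a[k]
      re <- stats::integrate(function(x)
        a * exp(-(x - m)^2 / (2 * s^2)) / (1 + (wi * exp(x))^2),
        m - 12 * s, m + 12 * s, rel.tol = 1e-9)$value
      im <- if (wi == 0) 0 else stats::integrate(function(x)
        -a * exp(-(x - m)^2 / (2 * s^2)) * wi * exp(x) / (1 + (wi * exp(x))^2),
        m - 12 * s, m + 12 * s, rel.tol = 1e-9)$value
      tot <- tot + complex(real = re, imaginary = im)
    }
    tot
  }, complex(1))
  structure(list(frequencies = frequencies, impedance = model$R_inf + z,
                 meta = list(model = "gaussian_mixture")),
            class = "impedance_spectrum")
}

#' F-test for one additional Gaussian component
#'
#' \deqn{F = \frac{RSS_{k-1} - RSS_k}{RSS_k} \times \frac{n - 3k - 1}{3},}
#' with n the number of tau bins entering the fit and 3 parameters
#' (amplitude, mean, spread) per Gaussian. The p-value is the upper tail
#' of the F distribution with (3, n - 3k - 1) degrees of freedom.
#'
#' @param rss_km1 residual sum of squares of the (k-1)-component model.
#' @param rss_k residual sum of squares of the k-component model
#'   (`rss_km1 >= rss_k > 0`).
#' @param n number of tau bins in the fit; must exceed `3k + 1`.
#' @param k component count of the larger model.
#' @return list of class `ftest_report`: `k`, `F`, `df1` (= 3), `df2`
#'   (= n - 3k - 1), `p_value`, `rss_km1`, `rss_k`.
#' @export
f_test <- function(rss_km1, rss_k, n, k) {
  if (rss_k <= 0) stop("rss_k must be positive (perfect fit: F undefined)")
  if (rss_km1 < rss_k) stop("rss_km1 must be >= rss_k")
  df2 <- n - 3 * k - 1
  if (df2 < 1) stop("degrees of freedom n - 3k - 1 = ", df2, " < 1")
  F <- (rss_km1 - rss_k) / rss_k * df2 / 3
  structure(list(k = as.integer(k), F = F, df1 = 3L, df2 = df2,
                 p_value = stats::pf(F, 3, df2, lower.tail = FALSE),
                 rss_km1 = rss_km1, rss_k = rss_k),
            class = "ftest_report")
}

#' @export
print.ftest_report <- function(x, ...) {
  cat(sprintf("<ftest_report> k=%d  F=%.3g  df=(%d,%d)  p=%.4g\n",
              x$k, x$F, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' Select the number of Gaussian components
#'
#' Fits each K in `K_range`, computes the full-range F sequence and a
#' tail-restricted F sequence (residuals recomputed on the bins with
#' \eqn{\tau <} `tail_cutoff`, with n replaced by the tail bin count),
#' and chooses the smallest K whose increment to K+1 has tail p-value
#' above `p_threshold` (i.e. the extra component adds nothing
#' significant to the short-time tail). Falls back to the largest K
#' with a warning when every increment is significant.
#'
#' @param drt a [drt_result()].
#' @param K_range contiguous ascending integer range of candidate K.
#' @param p_threshold significance threshold (default 0.05).
#' @param tail_cutoff tail window upper bound in seconds (default 6e-6).
#' @param tau_window optional fit window passed to [fit_gaussians()].
#' @param n_starts,seed passed to [fit_gaussians()].
#' @return list with `K` (chosen), `reports` (full-range
#'   [f_test()] reports), `tail_reports`, and `fits` (the fitted models,
#'   named by K).
#' @export
select_K <- function(drt, K_range, p_threshold = 0.05, tail_cutoff = 6e-6,
                     tau_window = NULL, n_starts = 6, seed = NULL) {
  stopifnot(inherits(drt, "drt_result"))
  K_range <- sort(unique(as.integer(K_range)))
  if (any(diff(K_range) != 1)) stop("K_range must be contiguous ascending")
  if (tail_cutoff <= drt$grid$tau_inf) {
    stop("tail window is empty: tail_cutoff <= grid tau_inf")
  }
  x_all <- drt$grid$log_centers
  y_all <- drt_curve(drt)
  keep <- rep(TRUE, length(x_all))
  if (!is.null(tau_window)) {
    keep <- drt$grid$centers >= tau_window[1] &
      drt$grid$centers <= tau_window[2]
  }
  x <- x_all[keep]
  y <- y_all[keep]
  in_tail <- exp(x) < tail_cutoff
  n_tail <- sum(in_tail)
  if (n_tail == 0) stop("tail window contains no bins of the fit window")
  fits <- list()
  rss_full <- rss_tail <- numeric(0)
  for (K in K_range) {
    fit <- fit_gaussians(drt, K, tau_window = tau_window,
                         n_starts = n_starts,
                         seed = if (is.null(seed)) NULL else seed + K)
    fits[[as.character(K)]] <- fit
    res <- y - decomposition_curve(fit, x)
    rss_full <- c(rss_full, sum(res^2))
    rss_tail <- c(rss_tail, sum(res[in_tail]^2))
  }
  n_full <- length(x)
  mk_reports <- function(rss, n) {
    reps <- list()
    for (i in seq_along(K_range)[-1]) {
      reps[[length(reps) + 1]] <- tryCatch(
        f_test(max(rss[i - 1], rss[i]), rss[i], n, K_range[i]),
        error = function(e) NULL)
    }
    reps
  }
  reports <- mk_reports(rss_full, n_full)
  tail_reports <- mk_reports(rss_tail, n_tail)
  chosen <- NA_integer_
  for (i in seq_along(tail_reports)) {
    rep_i <- tail_reports[[i]]
    if (!is.null(rep_i) && rep_i$p_value > p_threshold) {
      chosen <- rep_i$k - 1L   # increment K -> K+1 is insignificant
      break
    }
  }
  if (is.na(chosen)) {
    warning("every increment in K_range is significant; returning max K")
    chosen <- K_range[length(K_range)]
  }
  list(K = chosen, reports = reports, tail_reports = tail_reports,
       fits = fits)
}

#' Write / read a decomposition as JSON
#'
#' Fields: `components` (array of `{a, mu_s, sigma, R_pk}`), `R_inf`,
#' `R_0`, plus `rss` and `n` for provenance.
#'
#' @param model a [fit_gaussians()] result.
#' @param path JSON path.
#' @return `path` invisibly (`write_decomposition`); a
#'   `decomposition_model` (`read_decomposition`).
#' @export
write_decomposition <- function(model, path) {
  stopifnot(inherits(model, "decomposition_model"))
  c_ <- model$components
  obj <- list(
    components = lapply(seq_len(nrow(c_)), function(k)
      list(a = c_$a[k], mu_s = c_$mu[k], sigma = c_$sigma[k],
           R_pk = c_$R_pk[k])),
    R_inf = model$R_inf, R_0 = model$R_0, rss = model$rss, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) stop("decomposition file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  c_ <- as.data.frame(obj$components)
  comps <- data.frame(a = c_$a, mu = c_$mu_s, sigma = c_$sigma,
                      R_pk = c_$R_pk)
  structure(list(components = comps, R_inf = obj$R_inf,
                 R_0 = obj$R_inf + sum(comps$R_pk), K = nrow(comps),
                 rss = obj$rss, n = obj$n, tau_window = NULL),
            class = "decomposition_model")
}
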