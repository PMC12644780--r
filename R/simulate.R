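#' Tissue spectrum model
#'
#' Parameterization of a synthetic 2-electrode tissue measurement: a
#' high-frequency series resistance, a set of tissue dispersion elements
#' (alpha, beta, starch, organelle), electrode contributions
#' (charge-transfer RQ element and a slow diffusion element), and
#' multiplicative Gaussian measurement noise.
#'
#' @param R_inf series resistance, ohms (>= 0).
#' @param tissue_elements list of [dispersion_element] objects.
#' @param electrode_elements list of [dispersion_element] objects
#'   (relaxing more slowly than the tissue set in a physical model).
#' @param noise_sigma relative standard deviation of the multiplicative
#'   Gaussian noise applied independently to the real and imaginary
#'   parts (>= 0).
#' @param seed integer seed used by [generate_spectrum()] when
#'   `noise_sigma > 0`.
#' @return list of class `tissue_model`.
#' @export
tissue_model <- function(R_inf, tissue_elements, electrode_elements = list(),
                         noise_sigma = 0, seed = NULL) {
  stopifnot(R_inf >= 0, noise_sigma >= 0)
  stopifnot(all(vapply(tissue_elements, inherits, TRUE, "dispersion_element")),
            all(vapply(electrode_elements, inherits, TRUE, "dispersion_element")))
  structure(list(R_inf = R_inf, tissue_elements = tissue_elements,
                 electrode_elements = electrode_elements,
                 noise_sigma = noise_sigma, seed = seed),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model> R_inf=", format(x$R_inf, digits = 4), " ohm, ",
      length(x$tissue_elements), " tissue + ",
      length(x$electrode_elements), " electrode elements, noise=",
      x$noise_sigma, "\n", sep = "")
  for (el in c(x$tissue_elements, x$electrode_elements)) print(el)
  invisible(x)
}

#' Synthetic potato-tissue preset
#'
#' A 6-dispersion tissue model emulating a flat-brass 2-electrode
#' measurement of potato parenchyma: an alpha dispersion (counterion
#' cloud) near 3e-4 s, three beta (membrane polarization) modes near
#' 2e-5, 6e-6 and 2e-6 s — the spread reflecting variable cell size and
#' starch content — a starch-granule dispersion near 4e-7 s and an
#' organelle (nucleus) mode near 2e-7 s, with DC contributions matching
#' typical per-compartment resistances at a ~1 kOhm sample. Electrode
#' polarization is a charge-transfer RQ element near 5e-3 s plus a slow
#' finite-length diffusion element, both well above the 6e-4 s
#' tissue/electrode threshold.
#'
#' @param noise_sigma relative measurement noise (default 0.005).
#' @param seed integer seed for [generate_spectrum()].
#' @return a [tissue_model()].
#' @export
potato_model <- function(noise_sigma = 0.005, seed = NULL) {
  tissue_model(
    R_inf = 150,
    tissue_elements = list(
      lognormal_element(39, mu = 3e-4, sigma = 0.35, label = "alpha"),
      lognormal_element(221, mu = 2.5e-5, sigma = 0.30, label = "beta1"),
      lognormal_element(270, mu = 6e-6, sigma = 0.25, label = "beta2"),
      lognormal_element(266, mu = 1.6e-6, sigma = 0.25, label = "beta3"),
      lognormal_element(139, mu = 4e-7, sigma = 0.20, label = "starch"),
      lognormal_element(26, mu = 1.5e-7, sigma = 0.15, label = "nucleus")),
    electrode_elements = list(
      rq_element(400, q = 0.9, tau0 = 8e-3, label = "electrode_ct"),
      warburg_element(800, tau_d = 5, label = "electrode_diff")),
    noise_sigma = noise_sigma, seed = seed)
}

#' Ground-truth table of a tissue model
#'
#' @param model a [tissue_model()].
#' @param part `"tissue"` or `"electrode"`.
#' @return data.frame with columns `label`, `kind`, `R` and (for
#'   log-normal elements) `mu`, `sigma`.
#' @export
tissue_truth <- function(model, part = c("tissue", "electrode")) {
  part <- match.arg(part)
  els <- if (part == "tissue") model$tissue_elements else model$electrode_elements
  do.call(rbind, lapply(els, function(el) {
    data.frame(label = if (is.null(el$label)) NA_character_ else el$label,
               kind = el$kind, R = el$R,
               mu = if (!is.null(el$mu)) el$mu else NA_real_,
               sigma = if (!is.null(el$sigma)) el$sigma else NA_real_)
  }))
}

#' Generate a synthetic impedance spectrum
#'
#' Sums the element impedances and the series resistance, then applies
#' independent multiplicative Gaussian noise to the real and imaginary
#' parts: \eqn{Re' = Re\,(1+\epsilon_1)}, \eqn{Im' = Im\,(1+\epsilon_2)},
#' \eqn{\epsilon \sim N(0, \sigma)}. Reproducible per seed.
#'
#' @param model a [tissue_model()].
#' @param frequencies Hz (default: 300 log-spaced points, 20 Hz-400 kHz).
#' @param seed overrides `model$seed`.
#' @return an [impedance_spectrum()] with the model's noise level and
#'   seed recorded in `meta`.
#' @export
generate_spectrum <- function(model, frequencies = default_frequencies(),
                              seed = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  z <- rep(complex(real = model$R_inf), length(frequencies))
  for (el in c(model$tissue_elements, model$electrode_elements)) {
    z <- z + element_impedance(el, frequencies)
  }
  if (model$noise_sigma > 0) {
    seed <- if (is.null(seed)) model$seed else seed
    if (is.null(seed)) stop("a seed is required when noise_sigma > 0")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    n <- length(z)
    z <- complex(real = Re(z) * (1 + stats::rnorm(n, 0, model$noise_sigma)),
                 imaginary = Im(z) * (1 + stats::rnorm(n, 0, model$noise_sigma)))
  }
  impedance_spectrum(frequencies, z,
                     meta = list(synthetic = TRUE,
                                 noise_sigma = model$noise_sigma,
                                 seed = seed))
}

# apply multiplicative jitter / effect multipliers to a model's tissue
# elements; mults: named list(R = named vector, mu = named vector) keyed
# by element label (vector name "beta" matches beta1/beta2/beta3 etc.)
.apply_multipliers <- function(model, R_mult = NULL, mu_mult = NULL) {
  lookup <- function(tbl, label) {
    if (is.null(tbl) || is.null(label)) return(1)
    if (label %in% names(tbl)) return(tbl[[label]])
    pref <- names(tbl)[vapply(names(tbl), function(nm)
      startsWith(label, nm), TRUE)]
    if (length(pref)) tbl[[pref[1]]] else 1
  }
  model$tissue_elements <- lapply(model$tissue_elements, function(el) {
    el$R <- el$R * lookup(R_mult, el$label)
    if (!is.null(el$mu)) el$mu <- el$mu * lookup(mu_mult, el$label)
    el
  })
  model
}

#' Electroporation effect profiles
#'
#' Per-field-level multipliers on tissue element parameters used by
#' [generate_ep_dataset()]. A profile is a named list keyed by field
#' level (V/cm, as character) whose entries hold `R_mult` and `mu_mult`,
#' named vectors of multiplicative factors keyed by element label;
#' a name that is a prefix (e.g. `"beta"`) matches `beta1`, `beta2`, ...
#'
#' `ep_profile_reversible()` shifts the beta relaxation times
#' (`mu_mult = exp(-0.4)` by default) while leaving every R — hence the
#' DC resistance — unchanged. `ep_profile_irreversible()` shrinks the
#' beta, alpha and starch resistances (default to 0.3 of baseline),
#' the signature of permanent membrane permeabilization.
#'
#' @param field_levels numeric vector of field amplitudes, V/cm.
#' @param mu_factor multiplicative shift of beta time constants.
#' @param R_factor multiplicative shrink of alpha/beta/starch R.
#' @return a named list usable as `effect_profile`.
#' @export
ep_profile_reversible <- function(field_levels, mu_factor = exp(-0.4)) {
  prof <- lapply(field_levels, function(f)
    list(R_mult = NULL, mu_mult = c(beta = mu_factor)))
  names(prof) <- as.character(field_levels)
  prof
}

#' @rdname ep_profile_reversible
#' @export
ep_profile_irreversible <- function(field_levels, R_factor = 0.3) {
  prof <- lapply(field_levels, function(f)
    list(R_mult = c(alpha = R_factor, beta = R_factor, starch = R_factor),
         mu_mult = NULL))
  names(prof) <- as.character(field_levels)
  prof
}

#' @rdname ep_profile_reversible
#' @export
ep_profile_null <- function(field_levels) {
  prof <- lapply(field_levels, function(f) list(R_mult = NULL, mu_mult = NULL))
  names(prof) <- as.character(field_levels)
  prof
}

#' Generate a paired pre/post electroporation dataset
#'
#' Emulates a field-sweep experiment: for each field level and
#' replicate, the baseline model's tissue parameters are jittered
#' multiplicatively (log-normal, coefficient of variation `jitter_cv`)
#' to emulate sample heterogeneity, a pre-electroporation spectrum is
#' emitted, the level's effect multipliers are applied, and a
#' post-electroporation spectrum is emitted.
#'
#' @param baseline a [tissue_model()].
#' @param field_levels V/cm.
#' @param replicates samples per level.
#' @param effect_profile per-level multipliers; see
#'   [ep_profile_reversible()]. Must cover every level.
#' @param seed integer; drives jitter and both noise draws.
#' @param jitter_cv relative sample-to-sample spread (default 0.1).
#' @param frequencies acquisition grid, Hz.
#' @return list of records, each with `field`, `replicate`, `pre`,
#'   `post` ([impedance_spectrum()]s) and `truth` (pre/post ground-truth
#'   tables from [tissue_truth()]).
#' @export
generate_ep_dataset <- function(baseline, field_levels, replicates = 3,
                                effect_profile, seed = 1, jitter_cv = 0.1,
                                frequencies = default_frequencies()) {
  stopifnot(inherits(baseline, "tissue_model"))
  missing_lv <- setdiff(as.character(field_levels), names(effect_profile))
  if (length(missing_lv)) {
    stop("effect_profile missing levels: ", paste(missing_lv, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  out <- list()
  for (lv in field_levels) {
    eff <- effect_profile[[as.character(lv)]]
    for (rep_i in seq_len(replicates)) {
      m_pre <- baseline
      m_pre$tissue_elements <- lapply(baseline$tissue_elements, function(el) {
        el$R <- el$R * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        if (!is.null(el$mu)) el$mu <- el$mu * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        el
      })
      m_post <- .apply_multipliers(m_pre, eff$R_mult, eff$mu_mult)
      seed_pre <- sample.int(.Machine$integer.max, 1)
      seed_post <- sample.int(.Machine$integer.max, 1)
      pre <- generate_spectrum(m_pre, frequencies, seed = seed_pre)
      post <- generate_spectrum(m_post, frequencies, seed = seed_post)
      pre$meta$field <- lv; pre$meta$phase <- "pre"
      post$meta$field <- lv; post$meta$phase <- "post"
      out[[length(out) + 1]] <- list(
        field = lv, replicate = rep_i, pre = pre, post = post,
        truth = list(pre = tissue_truth(m_pre), post = tissue_truth(m_post)))
    }
  }
  out
}
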