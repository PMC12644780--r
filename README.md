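# tissuedrt

Distribution-of-relaxation-times (DRT) analysis of tissue impedance
spectra, for monitoring electroporation.

Electrical impedance spectroscopy of biological tissue measures a complex
impedance $Z(\omega)$ over a frequency sweep. Interpreting it directly in
the frequency domain is hard: the membrane ($\beta$) dispersion overlaps the
counterion ($\alpha$) dispersion, and in a 2-electrode setup everything sits
on top of electrode polarization. This package analyzes the same data on a
time scale instead, representing the spectrum as a continuum of first-order
relaxations,

$$Z(\omega) = R_\infty + R_p \int_0^\infty \frac{g(\tau)}{1+j\omega\tau}\,d\tau,
\qquad \int g \,d\tau = 1 .$$

On the $\ln\tau$ axis ($G(x) = \tau g(\tau)$), electrode processes appear
well above the tissue processes and can be removed with a simple
relaxation-time threshold; the tissue part decomposes into Gaussian
components in $\ln\tau$ (log-normal dispersions in $\tau$), one per tissue
compartment (counterion cloud, cell membranes with varying starch content,
starch granules, nuclei), each contributing
$R_{pk} = a_k \sigma_k \sqrt{2\pi}$ to the DC resistance
$R_0 = R_\infty + \sum_k R_{pk}$. Tracking the $R_{pk}$ across an
electroporation field sweep distinguishes reversible permeabilization
(DC resistance conserved, distribution deformed) from irreversible damage
(DC resistance collapses).

The package provides:

- `solve_drt()` — Tikhonov-regularized nonnegative inversion (M step
  functions on a log grid, first-difference smoothness penalty, joint
  real/imaginary fit, $R_\infty$ estimated as a free column), plus
  `reconstruct_impedance()` and GCV-based `tune_lambda()`;
- `split_drt()` / `suggest_tau_max()` / `geometry_rescale()` — electrode
  polarization removal and cross-geometry comparison;
- `fit_gaussians()`, `select_K()` (incremental F-test, full-range and
  tail-restricted), `component_resistances()` — compartment decomposition;
- `potato_model()`, `generate_spectrum()`, `generate_ep_dataset()` — a
  forward simulator (Debye, Cole-Cole/RQ, log-normal and finite-Warburg
  elements) with analytic Cole-Cole DRT oracle (`cole_cole_drt()`) and
  cell-scale time-constant formulas;
- `compare_pair()` / `field_sweep()` — pre/post electroporation comparison,
  reversibility calls and threshold estimates;
- `pulse_protocol()` and friends — thermal sanity checks for pulse trains;
- a thin CLI at `inst/cli/tissuedrt.R`
  (`drt | decompose | separate | simulate | compare | thermal`).

## Worked example

Simulate a noisy 2-electrode potato-tissue spectrum, invert it, strip the
electrode contribution, and decompose the tissue DRT:

```r
library(tissuedrt)

model <- potato_model(noise_sigma = 0.005, seed = 42)
spec  <- generate_spectrum(model)          # 300 pts, 20 Hz - 400 kHz
drt   <- solve_drt(spec)                   # M = 120, lambda = 0.1
#> solve_drt: N=300 M=120 lambda=0.1 residual=81.91 R_inf=146.4 R_p=1413

sep <- split_drt(drt, tau_max = 6e-4)      # tissue vs electrode
sep
#> <separation_result> tau_max = 6e-04 s (manual)
#>   tissue:    R_0 = 1119.1 ohm (R_p = 972.71)
#>   electrode: R_p = 440.78 ohm

fit_gaussians(sep$tissue_drt, K = 6, tau_window = c(1e-7, 6e-4), seed = 1)
#> <decomposition_model> K=6 Gaussians, n=82 bins, rss=372.2
#>   R_inf = 146.37 ohm, R_0 = 1123.7 ohm
#>        a        mu sigma   R_pk
#> 1  67.20 2.947e-04 0.263  44.23
#> 2  95.98 3.525e-05 0.216  51.97
#> 3 182.20 2.398e-05 0.321 146.70
#> 4 244.20 6.391e-06 0.473 289.80
#> 5 238.40 1.602e-06 0.479 286.00
#> 6 114.70 3.254e-07 0.552 158.60
```

The true tissue DC resistance of this model is 1111 Ω ($R_\infty$ = 150 Ω
plus 961 Ω of tissue dispersion); the pipeline recovers 1119 Ω with the
440-Ω electrode contribution cleanly separated. The six rows are the
compartment contributions ordered from slowest (counterion cloud,
$\mu \approx 3\times10^{-4}$ s) to fastest; their $R_{pk}$ sum with
$R_\infty$ to the tissue $R_0$. Note that neighbouring components exchange
some mass through the regularized inversion — global quantities are
recovered within ~1%, individual small components less precisely (see the
methods vignette, "Resolution limits").

Classify an electroporation pulse outcome from a simulated pre/post pair:

```r
ds  <- generate_ep_dataset(potato_model(0.005), 100, 1,
                           ep_profile_reversible(100), seed = 11)
cmp <- compare_pair(ds[[1]]$pre, ds[[1]]$post, seed = 11)
cmp$call
#> [1] "reversible"
round(cmp$delta_R0_ratio, 3)
#> [1] 1.002
```

Thermal sanity check for a standard 8 × 100 µs pulse train at 450 V / 12 A
on a 10 mm × 4.5 mm sample:

```r
p <- pulse_protocol(U = 450, I = 12, n_pulses = 8, pulse_duration = 100e-6)
s <- sample_thermal()
absorbed_energy(p)                         # 4.32 J
adiabatic_rise(absorbed_energy(p), heat_capacity(s))   # 3.05 K (upper bound)
diffusion_time(s$height / 2, s)            # 36.9 s
```

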