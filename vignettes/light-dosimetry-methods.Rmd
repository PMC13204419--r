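---
title: "Diffusion-model light dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-model light dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodose)
```

`photodose` implements the computation chain behind a wearable two-distance
diffuse-reflectance probe for phototherapy dosimetry: it turns surface
optical measurements into an estimate of the tissue's effective attenuation
coefficient, turns that coefficient into a relative map of the light dose
inside the tissue, monitors regional oxygen saturation as a dynamic sanity
check of the underlying optical model, and converts the probe's surface
temperature reading into a depth-resolved temperature prediction. This
vignette explains each model, its assumptions, the tunable parameters, the
numerical choices, and what the bundled simulator does and does not emulate.

## 1. Forward model and attenuation inversion

Light propagation in strongly scattering tissue is modeled by the
steady-state diffusion approximation in a homogeneous semi-infinite medium.
The detected radiant flux at source-detector distance $r$ is

$$R(r) \;=\; \frac{3}{2\pi r^2}\Big(1+\tfrac{2}{3}A\Big)\,
\mu_a\,\mu_s'\,e^{-\mu_{\mathrm{eff}}\,r},
\qquad \mu_{\mathrm{eff}} = \sqrt{3\,\mu_a\,\mu_s'},$$

with $\mu_a$ the absorption coefficient (mm$^{-1}$), $\mu_s'$ the reduced
scattering coefficient (mm$^{-1}$) and $A$ an internal-reflection boundary
factor. Units are fixed package-wide: mm, mm$^{-1}$, °C, seconds.

Taking the ratio of readings at two distances $r_1 < r_2$ cancels the
prefactor (including $A$ and any common detector gain) and gives the
closed-form inversion implemented by `invert_mu_eff()`:

$$\mu_{\mathrm{eff}} \;=\;
\frac{\ln\!\big(R_1 r_1^2/(R_2 r_2^2)\big)}{r_2-r_1}.$$

**Geometry presets.** Two detector placements are supported: a nominal
4 / 20 mm layout and the as-built 4.2 / 20.1 mm layout. Both are
available through `probe_geometry_preset()`; the as-built values are
the default because they are the ones the validity analysis (distance in
transport mean free paths) was carried out with. At $\mu_a = 0.01$,
$\mu_s' = 1.41/1.23/1.13$ mm$^{-1}$ (forearm skin at 730/810/855 nm) the
transport mean free path `transport_mfp()` is 0.704/0.806/0.877 mm, so the
4.2 mm near distance is 6.0/5.2/4.78 transport mean free paths — at the
edge of the classical >5 MTF validity requirement for the longest
wavelength. `distance_in_mfp()` offers both rounding and truncation
reporting because both conventions occur when such multiples are quoted.

**boundary_A.** Defaults to 1 (matched boundary). Every quantity the
pipeline consumes downstream is a ratio in which $A$ cancels exactly, so
its value only affects the simulator's absolute flux scale.

**Negative inversions.** Noise can make $R_1 r_1^2 < R_2 r_2^2$,
yielding a negative $\mu_{\mathrm{eff}}$. Batch streams should not abort
on a single bad frame, so the value is returned with a warning and a
`"flagged"` attribute instead of an error.

## 2. Relative internal fluence

For an isotropic point source the Taylor-expanded internal fluence rate is

$$\Phi(r,z) \approx \frac{P}{4\pi D}\,2(z_0+2AD)\,
\frac{z}{R^3}\,(1+\mu_{\mathrm{eff}}R)\,e^{-\mu_{\mathrm{eff}}R},
\qquad R=\sqrt{r^2+z^2},$$

valid when $z_0 \ll r$ or $z_0 \ll z$ ($z_0 = 1/\mu_s'$, $D =
1/[3(\mu_a+\mu_s')]$). The package's central dosimetry quantity is the
*ratio* of two such evaluations (`relative_fluence()`): $P$, $D$, $A$ and
$z_0$ all cancel, leaving a function of $\mu_{\mathrm{eff}}$ and geometry
only. That is exactly what makes a wearable feasible — one measured surface
coefficient determines the whole relative dose field.

Design choices that were genuinely open:

* **Reference point** (0, 1) mm: a shallow on-axis point directly beneath
  the source; `fluence_map()` snaps it to the nearest grid node so the
  reference cell is exactly 1.
* **Surface profiles at `z_eps` = 0.1 mm**: the expanded formula gives
  $\Phi(r,0)=0$ identically, so a literal surface slice is all zeros. The
  $z$ factor is constant along any fixed-depth slice, so the shape in $r$
  is independent of the choice of `z_eps`; 0.1 mm (one grid step) was
  fixed once and not revisited.
* **Grid extent** $r \in [-10, 10]$, $z \in [0, 10]$ mm at 0.1 mm step:
  chosen to cover the probe's sensitive volume; the extent is a
  configuration choice, not a physical constant.
* **log10 display floor** at $10^{-12}$ keeps the zero-valued surface row
  plottable.
* **Profile agreement metric**: max-normalized surface profiles for
  different subjects are compared by the maximum absolute difference in
  normalized units. Because the profile falls as $(z_\epsilon/R)^3$, the
  curves agree to well under 2% of peak for $r \le 5$ mm for the whole
  measured range of attenuation coefficients, while pointwise ordering
  (higher $\mu_{\mathrm{eff}}$ → lower intensity) holds strictly beyond
  5 mm — the behavior the model predicts for subjects with different attenuation.

## 3. Two-wavelength oximetry

The optical density $OD = -\log_{10} R(r)$ has radial derivative
$\partial OD/\partial r = (1/\ln 10)\,(\mu_{\mathrm{eff}} + 2/r)$.
Replacing the derivative by the finite difference between the two
detectors and removing the geometric $2/r$ term gives the
absorption-coefficient ratio between the two LED wavelengths
(`absorption_ratio()`):

$$\kappa \;=\; \frac{\mu_a(\lambda_1)}{\mu_a(\lambda_2)} \;=\;
\left[\frac{\Delta OD_{\lambda_1}-2\Delta r/(r\ln 10)}
{\Delta OD_{\lambda_2}-2\Delta r/(r\ln 10)}\right]^2,$$

valid under the assumption $\mu_s'(\lambda_1)=\mu_s'(\lambda_2)$. The
saturation then solves the two-chromophore mixture equation
(`rso2_from_ratio()`), mapping the pure-oxyhemoglobin and
pure-deoxyhemoglobin extinction ratios to exactly 1 and 0.

**Choice of $r$ in the $2/r$ term.** The finite-difference formula leaves
$r$ unspecified. We use the *logarithmic mean* $(r_2-r_1)/\ln(r_2/r_1)$
(10.15 mm for the as-built geometry): the OD difference contributed by the
$1/r^2$ prefactor is exactly $2\ln(r_2/r_1)/\ln 10$, which the correction
term cancels *exactly* when $r$ is the logarithmic mean. This makes the
estimator exact under its own forward model — clean synthetic streams
recover the programmed saturation to machine precision — whereas the
geometric mean or midpoint leave a systematic residual. Both alternatives
remain available via `r_reference()`.

**Extinction table.** Compiled literature values at 730/810/855 nm are
shipped as an editable CSV (`hemoglobin_extinction()`). Every test and
every simulated round trip constructs its forward data from the same
table, so no result depends on the table's absolute accuracy.

**Out-of-range saturations** are clipped to [0, 1] with a per-sample flag
rather than rejected: near the admissible boundary, noise routinely pushes
estimates slightly outside.

## 4. Pennes bioheat depth profiles

The steady-state one-dimensional Pennes equation with an exponentially
decaying optical source,

$$k\,T'' + \mu_a\phi_0 e^{-\mu_{\mathrm{eff}}z}
+ \rho_b c_b w_b\,(T_0 - T) = 0,$$

with $T(0)=T_s$ and $T(\infty)=T_0$, has the closed form implemented by
`steady_profile_full()`:

$$T(z) = T_0 + (u_s + C)e^{-mz} - Ce^{-\mu_{\mathrm{eff}}z}, \quad
C = \frac{\mu_a\phi_0}{k(\mu_{\mathrm{eff}}^2-m^2)}, \quad
m = \sqrt{\rho_b c_b w_b / k}.$$

In the physiological regime $\mu_{\mathrm{eff}} \gg m$ the optical term is
minor and the profile reduces to `steady_profile_simple()`,
$T(z) = T_0 + (T_s - T_0)e^{-mz}$, with defaults $m = 0.0876$ mm$^{-1}$
and $T_0 = 36.5$ °C (typical skin/perfusion values). These are generic
literature constants with no accompanying fluence rate or conductivity,
so the full solution is exercised on synthetic parameter sets (default $k = 5\times
10^{-4}$ W mm$^{-1}$ °C$^{-1}$, perfusion product chosen to give the
default $m$); its correctness is checked against a finite-difference
residual of the governing equation ($<10^{-6}$ of the source-term scale)
rather than against any fitted data.

**Quasi-static time series.** `depth_series()` applies the steady-state
profile independently at each time point of a measured surface
temperature record. This quasi-static treatment (no transient heat
equation) is a deliberate design choice of the chain; its signature
consequence — depth-$z$
oscillation amplitudes are exactly $e^{-mz}$ times the surface amplitude —
is asserted in the tests. The resonant case $\mu_{\mathrm{eff}} = m$ is
rejected rather than special-cased: it cannot occur for tissue-like
parameters.

## 5. The phantom simulator

The hardware (LED driver, photodiode, thermal sensor, radio) is replaced
by generators that are pure functions of their arguments and a seed:

* `generate_detector_readings()` — paired near/far fluxes from the forward
  reflectance model with multiplicative Gaussian noise. The default RSD of
  0.3% is the stability bound of a well-driven LED source; detector counts
  sit far above the noise floor, so a multiplicative model (with an
  optional additive dark term left at 0) is appropriate.
* `led_stability_series()` — constant mean flux, multiplicative noise, no
  trend; emulates the 20-sample/10-s-interval bench stability protocol.
* `occlusion_series()` — a muscle-occlusion saturation episode: first-order
  decay toward the occluded level from contraction at $t=0$
  ($\tau_{\mathrm{fall}} = 4$ s), first-order recovery after release at
  $t = 11$ s ($\tau_{\mathrm{rise}} = 3$ s), 30 s record at 0.5 s sampling.
  The kinetics are parametric stand-ins; the episode's absolute levels are
  not pinned by data, so only the dip/recover *shape* is ever asserted. Exact
  round-trip recovery additionally requires equal reduced scattering at
  the two wavelengths (the estimator's own assumption);
  `occlusion_phantom()` builds such a phantom.
* `temperature_rise_series()` — saturating-exponential surface temperature
  rise, $\Delta T_{\max}$ proportional to optical power, $\tau = 60$ s so a
  60 s irradiation window shows visible curvature without saturating;
  additive noise at 10% of the thermal sensor's ±0.5 °C accuracy
  (repeatability, not absolute accuracy, governs replicate scatter).
* `periodic_temperature_series()` — 2 min on / 2 min off, 3 cycles, 5 s
  sampling: the surface drive for the depth-series demonstration.

What the simulator does *not* emulate: layered or heterogeneous tissue,
melanin differences between subjects, probe-skin coupling drift, ambient
light, radio artifacts, or transient heat conduction. Passing tests
therefore demonstrate the *internal consistency* of the computation chain
(each inverse recovers its forward model, at the measured noise level),
not the accuracy of the homogeneous semi-infinite model on real skin.

## 6. The Monte Carlo oracle

`mc_oracle()` is an independent photon-packet transport simulation
(exponential steps at $\mu_t$, Henyey–Greenstein scattering, implicit
capture, Russian roulette below $10^{-4}$ weight, matched boundary)
against which the diffusion formulas are validated. Defaults $g = 0.9$ and
a matched boundary are conventional for skin; the validation properties
are formulated on ratios and shapes that are insensitive to either at the
tolerances used.

Weight accounting is exact by construction: launched weight equals
escaped + absorbed + net roulette adjustment (kills minus survivor
boosts) + step-cap truncation, auditable via `mc_weight_closure()`. A
per-photon step cap (default $10^6$) with an explicit `truncated` tally is
needed because at zero absorption the escape-time distribution is
heavy-tailed (the depth coordinate is a recurrent random walk with
infinite mean first-passage time).

**Reading the decay constant off MC data.** The far field of the
diffusion model is not a pure exponential over any finite window: the
reflectance carries an algebraic $(\mu_{\mathrm{eff}} + 1/\rho)$
prefactor, so the textbook least-squares slope of $\ln(r^2 R)$ over
$r \in [5\,\mathrm{MTF}, 15\,\mathrm{mm}]$ is systematically steep — by
about 14% at forearm-skin optics, *even when applied to noise-free
analytic diffusion data*. `mc_fit_mueff()` therefore offers three
estimators: `"raw"` (the biased textbook slope, kept for transparency),
`"corrected"` (single-source asymptotic model) and `"dipole"` (default:
the matched-boundary dipole reflectance model with amplitude profiled
out). The dipole fit recovers $\mu_{\mathrm{eff}}$ from MC data to ~1–2%
at $5\times10^5$ photons, which is the genuine level of MC/diffusion
agreement at these optical properties; the on-axis log-fluence shape
correlation between MC and the analytic profile over $z \in [2, 10]$ mm
exceeds 0.999.

## 7. Problem sizes and numerical settings

The test suite and the acceptance script use: inversion round trips over
$\mu_{\mathrm{eff}} \in [0.05, 0.5]$ mm$^{-1}$; noisy-recovery studies at
3 repeats and 0.3% RSD; occlusion records of 61 frames (30 s at 0.5 s);
fluence grids at 0.1–0.5 mm step; a finite-difference bioheat residual at
$h = 0.01$ mm over $z \in [0, 20]$ mm; and Monte Carlo runs of
$5\times10^5$ photons (half-mm bins to 20 mm radius, 12 mm depth) for
validation, with smaller runs ($5\times10^3$–$5\times10^4$) for
reproducibility and conservation checks. All generators take explicit
seeds; identical seeds give bitwise-identical output.

## 8. Known limitations

* Homogeneous semi-infinite medium: no layers, no melanin compartment —
  reconstruction is of *relative* trends, not absolute dose in J/cm².
* Two chromophores only; water and melanin are not modeled.
* Single-wavelength $\mu_a$/$\mu_s'$ separation is impossible by design
  (only $\mu_{\mathrm{eff}}$ is recovered); multi-distance Farrell-model
  fitting is out of scope.
* The bioheat chain is quasi-static and one-dimensional with constant
  surface temperature as boundary condition; transient and 3-D effects
  are not captured.
* The occlusion and temperature-rise dynamics in the simulator are
  plausible parametric shapes, not fitted physiology.
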