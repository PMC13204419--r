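# photodose

Diffusion-model light dosimetry for wearable tissue optics.

Phototherapy dosing is usually planned from fixed population parameters or
surface readings, yet the dose actually delivered inside tissue varies
between people, body sites and sessions. A compact two-distance
diffuse-reflectance probe can close that gap: measure the diffusely
reflected light at two source–detector distances, invert the tissue's
effective attenuation coefficient in closed form, and from that one number
reconstruct the *relative* light-dose distribution inside the tissue in
real time — with a co-located thermal sensor supplying a depth-resolved
temperature estimate of the photothermal load. `photodose` implements that
whole computation chain for people building or studying such probes:
forward models, inversions, an rSO₂ oximetry pipeline that stress-tests
the optical model on dynamic tissue, a Pennes bioheat depth predictor, a
tissue-phantom telemetry simulator standing in for the hardware, and a
photon-packet Monte Carlo oracle for validating the diffusion
approximation.

## The models

Steady-state diffusion approximation, homogeneous semi-infinite medium:

- Reflectance: `R(r) = 3/(2πr²) (1 + 2A/3) μa μs′ exp(−μeff r)` with
  `μeff = √(3 μa μs′)`.
- Two-distance inversion: `μeff = ln(R₁r₁²/(R₂r₂²)) / (r₂ − r₁)` — gain
  and boundary factors cancel in the ratio.
- Internal fluence (isotropic point source, Taylor-expanded):
  `Φ(r,z) ∝ z/R³ (1 + μeff R) e^(−μeff R)`, `R = √(r²+z²)`; ratios of Φ
  depend only on `μeff` and geometry, which is what makes wearable dose
  mapping possible.
- Oximetry: `ΔOD` at two wavelengths → absorption ratio
  `κ = μa(λ₁)/μa(λ₂)` → saturation from the two-chromophore mixture
  equation.
- Bioheat: `k T″ + μa φ₀ e^(−μeff z) + ρb cb wb (T₀ − T) = 0`, solved
  analytically; simplified form `T(z) = T₀ + (Ts − T₀) e^(−mz)` with
  `m = 0.0876 mm⁻¹`, `T₀ = 36.5 °C`.

Units everywhere: mm, mm⁻¹, °C, s.

## Worked example

```r
library(photodose)

# forearm skin at 730 nm
op <- optical_properties(mu_a = 0.01, mu_s_prime = 1.41)
op
#> Optical properties (homogeneous semi-infinite medium)
#>   mu_a       = 0.01 mm^-1
#>   mu_s'      = 1.41 mm^-1
#>   g          = 0.9   boundary A = 1
#>   mu_eff     = 0.20567 mm^-1   D = 0.23474 mm   z0 = 0.70922 mm

# simulate three noisy repeat measurements on a mu_eff = 0.21 phantom
# and invert them from the two-distance telemetry
geom <- probe_geometry_preset("asbuilt")          # r1 = 4.2, r2 = 20.1 mm
ph   <- phantom_with_mueff(0.21, noise_rsd = 0.3, seed = 42)
tel  <- generate_detector_readings(ph, geom, 730, n = 3)
est  <- invert_mu_eff(tel$flux[tel$detector_id == "near"],
                      tel$flux[tel$detector_id == "far"], geom)
summarize_repeats(as.numeric(est))
#> Repeat summary: n = 3, mean = 0.21 mm^-1, RSD = 0.0824%

# relative dose 5 mm deep on-axis, versus the (0, 1) mm reference point
relative_fluence(0.21, r = 0, z = 5)
#> [1] 0.02925642        # ~2.9% of the shallow reference fluence

# depth-resolved temperature under a 40 degC surface reading
steady_profile_simple(c(0, 3, 5, 10), Ts = 40)
#> [1] 40.00000 39.19113 38.75864 37.95756
```

The inversion recovers the phantom truth (0.21 mm⁻¹) to a fraction of a
percent from 0.3%-noise readings; the fluence ratio says a point 5 mm deep
receives about 3% of the dose at the shallow reference point; the bioheat
profile relaxes from the 40 °C surface toward the 36.5 °C core with the
0.0876 mm⁻¹ perfusion decay constant.

A thin CLI over the same functions lives at `inst/cli/photodose.R`
(subcommands `simulate`, `invert-mueff`, `fluence-map`, `rso2`, `bioheat`,
`mc-validate`, `monitor`, `report`).

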