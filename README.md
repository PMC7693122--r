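# gelmetrics

Multiscale characterization of semi-interpenetrating-network (semiIPN)
hydrogels: viscoelasticity, solute transport and pore structure, analyzed
consistently on the macroscopic and the microscopic scale.

SemiIPN hydrogels pair a gel-forming polymer (e.g. agarose), which sets
the network structure and mechanics, with a trace of interpenetrating
linear polyelectrolyte, which sets the binding — and therefore the
transport — of a charged solute. Evaluating such materials as controlled
release systems requires a battery of instrument modalities; `gelmetrics`
implements the full analysis chain for each of them, plus a seeded
synthetic-data module so that every stage is testable against known
ground truth. It is aimed at soft-matter and drug-delivery labs analyzing
rheometer, DLS-microrheology, UV-VIS, FCS/TCSPC and electron-microscopy
exports.

## What it computes

* **Macrorheology** — complex modulus |G\*| = √(G′² + G″²) and phase angle
  δ = arctan(G″/G′) from frequency sweeps; generalized Maxwell fit
  G′ = Σᵢ Gᵢ(2πfλᵢ)²/(1+(2πfλᵢ)²), G″ = Σᵢ Gᵢ(2πfλᵢ)/(1+(2πfλᵢ)²) with
  F-test model-order selection; crosslink density ρₓ = G/RT and
  rubber-elasticity mesh size ξ = (6/πρₓN_A)^⅓.
* **Microrheology** — tracer MSD → moduli through the generalized
  Stokes–Einstein relation |G\*(ω)| = k_BT / (πa ⟨Δr²(1/ω)⟩ Γ[1+α]),
  with α the local log-log MSD slope.
* **Transport** — concentration profiles fitted with the semi-infinite
  diffusion solution c(x,t) = c₀ erfc(x/√(4·D_eff·t)) for the effective
  diffusivity D_eff and partition coefficient ε = c₀/c_sol; absorbance
  calibration with scattering-baseline correction; replicate aggregation.
* **FCS / lifetime** — single-component 3-D autocorrelation fit
  G(τ) = N⁻¹(1+τ/τ_D)⁻¹(1+τ/κ²τ_D)⁻½ giving D_s = w₀²/4τ_D;
  mono-exponential TCSPC tail fit for the fluorescence lifetime.
* **Turbidimetry** — τ(λ) = ln(10)·OD/L, wavelength exponent from the
  700–800 nm log-log slope, mapped to a correlation length via a
  user-supplied calibration table.
* **Pore imaging** — bandpass preprocessing, Kapur maximum-entropy
  thresholding, 8-connected pore segmentation (optional watershed),
  Zhang–Suen skeletonization with branch/junction statistics.
* **Synthetic data** — seeded generators for all of the above with ground
  truth attached (`truth()`), used throughout the test suite.

## Worked example

Fit a synthetic four-element frequency sweep (5% multiplicative noise)
and derive the network estimate, then fit a noisy diffusion profile:

```r
library(gelmetrics)

sw <- gen_frequency_sweep(Gi = c(300, 600, 1200, 2400),
                          lambdai = c(0.01, 0.1, 1, 10),
                          spec = generator_spec(1, noise_multiplicative(0.05)))
n <- select_n(sw, n_max = 5)          # -> 4
fit <- fit_maxwell(sw, n)
fit
#> Generalized Maxwell model (4 elements)
#>  i    G_Pa lambda_s
#>  1  338.56 0.011433
#>  2  561.68 0.112820
#>  3 1144.90 0.934270
#>  4 2453.10 9.862100
#> G_total = 4498.27 Pa; RSS = 0.07084 on 32 dof
network_estimate(fit, temperature = 298.15)
#> Network estimate at T = 298.15 K
#>   crosslink density rho_x = 1.8147 mol m^-3
#>   mesh size xi = 12.05 nm

prs <- gen_concentration_profiles(Deff = 389, c0 = 53,
         spec = generator_spec(1, noise_additive(0.02, relative = TRUE)))
fit_profile(prs[[1]], csol = 10)
#> Diffusion fit (t = 24 h)
#>   Deff = 388.2 um^2 s^-1
#>   c0 = 53.195 g m^-3;  epsilon = c0/csol = 5.319
```

The fitted `G_total` (within ~1.5% of the generating 4500 Pa under 5%
noise) sets the mesh size through rubber elasticity; the diffusion fit
recovers the generating diffusivity (389 µm² s⁻¹) and partition
coefficient (5.3) from a single noisy profile.

`run_pipeline()` drives the same analyses from a YAML configuration with
per-modality readers/writers; see `?run_pipeline`.

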