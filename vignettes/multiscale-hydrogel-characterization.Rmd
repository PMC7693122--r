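---
title: "Multiscale characterization of semi-interpenetrating hydrogels"
author: "gelmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale characterization of semi-interpenetrating hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmetrics)
```

## Scope

Semi-interpenetrating-network (semiIPN) hydrogels combine a gel-forming
polymer (e.g. agarose), which rules the network structure and mechanics,
with a trace of linear polyelectrolyte (e.g. poly(styrene sulfonate) or
alginate), which rules the binding and hence the transport of a charged
solute. Characterizing such materials requires probing structure,
viscoelasticity and transport on both the macroscopic and the microscopic
scale. `gelmetrics` implements the complete analysis chain for six
instrument modalities, and a seeded synthetic-data module that generates
each modality from known ground truth so that every fitting stage can be
validated without instrument data.

## Macrorheology: generalized Maxwell model and mesh size

A frequency sweep records the storage and loss moduli $G'(f)$, $G''(f)$ of
an oscillatory shear deformation in the linear viscoelastic region. The
derived quantities are the complex modulus $|G^*| = \sqrt{G'^2 + G''^2}$,
the phase angle $\delta = \arctan(G''/G')$ (0° ideal solid, 45° gel point,
90° ideal liquid) and the complex viscosity $|G^*|/(2\pi f)$
(`derived_spectrum()`).

`fit_maxwell()` fits the parallel-element Maxwell model

$$G'(f)=\sum_{i=1}^{n} G_i\frac{(2\pi f\lambda_i)^2}{1+(2\pi f\lambda_i)^2},
\qquad
G''(f)=\sum_{i=1}^{n} G_i\frac{2\pi f\lambda_i}{1+(2\pi f\lambda_i)^2},$$

with spring constants $G_i$ (Pa) and relaxation times $\lambda_i$ (s). The
shear modulus is the spring-constant sum $G=\sum G_i$, which rubber
elasticity converts into the crosslink density and the mesh size
(`network_estimate()`):

$$\rho_x = \frac{G}{RT}, \qquad \xi = \left(\frac{6}{\pi\rho_x
N_A}\right)^{1/3}.$$

Numerical choices, each made where the procedure itself leaves the choice
open:

* **Residual weighting.** The two moduli are fitted jointly with
  *relative* residuals, $(\hat G - G)/G$ on each curve. Moduli span
  decades over a sweep; absolute least squares would fit only the
  high-frequency plateau. Whether the original spreadsheet fits were joint
  or sequential is not documented; a joint fit uses all information at
  once and is symmetric in the two curves.
* **Positivity.** $G_i, \lambda_i > 0$ is enforced by optimizing
  log-parameters (Levenberg–Marquardt via `minpack.lm`), not by penalty.
* **Initialization and restarts.** $\lambda_i$ start log-spaced across the
  observable window $[1/2\pi f_{max},\, 1/2\pi f_{min}]$ and $G_i =
  \max G'/n$; five jittered restarts run before failure is declared.
  Convergence tolerances are $10^{-12}$ on relative cost decrease.
* **Model order.** `select_n()` grows $n$ one element at a time and stops
  when the incremental F-test on the residual sum of squares is no longer
  significant at $\alpha = 0.05$ — a standard nested-model criterion. Note
  that an element whose $1/2\pi\lambda_i$ lies outside the measured
  frequency window is statistically invisible and will (correctly) not be
  selected.

## Microrheology: MSD to moduli via the generalized Stokes–Einstein relation

DLS microrheology observes the thermal motion of embedded tracer
particles and reports their 3-D mean square displacement
$\langle\Delta r^2(t)\rangle$ versus lag time. `gser_moduli()` converts
the trace to moduli with Mason's local power-law approximation of the
generalized Stokes–Einstein relation,

$$|G^*(\omega)| = \frac{k_B T}{\pi a\,\langle\Delta
r^2(1/\omega)\rangle\,\Gamma[1+\alpha(1/\omega)]},\qquad
G' = |G^*|\cos\frac{\pi\alpha}{2},\quad G'' = |G^*|\sin\frac{\pi\alpha}{2},$$

where $a$ is the tracer radius (default 50 nm, i.e. 100 nm nominal
particle size), and $\alpha$ is the local logarithmic slope of the MSD
(`local_slope()`, centered differences on the log–log grid, clipped to
$[0,1]$ with clips recorded). The frequency grid is the reciprocal lag
grid; no smoothing or resampling is applied, so the output has exactly one
point per correlator channel. Vendor microrheology tools do not document
their algorithm; Mason's approximation is the standard, citable choice.
The MSD is treated as 3-D displacement (the light-scattering convention);
users of 2-D particle tracking should rescale by 3/2.

In a purely viscous pore liquid $\alpha = 1$, $\delta \to 90^\circ$ and
$G''/\omega$ recovers the liquid viscosity — the package asserts this
closure to 2% in its tests. The phase angle mapping $\delta = 90\alpha$
means viscous character dominates exactly when $\alpha > 0.5$.

## Macroscopic transport: erfc profiles, diffusivity and partition

Diffusion of a dye from a stirred source solution into a gel-filled
cuvette produces, under the semi-infinite assumption, the concentration
profile

$$c(x,t) = c_0\,\mathrm{erfc}\!\left(\frac{x}{\sqrt{4 D_{eff}
t}}\right),$$

with effective diffusivity $D_{eff}$ and interface concentration $c_0$.
`fit_profile()` fits both jointly (unweighted least squares,
log-parameters for positivity) and attaches the partition coefficient
$\varepsilon = c_0/c_{sol}$ with $c_{sol} = 10$ g m⁻³ by default (a
0.01 g/dm³ source solution, configurable). A warning is raised when the
penetration depth $\sqrt{4D_{eff}t}$ exceeds 80% of the scanned depth,
where the semi-infinite boundary condition degrades. Fitting $c_0$ rather
than pinning it to the first measured point keeps the estimator unbiased
under read-out noise. `calibrate()` converts absorbance to concentration
through reference gels with known dye content, subtracting a linear
baseline fitted over 650–800 nm (where the dye does not absorb) to remove
the scattering background of turbid gels. `aggregate_fits()` pools the
three diffusion times and replicate measurements into per-composition
means and standard deviations.

## FCS and fluorescence lifetime

Fluorescence correlation spectroscopy provides the self-diffusion
coefficient of individual dye molecules. `fit_fcs()` uses the simplest,
single-component 3-D Gaussian-volume model

$$G(\tau) = \frac{1}{N}\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{\tau}{\kappa^2\tau_D}\right)^{-1/2},\qquad
D_s = \frac{w_0^2}{4\tau_D}.$$

The beam waist $w_0$ (default 0.3 µm) and structure parameter $\kappa$
(default 5) are calibration inputs: they are not identifiable from a
single curve, and typical confocal calibrations fall in this range. The
sensitivity of $D_s$ to the assumed $\kappa$ is weak (a few percent over
$\kappa \in [4,6]$ in our tests), which justifies fixing it.

`fit_lifetime()` fits a mono-exponential decay plus constant background
to the tail of a TCSPC histogram, starting (by default) 1 ns past the
peak. Tail fitting avoids reconvolution with an instrument response
function, which is rarely exported with the histogram; for
nanosecond-scale lifetimes sampled over 50 ns the bias of this shortcut is
far below the replicate spread.

## Turbidimetry

`turbidity_spectrum()` converts transmittance to optical density
$OD = -\log_{10} T$ and turbidity $\tau = \ln(10)\,OD/L$ per cm of path
(the literal factor "2.3" in common write-ups is taken as $\ln 10$).
`wavelength_exponent()` regresses $\log_{10}\tau$ on $\log_{10}\lambda$
over an inclusive 700–800 nm window — chosen because no chromophore
absorbs there, so all attenuation is scattering. The slope (the
wavelength exponent, $-4$ in the Rayleigh limit) maps to an effective
correlation length through a user-supplied monotone calibration table
(`correlation_length()`, linear interpolation in log-length, no
extrapolation). The calibration numbers are published externally and are
deliberately *not* shipped: the package refuses to invent calibration
data.

## Pore imaging

Micrograph quantification follows the classical particle/skeleton recipe:

1. `preprocess()` — contrast stretch saturating 0.35% of pixels per tail,
   then a radial Butterworth (order 4) bandpass keeping structure between
   `band[1]` = 3 px and `band[2]` = 40 px by default, suppressing
   large-scale illumination gradients and single-pixel noise.
2. `threshold_maxentropy()` — Kapur's maximum-entropy threshold over the
   256-bin histogram, ties broken toward the lower threshold; the test
   suite holds it bit-exactly equal to an exhaustive brute-force entropy
   scan. The pore phase defaults to *dark*, matching cryo-SEM contrast.
3. `analyze_pores()` — 8-connected component labeling (background
   4-connected), optional distance-transform watershed to split touching
   pores, a minimum-area filter (default 4 px², suppressing single-pixel
   noise), and per-pore area and perimeter in px and nm. The perimeter is
   a crack-length estimator with a diagonal-corner correction; perimeter
   definitions differ between tools, so only within-tool comparisons are
   meaningful.
4. `analyze_skeleton()` — Zhang–Suen topology-preserving thinning,
   pixel classification by 8-neighbor count (endpoint 1, slab 2, junction
   ≥ 3), junction clustering, and branch tracing with $\sqrt2$-weighted
   diagonal steps. Note that thinning shortens a bar of width $W$ by about
   $W/2$ at each end: the medial axis of an $L\times W$ rectangle spans
   $L - W$ pixels, which is what the branch length reports.
5. `summarize()` — five-number box-plot summary plus mean, quartiles by
   linear interpolation.

## The synthetic-data module

Every generator is a pure function of its parameters and a
`generator_spec(seed, noise, grid)`: the same seed gives bit-identical
output, and `noise_none()` reproduces the closed-form model exactly, so
each generator/fitter pair forms an exact-inverse test. Defaults emulate
the study conditions:

| modality | grid | default noise |
|---|---|---|
| frequency sweep | 0.01–20 Hz, 6 pts/decade | 5% multiplicative |
| concentration profile | 0–10 mm, 0.25 mm steps; 24/48/72 h | additive, 2% of $c_0$ |
| MSD trace | 10⁻⁵–10 s, 30 pts/decade | 2% multiplicative |
| FCS curve | 10⁻⁷–1 s, 24 pts/decade | 1% multiplicative |
| TCSPC decay | 0–50 ns, 1024 bins | Poisson |
| turbidity | 300–800 nm, 2 nm steps | 1% multiplicative |

The sweep noise level matches the ≤10% duplicate-run reproducibility
typical of rotational rheometry; the 2%-of-$c_0$ profile noise is a
realistic photometric read-out error that still leaves parameter recovery
meaningful; photon counts are intrinsically Poisson. No instrument
physics is simulated (no scattering correlograms, confocal point-spread
functions or detector afterpulsing), and no binding chemistry: the
generators produce the *idealized* closed-form signal plus noise.
Consequently, passing recovery tests demonstrates that the estimators are
correct and unbiased under the stated noise, not that real instruments
are free of systematic effects. The pore-image generator offers exact
ground truth (disk areas, bar/cross skeleton topology) for structured
kinds, and statistical ground truth (target porosity at a stated
correlation length of a thresholded Gaussian random field) for the random
kind, where per-pore truth is ill-defined.

Test and validation problem sizes were chosen to make sampling spread
negligible relative to the asserted tolerances at interactive runtimes:
recovery simulations use 50 seeds (three diffusion times each for
profiles), model-order selection uses 50 (single-element) and 10
(four-element) replicates, and synthetic micrographs are 64–128 px
squares; analysis functions handle the conventional 512 × 512 crops
identically.

## Known limitations

* Rubber-elasticity mesh sizes and turbidity correlation lengths are
  *effective*, method-specific lengths; they need not agree with each
  other or with imaged pore sizes, and the package makes no attempt to
  reconcile them.
* GSER assumes the tracer probes a homogeneous continuum; in a gel whose
  pores are comparable to the tracer size the moduli characterize the
  pore liquid, not the bulk.
* The single-component FCS model returns one global diffusion time;
  strongly bound, statically quenched molecules are invisible to it.
* Tail fitting cannot resolve lifetimes comparable to the instrument
  response width.
* Absolute $D_s$ values require a calibrated $w_0$; with an uncalibrated
  waist only ratios between samples are meaningful.
* Watershed splitting is geometric; heavily concave pores may be
  over-split.
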