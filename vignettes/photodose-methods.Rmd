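---
title: "Methods: Monte Carlo light transport and singlet-oxygen dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo light transport and singlet-oxygen dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

photodose computes the dose quantity that drives type II photodynamic
therapy (PDT): the cumulative concentration of singlet oxygen that has
reacted with tissue, written $[^1O_2]_{rx}$. Incident light dose (J/cm$^2$)
ignores how light, photosensitizer and oxygen are actually distributed and
consumed; $[^1O_2]_{rx}$ accounts for all three, and correlates far better
with treatment outcome. The package couples three models:

1. a voxel-based Monte Carlo (MC) simulation of the light fluence rate
   $\phi(\mathbf{r})$ in turbid tissue,
2. per-voxel macroscopic photokinetic rate equations integrated over the
   treatment time, and
3. an outcome layer linking the simulated dose to tumor regrowth and cure
   index.

This vignette records the model assumptions, the numerical choices, and the
design decisions taken where the problem left the design open.

## Monte Carlo light transport

Photon packets are launched from a collimated disc source in air, normal to
the illuminated face of a grid of identical cubic voxels (the z = 0 plane;
depth increases with z; the beam axis passes through the lateral grid
centre). Each packet starts with weight 1 and loses the specular Fresnel
fraction at the air-tissue interface ($R_{sp} = 2.78\%$ for n = 1.4 at
normal incidence). Inside the medium the standard variance-reduced random
walk applies:

* free paths are sampled as $-\ln(u)/\mu_s$ and carried as dimensionless
  optical depth, so when a path crosses into a voxel with a different
  $\mu_s$ the remaining path is rescaled automatically — the unbiased
  treatment of path adjustment across property changes;
* along every traversed voxel sub-path of length $l$ the packet deposits
  $w(1 - e^{-\mu_a l})$ and its weight is attenuated by $e^{-\mu_a l}$
  (continuous absorption weighting);
* scattering directions come from the Henyey-Greenstein phase function with
  anisotropy $g$, azimuth uniform;
* at every exterior face the packet sees an unpolarized Fresnel reflection
  against air ($n$ vs 1.0), which produces the total internal reflection
  that pins light under the surface; escaping weight through z = 0 is
  tallied as diffuse reflectance $R_d$, through any other face as
  transmittance. Escaping packets are tallied, not geometrically refracted:
  no detector geometry is modelled.

The per-voxel fluence rate uses the absorbed-weight estimator
$\phi = A P / (\mu_a V N)$ with $P$ the source power in mW, $V$ the voxel
volume and $N$ the photon count. In voxels with $\mu_a = 0$ this estimator
is undefined, so those voxels fall back to the track-length estimator
$\phi = \sum w\,l \cdot P / (V N)$, which estimates the same quantity
without the absorption intermediate.

**Anisotropy.** Tumor optical measurements give the reduced scattering
coefficient $\mu_s' = \mu_s(1-g)$ only. The package defaults to the
conventional soft-tissue $g = 0.9$ (hence $\mu_s = 110$/cm for
$\mu_s' = 11$/cm) and exposes $g$ in the configuration; in the diffusive
regime results depend on $g$ mainly through $\mu_s'$. The test suite
measures this similarity directly: $g=0.9, \mu_s=110$ and $g=0, \mu_s=11$
give identical attenuation slopes (within 2%) and near-axis fluence within
10% beyond one transport mean free path. The residual is real physics, not
noise — first-order similarity is exact only asymptotically, and for this
extreme anisotropy contrast the fluence keeps a few-percent systematic
difference at intermediate depths (diffuse reflectance 0.323 vs 0.332);
moderate contrasts such as $g = 0.5$ vs $0.9$ sit well inside it.

**Termination.** Packets below the weight threshold ($10^{-4}$ by default)
undergo Russian roulette: survival probability 1/10, survivor weight
multiplied by 10, which terminates histories without biasing the estimator.
A `roulette = FALSE` mode truncates instead, for strict literalism at the
cost of a (tiny, $\le 10^{-4}$) absorbed-weight bias. Because roulette
injects weight into survivors, a naive four-way energy ledger would not
close run by run; the package books roulette-killed weight as absorbed and
subtracts the injected survivor weight from the same component, so
specular + diffuse + transmitted + absorbed = 1 to floating-point rounding
on every run while the deposition estimator stays unbiased.

**Randomness.** Each photon owns a counter-based splitmix64 stream keyed on
`(seed, photon index)`. Tallies are order-independent sums, so results are
reproducible bit for bit for a given seed regardless of scheduling, and a
single photon can be replayed in isolation (`trace_photon()`).

**Linearity.** Transport is linear in source power: the fluence map per unit
incident power depends only on geometry and optics. `scale_source()`
rescales a completed map exactly to a new lamp setting, and the batch
driver exploits this to run one MC simulation per distinct incident fluence
rate rather than one per treatment group.

## Photokinetics

Each voxel evolves independently under its (time-constant) fluence rate
$\phi$ according to the macroscopic rate equations for ground-state
photosensitizer $[S_0]$, ground-state oxygen $[^3O_2]$ and reacted singlet
oxygen:

$$\frac{d[S_0]}{dt} = -\xi\sigma\phi\,([S_0]+\delta)\,
  \frac{[^3O_2]}{[^3O_2]+\beta}\,[S_0]$$
$$\frac{d[^3O_2]}{dt} = -\xi\phi\,[S_0]\,\frac{[^3O_2]}{[^3O_2]+\beta}
  + g\left(1 - \frac{[^3O_2]}{[^3O_2]_{t=0}}\right)$$
$$\frac{d[^1O_2]_{rx}}{dt} = \xi\phi\,[S_0]\,\frac{[^3O_2]}{[^3O_2]+\beta}$$

with the published BPD parameter set ($g = 1.7\ \mu$M/s, $\delta = 33\ \mu$M,
$\beta = 11.9\ \mu$M, $\sigma = 1.8\times10^{-5}/\mu$M,
$\xi = 0.055$ cm$^2$mW$^{-1}$s$^{-1}$) and 40 $\mu$M initial oxygen.
Internally concentrations are $\mu$M and $\phi$ is mW/cm$^2$, so $\xi\phi$
has units 1/s; dose maps are reported in mM.

Holding $\phi$ constant during treatment mirrors applying a single
transport solution to the whole session — photobleaching is assumed not to
change the tissue optics.

**Solver.** An embedded Dormand-Prince RK5(4) pair with adaptive steps
(rtol $10^{-6}$, atol $10^{-9}\ \mu$M, initial step 1 ms). Non-negativity
is enforced by rejecting and halving any trial step whose fifth-order
solution has a component below $-10^{-12}\ \mu$M and clamping smaller
undershoots to zero; away from the constraint boundary the scheme keeps its
usual order. The solver is validated two ways in the test suite: against a
brute-force fixed-step classical RK4 at dt = 1 ms
(`integrate_pk_rk4()`), and against an independent stiff solver
(`deSolve::lsoda` at rtol $10^{-10}$), both to 0.1% relative in
$[^1O_2]_{rx}$. The specific RK5(4) coefficient set is a package choice;
equivalence is asserted through these oracles, not coefficient identity.

**Dose at depth.** The clinically quoted scalar is the dose at 3 mm below
the surface on the beam axis, defined on voxel-layer interfaces as the mean
of the two adjacent beam-axis voxel values: layers 3 and 4 of a 1-mm grid,
6 and 7 of a 0.5-mm grid, 12 and 13 of a 0.25-mm grid. Because even voxel
counts put the beam axis on a voxel corner, "beam axis" values average the
central 2 x 2 voxel columns.

## Analytic cross-check

The centre-beam depth profile of $\phi/\phi_{air}$ for a broad beam is well
approximated by a buildup term times a two-exponential decay,
$(1 - b e^{-\lambda_1 d})(C_2 e^{-\lambda_2 d} + C_3 e^{-\lambda_3 d})$.
The closed-form coefficient functions of $(\mu_a, \mu_s', \mu_{eff}, R_d)$
are not re-derived here; instead `fit_eq5()` fits the six parameters to an
MC profile by multi-started Levenberg-Marquardt least squares (exponential
mixtures are ill-conditioned, hence the restarts and the tail-slope-based
initialization). Residuals are weighted by 1/ratio by default because MC
profile noise is approximately multiplicative; relative weighting is also
what keeps the near-surface buildup constant $\lambda_1$ identifiable —
with absolute weighting the handful of buildup points carry too little of
the objective. The fitted curve reproduces the MC profile within 3% of
the peak ratio for the reference optics, which is the package's working
cross-check between the transport code and the 1-D diffusion-theory
picture.

## Outcome layer

Tumor volumes from caliper diameters use $V = \pi a^2 b / 6$. The regrowth
rate $k$ is the least-squares slope of $\ln V$ against day over the 14-day
follow-up; cured tumors produce zero volumes, which cannot enter a log fit
— those points are dropped, and if fewer than three positive measurements
remain the animal is booked as cured with $k = 0$ (matching how cured
groups carry $k = 0$ in the reference table). The cure index is
$CI = 1 - k/k_{ctr}$ against the untreated-control rate. Group-level CI can
be computed from the group-mean $k$ ("formula mode") or averaged over
per-subject CIs; the reference table's printed group CIs are not exactly
$1 - k/k_{ctr}$ of its printed group-mean rates (per-mouse averaging is the
likely cause), so the package provides both routes and hard-codes neither.

The dose-response model is the three-parameter logistic
$CI(D) = A/(1 + B e^{-cD})$, fitted by unweighted least squares
(`correlate_outcomes()`). Fitting it to the printed group table against
$[^1O_2]_{rx}$ at 3 mm and against incident fluence quantifies the
central claim: the singlet-oxygen fit has a markedly smaller RMS residual
and higher rank correlation. With the published curve
($A = 1.08$, $B = 3490$, $c = 8.301$/mM), $CI \ge 1$ first occurs near
1.3 mM — the cure threshold.

## Synthetic data and what the tests can show

Two generators stand in for experimental inputs:

* **Optical phantoms** (`make_phantom()`): homogeneous blocks plus layered
  or spherical-inclusion heterogeneities. They emulate tissue with known,
  piecewise-constant optical properties. They do not emulate curved
  surfaces, anatomical heterogeneity or measured property maps, so passing
  tests demonstrate correct transport physics on idealized geometry, not
  anatomical realism (the planar geometry matches the superficial-tumor
  setting the model targets).
* **Regrowth measurements** (`simulate_regrowth()`): exponential volume
  growth with 10% multiplicative lognormal measurement noise, daily over 14
  days, the scale of the reference study (whose group-4 rate is
  0.28/day). Real follow-up data add treatment-induced shrinkage phases
  and per-animal heterogeneity the generator does not model.

## Problem sizes and numerical conditions

Reference reproduction runs use the study conditions themselves: 100^3
grids at 0.5-mm voxels (0.25- and 1-mm grids for convergence), the 10-mm
disc, and the printed per-group illumination settings and BPD
concentrations. Monte Carlo runs use $2\times10^6$ photons — the package's
standard desk-scale photon budget, which holds the MC standard error of the
3-mm beam-axis dose below 1% (the acceptance band for cross-implementation
dose comparison is ±5%, justified by the reference study's own
re-implementation mismatches of −0.5% to +4.3%). The test suite's
similarity and Beer-Lambert checks use (4-5)$\times10^5$ photons, enough
for their 1-3% tolerances.

## Known limitations

* Voxel-based transport approximates curved boundaries by staircases; for
  the planar superficial geometry this is immaterial, but mesh-based MC
  would be preferable for strongly curved targets.
* The photokinetic model is macroscopic: no microscopic singlet-oxygen
  diffusion, no explicit triplet-state kinetics, no type I chemistry, no
  vascular oxygen transport; oxygen resupply is a single saturating source
  term.
* $\phi$ constant in time excludes dynamic optical-property changes.
* Escaping photons are tallied at the face they cross without refraction
  into a detector geometry, so angularly resolved emission is out of scope.
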