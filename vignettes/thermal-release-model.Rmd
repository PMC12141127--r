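---
title: "A two-step diffusion–desorption model of thermal radioscandium release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-step diffusion–desorption model of thermal radioscandium release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screlease)
```

## The physical problem

Heating an irradiated titanium foil in vacuum releases the tracer-level
radioscandium it contains: atoms first diffuse through the titanium lattice
to the foil surface, then sit adsorbed on the hot surface until they gain
enough energy to desorb into the vacuum, where a cooled catcher foil can
collect them. `screlease` models both steps, simulates them with a seeded
Monte Carlo engine, and inverts the model to estimate the Sc/Ti desorption
enthalpy from measured release curves.

## Model and assumptions

**Step 1 — diffusion.** For a plane sheet of thickness $d$ with a uniform
initial tracer distribution, the fraction of atoms that have reached the
surface by time $t$ is taken in the single-term approximation

$$F(t) = 1 - \frac{8}{\pi^2}\exp\!\left(-\frac{D(T)\,t}{d^2}\right),$$

with the Sc-in-Ti diffusion coefficient

$$D(T) = 10^{\,0.0039\,T - 13.252}\ \mathrm{cm^2/s}, \qquad T \text{ in K},$$

a log-linear fit to published tracer-diffusion measurements over the
850–1150 °C range. Two deliberate modelling choices deserve emphasis:

* $D(T)$ is a base-10 exponential in $T$, *not* an Arrhenius law in $1/T$.
  It is an empirical fit valid over the stated range and is used exactly as
  fitted; `fit_enthalpy()` never re-estimates it, because doing so would
  detach the diffusion law from the data it came from.
* The exponent of $F$ is $-D t/d^2$ exactly as the model line states, with
  no $\pi^2/4$-type geometric factor such as appears in full eigenfunction
  series solutions for slab release. The package implements the model as
  specified and does not "correct" it; $d$ is the printed foil thickness,
  with no assumption about one- or two-sided release.

Since $F(0) = 1 - 8/\pi^2 \approx 0.189 > 0$, the single-term form assigns
positive probability to arrival "already at $t=0$". We interpret this mass
as a point mass of immediate surface arrival, which makes $F$ a proper CDF
so that both inverse-transform sampling and quadrature are well defined.

**Step 2 — desorption.** An adsorbed atom leaves the surface after an
exponentially distributed residence time with Frenkel mean

$$\bar\tau_a = \tau_0\,e^{E_{des}/(RT)},$$

where $\tau_0 = 1.6\times10^{-13}$ s is the Lindemann estimate of the
oscillation period of the adsorbed atom perpendicular to the surface, and
$E_{des}$ (kJ/mol) is the positive desorption energy. The literature on
adsorption works with negative adsorption enthalpies ($\Delta H_a$ between
roughly −385 and −395 kJ/mol for Sc on Ti); the package stores the positive
quantity $E_{des} = -\Delta H_a$ to avoid double-negative sign errors, and
prints both conventions. The gas constant is fixed at
$R = 8.314$ J mol⁻¹ K⁻¹; energies are kJ/mol at the interface and converted
to J/mol internally. Temperatures are kelvin internally; `celsius()`
converts user-facing °C.

An atom **evaporates** if arrival time + residence time ≤ experiment
duration; otherwise it is **adsorbed on the surface** at the end of the
run, or **retained in the bulk** if it never arrived. Atoms are independent
(tracer level), re-adsorption from the vacuum is excluded (perfect sink),
and the temperature is constant over a run — each condition is treated as
an independent experiment, which is the model's reading even where a
laboratory series may in fact have annealed one target stepwise through
several temperatures.

## Monte Carlo engine and reproducibility

Arrival times are sampled by inverse CDF on the truncated distribution: a
deviate $u$ below the point mass maps to $t=0$; $u \le F(t_{exp})$ maps to
$t = -\tau_D\,\ln(\pi^2(1-u)/8)$ with $\tau_D = d^2/D(T)$; larger $u$ means
the atom never arrives. This is exact and rejection-free.

Each atom consumes exactly **two** uniform deviates — one for arrival, one
for residence — in atom order, with the residence draw discarded for atoms
that never arrive. The fixed two-draws-per-atom layout keeps the random
stream aligned regardless of atom fates, so (i) a run is bit-reproducible
from its seed, and (ii) holding the seed fixed while varying the desorption
energy reuses the same deviates (common random numbers), which makes the
SSE profile of the grid search smooth in $E_{des}$ and its argmin stable at
10⁴ atoms. Sweeps derive one sub-seed per condition deterministically from
the master seed.

A zero-duration experiment is a special case: every atom is retained in the
bulk, because zero heating time allows no transport even though the
single-term CDF would formally assign the $t=0$ point mass.

## The semi-analytic oracle

`semi_analytic_release()` computes the same release probability without
randomness, as the convolution of the two steps:

$$P = p_0\left(1 - e^{-t_{exp}/\bar\tau_a}\right)
  + \int_0^{t_{exp}} \frac{8}{\pi^2}\frac{1}{\tau_D} e^{-t/\tau_D}
    \left(1 - e^{-(t_{exp}-t)/\bar\tau_a}\right)\,dt .$$

The integral is evaluated with adaptive quadrature at a relative tolerance
of 10⁻⁹. The integrand varies on two very different scales — the arrival
decay $\tau_D$ near $t=0$ and a desorption boundary layer of width
$\bar\tau_a$ near $t = t_{exp}$ — so the integration range is split at
$30\,\tau_D$ and $t_{exp} - 30\,\bar\tau_a$ (cuts are dropped when they
fall within $10^{-6} t_{exp}$ of the endpoints, where the corresponding
feature contributes below tolerance). Without the split, the adaptive rule
can step over the boundary layer and overestimate the release by a few
times 10⁻⁵. The test suite checks the quadrature against an independent
closed two-exponential form of the same convolution. No probability is
clamped anywhere: out-of-range values are treated as bugs.

In the instantaneous-desorption limit $E_{des}=0$ the oracle collapses to
$F(t_{exp})$, the diffusion-only curve; the Monte Carlo engine reproduces
both within binomial sampling error. Comparing the two curves is the
model's central diagnostic: at 25 µm and 2 h, diffusion alone would predict
≥ 80% release already at 850 °C, while the full model gives ~2% — the
desorption step dominates below about 1100 °C.

## Fitting the desorption enthalpy

`fit_enthalpy()` performs a grid search (default 385–395 kJ/mol in 1 kJ/mol
steps) minimising the sum of squared residuals between observed and
predicted release percentages. Choices made where the procedure was
genuinely open:

* **Weighting** defaults to unweighted SSE — the minimal reading of "least
  squares"; inverse-variance weighting by the reported `sigma_pct` is
  available.
* **No sub-grid interpolation** by default: the estimator reports a grid
  value, matching the 1 kJ/mol resolution of the search; parabolic
  refinement through the three points around the minimum is available
  behind `refine = TRUE`.
* **Ties** in the SSE profile resolve to the smallest energy; observations
  are canonically ordered internally so the estimate cannot depend on input
  order.
* A minimum on the grid **boundary** triggers a warning (the truth likely
  lies outside the grid), as does a **degenerate** design with fewer than
  two distinct temperatures.

`estimate_uncertainty()` reports a residual bootstrap: resample the
percent-scale residuals with replacement, add them to the fitted curve,
refit, and take the half-width of the central 68% interval of refitted
energies, floored at step/2 (a grid search cannot resolve below half its
step). The bootstrap is labelled as such in reports; no closed-form
uncertainty is claimed. Bootstrap refits default to the noise-free
semi-analytic engine — its profile argmin coincides with the
common-random-numbers Monte Carlo argmin in almost all seeded trials, and
it is orders of magnitude faster. Notably, with 2% relative measurement
noise on a 13-temperature sweep the bootstrap routinely collapses to the
0.5 kJ/mol floor: the release sigmoid is so steep in $E_{des}$ that the
statistical uncertainty of the estimator is below the grid step. A quoted
±5 kJ/mol on such a fit therefore has to cover model and systematic
contributions, not statistical scatter alone.

## Synthetic measurements

`generate_release_observations()` emulates γ-counting release measurements:
the true release fraction comes from the semi-analytic oracle, then two
independent multiplicative zero-mean Gaussian noise terms are applied — a
counting-statistics term (default 0.2% relative) and a systematic term
(default 1.5% relative), the middles of the 0.1–0.2% and 1–2% ranges
typical of such experiments. Noise is applied per observation
(uncorrelated), the simplest structure consistent with stated magnitude
ranges; Poisson counting statistics are unnecessary at these relative
sigmas. Results are truncated to [0, 100]% afterwards and truncation events
are counted. Catcher recovery is modelled phenomenologically as a single
per-material sticking fraction (defaults: Au 0.65, brass 0.47, Ti 0.30,
Ta 0.27 — the cold-finger scale); any mechanism behind those numbers, such
as Sc dissolving into a gold matrix, is out of scope.

What the generator does *not* emulate: detector efficiency and dead time,
decay correction, correlated systematic drifts across an experimental
series, temperature-ramp transients, or porosity effects in sintered
targets. Tests passing on synthetic data therefore demonstrate the
pipeline's internal consistency — generator, oracle, Monte Carlo engine and
estimator agree — not the adequacy of the two-step model for any particular
laboratory system.

`reference_conditions()` returns the standard two-series design used
throughout: five temperatures (900–1100 °C in 50 °C steps) on 25 µm foil
plus six thicknesses (0.025–1 mm) at 1100 °C, all at 2 h.

## Problem sizes and runtime

Defaults follow the design the model was built around: 10⁴ atoms per
simulation, 13-temperature sweeps (850–1150 °C in 25 °C steps), the
385–395 kJ/mol grid, 50 bootstrap replicates. The full test suite —
including a 10⁵-draw Kolmogorov–Smirnov check of the arrival sampler, a
5×5 (T, d) oracle-agreement grid at 10⁴ atoms, and 30 noisy
parameter-recovery fits — runs in well under a minute, and the acceptance
script in a few seconds; these sizes are the package's chosen study
conditions, with sampling error kept at or below the measurement noise
being emulated.

## Known limitations

* The single-term diffusion approximation misstates the true early-time
  arrival law; its $t=0$ point mass is a modelling convention, and the
  package inherits whatever bias that carries.
* $D(T)$ is an empirical fit; outside roughly 850–1150 °C both it and the
  conclusions drawn from it are extrapolations.
* The estimator's statistical precision (≤ 1 kJ/mol under 2% noise) should
  not be mistaken for accuracy: errors in $D(T)$, in $\tau_0$, or in the
  single-term approximation propagate directly into the fitted enthalpy.
* No spatially resolved concentration profiles, multi-layer or cylindrical
  geometries, temperature schedules, or catcher-side transport.
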