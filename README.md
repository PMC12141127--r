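# screlease

Modelling the thermal release of radioscandium from titanium targets.

Non-carrier-added ⁴⁷Sc — the therapeutic partner of the diagnostic ⁴³/⁴⁴Sc in
a true theranostic pair — can be separated from macroscopic titanium targets
*dry*, by heating the irradiated foil in vacuum until the tracer-level Sc
atoms leave it and condense on a cooled catcher. `screlease` is for
radiochemists and target designers who want to predict release fractions for
a given temperature, foil thickness and heating time, and to extract the
Sc/Ti desorption enthalpy from measured release curves.

## The model

Release is a two-step process:

1. **Diffusion to the surface.** With Sc produced homogeneously at tracer
   level in a foil of thickness *d* (cm), the probability that an atom has
   reached the surface by time *t* is taken in the first-term plane-sheet
   approximation

   F(t) = 1 − (8/π²) · exp(−D(T)·t / d²),

   with the Sc-in-Ti diffusion coefficient fitted log-linearly in absolute
   temperature, D(T) = 10^(0.0039·T − 13.252) cm²/s. F(0) = 1 − 8/π² ≈ 0.189
   is treated as a point mass of immediate surface arrival, which makes F a
   proper CDF for sampling.

2. **Desorption into vacuum.** An atom on the surface waits an exponentially
   distributed residence time with Frenkel mean

   τ̄ₐ = τ₀ · exp(E_des / (R·T)),

   where τ₀ = 1.6 × 10⁻¹³ s (Lindemann oscillation period) and
   E_des = −ΔH_a is the positive desorption energy in kJ/mol (the package
   stores the positive quantity; an adsorption enthalpy of −390 kJ/mol is
   `E_des = 390`).

A seeded Monte Carlo engine simulates atom histories (inverse-CDF arrival
sampling, exponential residence), and a deterministic quadrature oracle
computes the same release probability by convolving the two steps. The
desorption energy is estimated from release-vs-temperature data by a
grid-search least-squares fit (default grid 385–395 kJ/mol in 1 kJ/mol
steps, 10 000 atoms per grid point, common random numbers across the grid),
with a residual-bootstrap uncertainty. Release and recovery bookkeeping
(R_rel = (Cᵢ−C_f)/Cᵢ·100, R_rec = Cₐ/(Cᵢ−C_f)·100) and a synthetic
γ-counting data generator round out the pipeline.

## Worked example

```r
library(screlease)

diff <- diffusion_law()          # D(T) = 10^(0.0039 T - 13.252) cm^2/s
des  <- desorption_law(390)      # E_des = 390 kJ/mol, tau0 = 1.6e-13 s

# release of a 25 um foil heated 2 h at 1100 degC
cond <- experiment_condition(celsius(1100), thickness = 0.0025, duration = 7200)
simulate_release(cond, diff, des, n_atoms = 10000, seed = 7)
#> Monte Carlo release: 10000 atoms (seed 7)
#>   evaporated 10000 | on surface 0 | in bulk 0
#>   release fraction 1.0000

# temperature sweep, 850-1150 degC: the release sigmoid
sw <- sweep_temperature(d = 0.0025, t_exp = 7200, diff = diff, des = des,
                        n_atoms = 10000, seed = 3)
round(sw$release_fraction, 4)
#>  [1] 0.0222 0.0515 0.1211 0.2733 0.5287 0.8092 0.9667 0.9976 0.9999 1.0000
#> [11] 1.0000 1.0000 1.0000

# recover the desorption energy from noisy synthetic measurements
conds <- lapply(default_temperatures(), experiment_condition,
                thickness = 0.0025, duration = 7200)
obs <- generate_release_observations(desorption_law(390), diff, conds,
                                     noise_model(0, 0.02), seed = 11)
fit_enthalpy(obs, enthalpy_grid(), diff, seed = 5, engine = "monte_carlo")
#> Desorption-enthalpy fit (monte_carlo engine, none weighting)
#>   E_des = 390.00 kJ/mol (adsorption enthalpy dH_a = -390.00 kJ/mol)
#>   uncertainty: not estimated
#>   grid: 385..395 kJ/mol, step 1; 10000 atoms/point; seed 5
```

The release fraction of 1.0000 at 1100 °C on 25 µm foil says that under
optimal conditions essentially every Sc atom both reaches the surface and
desorbs within 2 h; at 850 °C only ~2% do, because the mean residence time
on the surface (~2 × 10⁵ s) far exceeds the heating time — desorption, not
diffusion, limits the release below ~1100 °C. The fit returns the grid
value whose simulated sigmoid best matches the observations, here exactly
the generating 390 kJ/mol.

A file-based pipeline (`run_simulate()`, `run_synthesize()`, `run_fit()`,
`run_report()`) reads/writes the standard CSV and JSON formats; a thin
command-line wrapper lives at
`system.file("cli", "screlease.R", package = "screlease")`.

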