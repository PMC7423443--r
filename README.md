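# hillsym

Symmetry-based model selection for Hill enzyme kinetics.

## The problem

The Hill family

$$\frac{dS}{dt} \;=\; -\,\frac{v_{\max}\,S^{\,n}}{K_m + S^{\,n}}$$

describes enzymatic depletion of a substrate concentration *S* (mM) over
time (min); the order *n* — the Hill coefficient — encodes the
cooperativity of the reaction, with *n* = 1 giving Michaelis–Menten
kinetics. Deciding *n* from a single noisy time series is hard: over a
typical experimental window the best fits of orders 1, 2 and 3 are nearly
indistinguishable, so the classical root-mean-square residual ρ₀ cannot
separate them.

hillsym implements a complementary, structure-based criterion. In the
dimensionless variables τ = v_max t / K_m^(1/n), y = S / K_m^(1/n) the
model becomes dy/dτ = −yⁿ/(1+yⁿ), and each order n possesses its own
one-parameter Lie point symmetry

$$\Gamma^n_\varepsilon : (\tau, y) \;\mapsto\;
\bigl(-y e^{\varepsilon} + (\tau + y)\,e^{-(n-1)\varepsilon},\;
y e^{\varepsilon}\bigr),$$

which maps order-n solutions to order-n solutions and distorts the
solutions of every other order. The selection statistic ρ(ε) applies a
candidate's symmetry to the data, refits the candidate to the transformed
points, pulls the fit back through the inverse transform, and measures
the RMS misfit (mM) against the original series. For the true order
ρ(ε) stays at ρ₀ (exactly, in the noiseless limit); for a wrong order it
grows with ε. Candidates are compared through replicate-averaged ρ(ε)
curves with one-standard-error bands; when the bands overlap the method
abstains rather than forcing a choice. A validation mode runs the same
pipeline with the time-translation symmetry — shared by all orders — for
which the relative statistic Δ(ε) = ρ(ε)/ρ(0) − 1 must vanish.

The package provides the model and its closed-form first integral
(`hill_model`, `first_integral`, `hill_solution`, `solve_hill`), the
symmetry group machinery and a numerical closure oracle
(`point_transform`, `apply_point`, `compose_transforms`,
`symmetry_defect`), a log-normal-noise simulator of benchmark kinetic
experiments (`default_design`, `generate_replicates`), classical and
symmetry-based selection (`fit_hill`, `classical_selection`,
`rho_curve`, `run_symmetry_selection`, `validate_translation`), and a
command-line interface (`run_cli`, `inst/cli/hillsym.R`).

## Worked example

Simulate five replicate series from a second-order Hill model at the
benchmark settings (v_max = 0.0102 mM/min, K_m = 0.30 mM, S₀ = 2 mM,
multiplicative log-normal noise with σ = 0.1):

```r
library(hillsym)
design <- default_design(2, master_seed = 42)
design
#> Simulation design: Hill order 2 (v_max = 0.0102 mM/min, K_m = 0.3 mM), S0 = 2 mM
#>   15 points on [0, 308.8] min, sigma = 0.1, N = 5 replicates, master seed 42

replicates <- generate_replicates(design)
fit_hill(replicates[[1]], n_fit = 2, fit_options(seed = 42))
#> Hill fit (order 2): v_max = 0.00948059 mM/min, K_m = 0.260643 mM, S0 = 1.92834 mM
#>   rho0 = 0.0521401 mM, converged: TRUE
```

The classical residuals cannot tell the three candidate orders apart:

```r
classical_selection(replicates, 1:3, fit_options(seed = 42))
#> Classical (rho0) model selection verdict
#>   selected order:          none
#>   rejected orders:         -
#>   indistinguishable:       1, 2, 3
```

The symmetry statistic sharpens the comparison — on noiseless data it is
decisive, because the true order's ρ(ε) is pinned at zero by solution-set
closure while the wrong orders deteriorate:

```r
clean <- generate_series(default_design(2, noise = noise_model(0),
                                        n_replicates = 1), 0)
run_symmetry_selection(clean, 1:3, family = "hill", eps_max = 4,
                       eps_points = 9, options = fit_options(seed = 1))
#> Symmetry selection (hill family, eps in [0, 4], 3 candidates)
#> Symmetry-based model selection verdict
#>   selected order:          2
#>   rejected orders:         1, 3
#>   indistinguishable:       -
#>   epsilon range used:      [0, 4]
```

(The window-mean ρ values behind that verdict are 2.6e-02, 1.5e-10 and
2.2e-02 mM for orders 1, 2, 3.) At the full benchmark noise level
(σ = 0.1, 15 samples, N = 5) the one-SE bands of the three candidates
overlap and the verdict is an honest abstention, with the true order
carrying the lowest band (window means 0.0853, 0.0765, 0.0782 mM for
orders 1, 2, 3 at master seed 42); see the methods vignette
(`vignettes/symmetry-model-selection.Rmd`) for why the separation is
noise-limited and which knobs (sampling density first) recover it.

The translation consistency check is exact by construction:

```r
d <- validate_translation(default_design(1, master_seed = 42), 1:3,
                          eps_max = 5, eps_points = 11)
max(sapply(d, function(x) max(abs(x$delta))))
#> [1] 0
```

## Command line

```sh
Rscript inst/cli/hillsym.R simulate --n-sim 2 --seed 7 --out runs/sim
Rscript inst/cli/hillsym.R fit      --data runs/sim --orders 1,2,3 --out runs/fit
Rscript inst/cli/hillsym.R select   --data runs/sim --orders 1,2,3 \
        --family hill --eps-max 10 --eps-points 50 --out runs/select
Rscript inst/cli/hillsym.R validate --n-sim 2 --seed 7 --out runs/validate
```

All randomness is controlled by `--seed`; identical invocations produce
byte-identical outputs. Verdicts and resolved configurations (including
derived horizons and per-replicate seeds) are written as JSON, curves as
tidy CSV.

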