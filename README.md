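# mmrtcp

Activation heat capacity changes (ΔC<sub>P</sub><sup>‡</sup>) in enzyme
catalysis, estimated two ways: by fitting macromolecular rate theory (MMRT)
to temperature–rate profiles, and from enthalpy fluctuations of
reactant-state versus transition-state-analogue ensembles sampled by
molecular-dynamics replicas.

## Who this is for

Enzymologists and simulators who need to quantify why ln(rate) vs
temperature curves bend and where the temperature optimum sits, and to
connect that macroscopic curvature to microscopic energy fluctuations.
The package consumes plain-text rate tables, per-replicate energy tables
and (optionally) coordinate trajectories; it does not run molecular
dynamics or recompute force-field energies.

## The model

MMRT extends transition state theory with a temperature-independent
activation heat capacity change:

    ln k = ln(kB·T/h) − [ΔH‡(T0) + ΔCp‡·(T − T0)]/(R·T)
                      + [ΔS‡(T0) + ΔCp‡·ln(T/T0)]/R

A negative ΔCp‡ makes the Eyring plot concave and produces a finite optimum
at `Topt = (ΔCp‡·T0 − ΔH‡)/(ΔCp‡ + R)` whenever ΔCp‡ < −R. `fit_mmrt()`
solves the (exactly linear) weighted least-squares problem inside a
self-consistency loop that pins the reference temperature to the
experimental convention T0 = Topt − 4 K.

On the simulation side, the equilibrium fluctuation formula
`Cp = ⟨δH²⟩/(R·T²)` turns enthalpy variances into heat capacities, and
ΔCp‡ is the variance difference between the two state ensembles. Because
conformational substate switching inflates naive variances, two protocols
are provided: cluster-occupancy-weighted variances
(`cluster_weighted_variance()`) and moving-window variances with a
window-size convergence scan (`moving_window_variance()`,
`window_scan()`), plus per-region partial ΔCp‡ (`partial_cp()`).
Coordinate support covers Kabsch superposition, pairwise RMSD, K-means and
hierarchical conformational clustering, running-average-reference RMSF and
per-residue two-state significance testing. Synthetic generators with
exact ground truth (`gen_switching_energy()`, `mall_like_experiment()`,
...) back every estimator.

## Worked example

```r
library(mmrtcp)

# --- kinetics route: fit a noisy synthetic profile with known truth ------
gen  <- mmrt_params(dH_T0 = 50, dS_T0 = -0.05, dCp = -11.6, T0 = 316)
prof <- gen_rate_profile(gen, seq(280, 330, 2), noise_sd = 0.05, seed = 1)
fit  <- fit_mmrt(prof)
print(fit)
#> MMRT fit 'synthetic'
#>   dCp  : -11.6519 +/- 0.0723 kJ mol^-1 K^-1
#>   dH_T0: 43.9432 +/- 1.0340 kJ mol^-1 (T0 = 316.47 K)
#>   dS_T0: -0.06906 +/- 0.00327 kJ mol^-1 K^-1
#>   Topt : 320.47 K
#>   residual sd: 0.04803 (ln rate), 1 refits of T0
```

The fitted ΔCp‡ (−11.65 ± 0.07 kJ mol⁻¹ K⁻¹) recovers the generator value
−11.6 within its standard error, and the optimum lands near 320 K — large
negative ΔCp‡ pins Topt just above the reference.

```r
# --- fluctuation route: two-state synthetic experiment at 320 K ---------
exp  <- mall_like_experiment(seed = 1)   # truth: delta_cp = -10
scan <- window_scan(exp$reactant, exp$ts_analogue)
print(scan)
#> Window scan (320 K), 9 windows 5-80 ns
#>  window_ns  delta_cp       sd
#>          5 -9.590620 1.359479
#>         10 -9.549959 1.465263
#>         20 -9.441636 1.700173
#>         30 -9.457070 1.965566
#>         40 -9.497478 2.197615
#>         50 -9.547494 2.365982
#>         60 -9.641316 2.421385
#>         70 -9.712405 2.460968
#>         80 -9.750876 2.438334
#>   plateau: -9.5765 kJ mol^-1 K^-1 over 5-80 ns
```

The moving-window scan is stable across window sizes and its plateau
(−9.58 ± ~0.8 kJ mol⁻¹ K⁻¹ across replicates) recovers the constructed
within-state difference of −10 kJ mol⁻¹ K⁻¹; the per-window `sd` column is
the across-replicate spread of the two states combined in quadrature.

A configuration-driven pipeline (`run_pipeline()`, YAML config; thin CLI in
`inst/scripts/mmrtcp`) chains simulation, kinetics fitting, ΔCp‡
estimation, window scans, partial ΔCp‡, clustering and RMSF, writing tidy
CSV tables and a JSON run report.

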