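---
title: "Activation heat capacity from rate curvature and energy fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation heat capacity from rate curvature and energy fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrtcp)
```

## The scientific problem

Enzyme-catalysed rates do not follow simple Eyring behaviour: ln(rate)
versus temperature is curved, and most enzymes show an intrinsic temperature
optimum $T_{opt}$ that is not explained by unfolding. Macromolecular rate
theory (MMRT) attributes this to a difference in heat capacity between the
enzyme–substrate ground-state ensemble and the enzyme–transition-state
ensemble, the activation heat capacity change $\Delta C_P^\ddagger$. When
$\Delta C_P^\ddagger$ is negative the Eyring plot bends downwards and a
finite optimum appears.

`mmrtcp` implements both routes to $\Delta C_P^\ddagger$:

1. **Kinetics route.** Fit the MMRT expression
   $$\ln k = \ln\frac{k_B T}{h}
     - \frac{\Delta H^\ddagger_{T_0} + \Delta C_P^\ddagger (T - T_0)}{RT}
     + \frac{\Delta S^\ddagger_{T_0} + \Delta C_P^\ddagger \ln(T/T_0)}{R}$$
   to measured temperature–rate profiles (`fit_mmrt()`), with the
   transmission coefficient fixed at 1.
2. **Fluctuation route.** At equilibrium the heat capacity of a state is
   $C_P = \langle \delta H^2 \rangle / (R T^2)$, so the activation value is
   the difference of enthalpy variances between the two state ensembles,
   $\Delta C_P^\ddagger = (\langle\delta H^2\rangle_{TS} -
   \langle\delta H^2\rangle_{RS}) / (R T^2)$ (`variance_cp()`,
   `delta_cp()`). Enthalpies are approximated in practice by solute
   force-field potential energies sampled from replicate molecular-dynamics
   runs; this package consumes those precomputed energy tables and does not
   run or re-evaluate any force field.

All energies are molar (kJ mol^-1^), so the denominator uses the gas
constant $R$ = 8.314462618×10^-3^ kJ mol^-1^ K^-1^ rather than the
per-molecule Boltzmann constant; the formula is otherwise unchanged.

## Fitting conventions for the kinetics route

At fixed reference temperature $T_0$ the MMRT expression is *linear* in
$(\Delta H^\ddagger_{T_0}, \Delta S^\ddagger_{T_0}, \Delta C_P^\ddagger)$,
so each inner fit is solved exactly by (weighted) linear least squares —
there is nothing to gain from an iterative nonlinear optimiser, and no
starting values or convergence tolerances affect the result. The
experimental convention ties the reference to the optimum,
$T_0 = T_{opt} - 4\,K$, but $T_{opt}$ is itself a fit output; `fit_mmrt()`
therefore iterates fit → closed-form optimum → reset $T_0$ until $T_0$
moves by less than 0.01 K (at most 20 refits), starting from the vertex of
a quadratic smooth of the data. Because a change of reference only re-mixes
the design columns, $\Delta C_P^\ddagger$ and its standard error are exactly
invariant to $T_0$; the loop merely fixes the reporting convention for
$\Delta H^\ddagger_{T_0}$ and $\Delta S^\ddagger_{T_0}$. The closed-form
optimum is
$$T_{opt} = \frac{\Delta C_P^\ddagger T_0 - \Delta H^\ddagger_{T_0}}
  {\Delta C_P^\ddagger + R},$$
a maximum exactly when $\Delta C_P^\ddagger < -R$; otherwise the curve is
monotonic and `topt_closed_form()` returns `NA`.

Weighting: when per-point replicate standard deviations of ln(rate) are
supplied they are used as inverse-variance weights; otherwise the fit is
unweighted. Whether the original experimental fits were weighted is not
knowable from a rate table alone, so the choice is explicit, not guessed.
Rates are accepted on the linear or log scale behind an explicit flag,
never auto-detected: silently misreading the scale would corrupt every
downstream number.

## Variance protocols for the fluctuation route

The plain variance over a full trajectory is the right estimator only when
the state occupies a single conformational substate. Switching between
substates with different mean energies inflates the variance by the spread
of the substate means, which is sampling structure, not thermodynamics of a
single basin. Two protocols control this:

* **Cluster-weighted** (`cluster_weighted_variance()`): with frames
  assigned to conformational clusters, the state variance is the
  occupancy-weighted mean of per-cluster variances,
  $\sum_c f_c \mathrm{Var}_c$. With the $n$-denominator convention the law
  of total variance is an exact identity (plain = within + between), which
  the tests assert to machine precision; the default reporting convention
  is the unbiased $n-1$ form per cluster. Per-cluster variances can be
  computed per replicate (default) or pooled across replicates
  (`pooled = TRUE`); both appear in the literature and the difference is
  reported, not hidden.
* **Moving-window** (`moving_window_variance()`): the mean of unbiased
  variances in fixed-length windows slid along the trajectory, independent
  of any clustering. Windows shorter than substate dwell times exclude the
  between-substate term while still counting genuine fast switching. The
  stride defaults to window/10 (90% overlap) — overlap lowers estimator
  noise at no bias cost and is configurable for sensitivity checks, since
  the original protocol does not state it.

`state_variance()` applies either protocol per replicate after discarding a
burn-in fraction (default 10%, mirroring the convention of analysing only
the equilibrated 50–500 ns of 500 ns runs); the state value is the mean
across replicates and its uncertainty the across-replicate standard
deviation. `delta_cp()` differences two states at the same temperature and
combines the two spreads in quadrature — the natural reading of error bars
built from the cumulative spread of independent replicate simulations.
Temperatures always come from trajectory metadata, never inferred from the
energies.

`window_scan()` recomputes the moving-window $\Delta C_P^\ddagger$ over a
ladder of window lengths (default 5–80 ns). Convergence is declared where
three consecutive windows agree pairwise within 5% relative, extended while
the rule holds; the plateau value is the mean over that run. The original
analysis reports convergence over a window range without stating a
criterion, so the rule here is an explicit, documented choice; scans
without a plateau are returned with `plateau_value = NA` rather than
silently picking a window.

`partial_cp()` runs the same machinery on a region's energy column.
Inter-region interaction energies are excluded by construction, so partial
values need not (and in general do not) sum to the total: the gap is
exactly twice the inter-region covariance difference divided by $RT^2$, an
identity the tests verify on generator data with known covariance.

## Coordinate support

Clustering and flexibility analyses operate on Cα coordinates.
`kabsch_superpose()` is the SVD-based least-squares rigid superposition
(proper rotation enforced), feeding `pairwise_rmsd()`. Two clusterers
mirror the two analysis routes: `kmeans_cluster()` (k-means++ seeding,
fixed seed, 10 restarts — deterministic and within 1% of a long
random-restart search in the tests) for a preset cluster count, and
`hierarchical_cluster()` (average linkage by default, single/complete
available) cutting the tree where the smallest inter-cluster linkage
distance exceeds a threshold such as 2.1 Å; the linkage behind the original
"minimum cluster distance" convention is not stated, so it is exposed as
configuration rather than resolved by guesswork.

`running_average_rmsf()` computes per-residue RMSF against a running-average
reference (default window 10 ns): frames are first aligned to a common
frame, each frame is then re-fitted onto the centred moving average of the
coordinates, and fluctuations are measured about that local mean. This
keeps slow conformational drift out of the fluctuation measure. Windows are
truncated at the trajectory ends — the simplest well-defined contract.
`rmsf_state_test()` compares replicate RMSF values per residue between the
two states with a Welch t-test at p < 0.01, unadjusted by default to match
the per-residue flag convention (a Benjamini–Hochberg option is available).
Residues constant in both states get p = 1 (no 0/0), flagged p = 0 only if
the constants differ.

## What the synthetic generators emulate

The generators provide ground truth for every estimator:

* `gen_rate_profile()`: MMRT curves plus iid Gaussian noise on ln(rate),
  optionally with replicate spread.
* `gen_switching_energy()`: a hidden Markov chain over conformational
  clusters with per-cluster means and variances, emitting AR(1)-correlated
  Gaussian energies (stationary within-cluster variance equal to the
  cluster variance). The AR(1) term matters: molecular-dynamics energies
  are autocorrelated, and without it the window-size dependence that the
  scan protocol probes would be trivial.
* `gen_region_energies()`: multivariate Gaussian region streams with a
  specified covariance matrix whose row sums reproduce the total energy
  exactly, enabling exact covariance-decomposition checks for partial
  estimates.
* `gen_toy_trajectory()`: reference coordinates plus basin displacements
  plus isotropic jitter, contaminated with a random rigid motion per frame
  (on by default) so that analyses are forced to superpose honestly.

Two presets mirror the sampling geometry of the two study systems at desk
scale: `mall_like_experiment()` (320 K, 6 substates switching with ~20 ns
dwell, AR(1) φ = 0.8, 10 replicates × 45 000 frames at 10 ps ≡ 450 ns
analysed per run; within-state heat capacities 60 and 50 kJ mol^-1^ K^-1^
so the constructed within-state difference is exactly −10 kJ mol^-1^ K^-1^)
and `ksi_like_experiment()` (300 K, two substates at 75/25% occupancy with
distinct variances, difference −0.86 kJ mol^-1^ K^-1^). Both states share
the substate mean layout and switching kinetics, so the between-substate
contamination largely cancels in the state difference — the situation the
moving-window protocol is designed for. Cluster mean separations (spread
±100 kJ mol^-1^) and dwell times are not quantities the source analysis
reports; they were chosen once as plausible for a protein sampling several
loop conformations and are not tuned thereafter.

What the generators deliberately do **not** emulate: force-field energetics,
solvent, slow non-stationary drift, non-Gaussian within-substate
distributions, and correlations between structural clusters and energy
variance beyond the cluster means/variances supplied. Passing tests
therefore demonstrate estimator correctness under a stationary
Markov-switching model, not the fidelity of any molecular simulation.

## Numerical choices and degenerate inputs

* Unbiased ($n-1$) variances throughout; small moving windows make the
  $n$-denominator bias material. The one deliberate exception is the
  machine-precision law-of-total-variance identity, which holds in the
  population convention and is tested there.
* Moving-window sums use cumulative sums on mean-centred data, so windowed
  variances are O(1) per window and numerically stable for large energy
  offsets.
* `variance_cp` demands ≥ 2 samples; clusters with < 2 frames raise an
  error naming the cluster; windows longer than the series, empty
  selections, temperature mismatches between states and missing region
  columns are all hard errors rather than silent coercions.
* Superposition refuses < 3 atoms or (near-)collinear selections, where
  the rotation is not identifiable.
* Profile validation requires ≥ 5 distinct temperatures; individual
  missing measurements (`NA`) are allowed and dropped at fit time, with
  fewer than 4 usable points an explicit insufficient-data error.

## Problem sizes used in the tests

The shipped test-suite and verification script run entirely from code-built
fixtures: the full two-state scan check uses the complete preset
(10 replicates/state × 45 000 frames), the calibration checks use 100 null
repetitions × 200 residues for the flexibility test and 200 noisy refits
for confidence-interval coverage, and the remaining unit tests use series
of 10^3^–10^5^ points. These sizes give Monte-Carlo errors comfortably
inside the asserted tolerances while keeping a full run in the order of
seconds.

## Known limitations

* The fluctuation route inherits every approximation of its inputs:
  solute-only potential energies as enthalpy proxies, transition-state
  *analogues* standing in for true transition-state ensembles, finite
  sampling. The package quantifies replicate spread; it cannot correct
  systematic error in the ensembles themselves.
* $\Delta C_P^\ddagger$ is assumed temperature independent over the fitted
  range, and no unfolding correction is applied at high temperature.
* The entropy-fluctuation alternative route is not implemented.
* The plateau rule is a heuristic; scans should be inspected (the full
  table is always returned) rather than trusting the plateau value blindly
  when the scan is noisy.

## A worked example

```{r example, eval = FALSE}
# kinetics route on synthetic data with known truth
gen <- mmrt_params(dH_T0 = 50, dS_T0 = -0.05, dCp = -11.6, T0 = 316)
prof <- gen_rate_profile(gen, seq(280, 330, 2), noise_sd = 0.05, seed = 1)
fit <- fit_mmrt(prof)
print(fit)

# fluctuation route on the large-system preset
exp <- mall_like_experiment(seed = 1)
scan <- window_scan(exp$reactant, exp$ts_analogue)
print(scan)
```
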