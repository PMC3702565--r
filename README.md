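# pathfe

Free-energy profiles along principal-curve transition pathways.

Large conformational transitions — the open/closed motion of adenylate
kinase is the textbook case — live in a high-dimensional space: with a
protein represented by its N Cα atoms, a conformation is a point in
D = 3N dimensions. `pathfe` computes a one-dimensional free-energy
profile along a *curved* pathway through that space:

1. **Pathway construction.** Frames from unrestrained trajectories are
   rigid-body aligned, projected onto the straight line between the two
   endpoint structures, binned (100 segments over the observed range),
   and averaged per bin; a smooth sinusoidal curve
   f_i(t) = a_i + b_i·t + Σ_p c_ip·sin(pπt) is fitted through the bin
   averages jointly over coefficients and node parameters, then
   reparametrized by arc length so the curve parameter α ∈ [0, 1] is
   proportional to distance along the pathway (length L).
2. **Tangent-only umbrella sampling.** Window i anchors at
   Z(α_i) with a harmonic bias U = (K/2)[(x − Z_i)·e_i]² acting *only*
   along the frozen unit tangent e_i — perpendicular motion is
   unrestrained, so F(α) integrates out the tube cross-section. In
   curve-parameter units the stiffness is κ = K·L² (0.08 kcal/mol/Å² on
   a 197.2 Å pathway gives κ ≈ 3,111 kcal/mol). Harmonic center and
   orientation-angle restraints remove the six rigid-body degrees of
   freedom.
3. **Hamiltonian replica exchange.** Adjacent windows attempt to swap
   biases on a fixed schedule (alternating pairing phases), accepted
   with the Metropolis rule on the combined-Hamiltonian change.
4. **WHAM.** The biased α histograms are combined by the self-consistent
   weighted-histogram iteration into F(α) = −kT·log p(α),
   minimum-shifted, with block-averaged mean-coordinate errors
   propagated along the window chain relative to window 1.

A toy layer — overdamped Langevin dynamics, analytic curved-valley and
double-well potentials, a synthetic-ensemble generator, and a
brute-force quadrature oracle for F(α) — makes the entire pipeline
testable without a molecular-dynamics engine. Analysis utilities cover
projection time series, domain-center distances (LID/AMPbd/CORE
built-in), trailing-mean RMSD tables, and hydrogen-bond-based
salt-bridge detection.

## Worked example

The packaged validation study runs the full pipeline on a 2D curved
valley (a semicircular channel of radius 3 with a 4 kT tilt imposed
between its ends, kT = 1):

```r
library(pathfe)
study <- toy_free_energy_study("tilted", seed = 1, n_cycles = 2000)
study$curve
#> <path_curve> D = 2, P = 2, L = 9.5046, uniform (arc-length) parametrization
#>   fit objective 0.394058 after 1192 iteration(s)
study$run
#> <hrex_run> 30 window(s), 2000 cycle(s), swap acceptance 61.8%
glance(study$profile)
#> # A tibble: 1 × 8
#>   n_bins n_windows n_samples    kT iterations converged barrier alpha_min
#>    <int>     <int>     <int> <dbl>      <int> <lgl>       <dbl>     <dbl>
#> 1    120        30     45000     1        775 TRUE         8.54     0.968

profile_rms(study$profile, study$reference)$rms
#> [1] 0.1801994
```

Reading the output: the principal curve recovered from the noisy
synthetic ensemble is 9.5 length units long; 30 umbrella windows with
replica exchange (62% swap acceptance — well-overlapping windows)
produced 45,000 α samples; WHAM converged in 775 iterations. The
reconstructed profile descends ~4 kT from the α = 0 end to the minimum
near α = 1, mirroring the imposed tilt, and agrees with the brute-force
quadrature oracle to 0.18 kT RMS at this demonstration length (the
default 8,000-cycle study used by `scripts/acceptance.R` is tighter).
`autoplot(study$profile)` draws F(α) with its error ribbon; `tidy()`
returns the profile as a tibble.

For protein work the same verbs chain over real input:
`read_pdb_ca()` → `bin_and_average()` → `fit_curve()` →
`reparametrize()` → `window_layout()` → (sampling with the exported
restraint energies/forces in your engine of choice) → `wham_1d()` →
`wham_error()`, with `projection_timeseries()`, `domain_distances()`,
`rmsd_table()` and `detect_salt_bridges()` for trajectory analysis. A
thin CLI wraps the same functions
(`inst/cli/pathfe build-path | project | windows | toy-run | wham |
analyze`).

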