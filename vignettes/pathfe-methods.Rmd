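---
title: "Free-energy profiles along principal-curve pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy profiles along principal-curve pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pathfe)
```

## The problem

Large conformational transitions of proteins — the open/closed motion of
adenylate kinase is the canonical example — are intrinsically
high-dimensional: with the molecule represented by the positions of its N
Cα atoms, a conformation is a point in a D = 3N dimensional space
(D = 642 for a 214-residue kinase). Unrestrained simulations visit a
"transition tube" connecting the two endpoint states, but they rarely
cross the free-energy barriers often enough to yield converged
thermodynamics. `pathfe` implements a workflow that (i) condenses
unrestrained trajectories into a single smooth curve through the middle
of the visited region — a principal curve, (ii) defines one collective
variable α ∈ [0, 1], the normalized arc length along that curve, (iii)
samples biased distributions in overlapping umbrella windows restrained
*only along the curve tangent*, with Hamiltonian replica exchange between
adjacent windows, and (iv) reconstructs the one-dimensional free-energy
profile F(α) with WHAM, including propagated statistical errors.

Because the restraint acts only along the pathway direction, all
perpendicular degrees of freedom remain unbiased, and F(α) is a true
one-dimensional free energy with the tube cross-section integrated out —
in contrast to string-method profiles defined on the full set of coarse
coordinates.

## Building the pathway

1. **Straight-line projection.** Each (rigid-body aligned) frame x is
   projected onto the line joining the two endpoint structures:
   λ = (x − a)·(b − a)/|b − a|². The observed range [min λ, max λ] — not
   [0, 1] — is divided into `n_bins` equal segments (default 100,
   giving the M + 1 = 100 groups of the standard configuration). Using
   the observed range is why the final curve can extend beyond the
   endpoint structures when the simulations explored further; empty
   segments are dropped, since a mean over zero frames is undefined and
   the fit below does not require uniform node spacing.
2. **Bin averaging.** The component-wise mean of the frames in each
   segment gives an ordered chain of nodes through the center of the
   visited region (`bin_and_average()`).
3. **Smooth fit.** Per dimension i, the curve is
   f_i(t) = a_i + b_i t + Σ_{p=1..P} c_{ip} sin(pπt), fitted by
   minimizing Σ_k |Z(t_k) − node_k|² jointly over the coefficients and
   the per-node parameters t_k (`fit_curve()`). The optimization
   alternates an exact linear least-squares solve for the coefficients
   with bounded one-dimensional minimization of each interior t_k;
   endpoints are pinned at t = 0 and t = 1. Each half-step cannot
   increase the objective, so the iteration is monotone; it stops when
   the relative improvement falls below `tol` (default 1e-10) and errors
   out after `max_iter` (default 500) iterations with the last objective
   value. t_k are initialized proportional to node order, which is
   correct because nodes are ordered by λ. The global sinusoidal basis
   is infinitely differentiable, which the tangent linearization below
   relies on; P = 1 gives a gently curved pathway appropriate for
   protein transitions, while tightly bent test valleys need P = 2–3
   (see *Toy systems*).
4. **Arc-length reparametrization.** The arc length s(t) = ∫|dZ/dt'|dt'
   is tabulated at 2,001 points by per-cell Simpson quadrature on the
   analytic speed, and inverted with a monotone (Hyman-filtered) cubic
   spline, giving the uniform parameter α with s = αL
   (`reparametrize()`). After reparametrization |dZ/dα| = L uniformly,
   so equal steps in α are equal steps along the pathway. `arc_length()`
   itself uses adaptive quadrature (rel. tol 1e-10). A non-monotone arc
   table (a numerically degenerate fit) is an error.

## Tangent-only umbrella restraints

The projection operator Π(x) returns the α of the curve point nearest to
x; `project()` finds the global minimum by a ≥ 201-point grid scan plus
bounded refinement, clamping to the boundary for points beyond either
end (rarely relevant, because the curve deliberately extends past the
endpoint structures). Near a window anchor Z_i = Z(α_i) the curve is
approximated by its tangent line, making the projection linear:
α_lin = α_i + (x − Z_i)·e_i / L, with e_i the unit tangent. The umbrella
potential in window i is then

U_i(x) = (K/2) d²,  d = (x − Z_i)·e_i,

equivalently (κ/2)(α_lin − α_i)² with κ = K·L². With the production
values K = 0.08 kcal/mol/Å² and L = 197.2 Å this evaluates to
κ ≈ 3,111 kcal/mol. The force −K·d·e_i acts strictly along the frozen
window tangent: displacements perpendicular to e_i contribute exactly
zero energy, which is the defining property of the method. The tangent
is frozen per window (evaluated at α_i); the nonlinear `project()` is
used for analysis and reporting only, never for forces. The
approximation is controlled by how little the tangent rotates over one
window spacing; `window_layout()` places `n_windows` (default 30)
windows at α_i = (i−1)/(n_windows−1), i.e. spacing 1/29.

Because U_i is a function of raw Cartesian coordinates it is not
invariant under rigid-body motion; `rigid_body_restraint()` removes the
six rigid-body degrees of freedom with a harmonic centroid restraint
(default 1,000 kcal/mol/Å²) and a harmonic restraint on the orientation
angle (default 200 kcal/mol/degree²). The orientation angle is defined
here as the rotation angle θ of the optimal (Kabsch) superposition of
the instantaneous structure onto the reference, extracted from the
rotation-matrix trace, cos θ = (tr R − 1)/2 — a unique axis-free scalar,
smooth near 0, in the stated units. No closed-form coordinate gradient
of θ through the SVD is exposed, so the orientation term's gradient is
evaluated by central finite differences (step 1e-5 Å); the centroid
gradient is analytic. Superposition itself (`kabsch_align()`) always
returns a proper rotation: if the SVD solution would be a reflection,
the sign of the singular vector with the smallest singular value is
flipped.

## Hamiltonian replica exchange

At a fixed interval (400 fs in the production setting; `steps_per_cycle`
Langevin steps in the toy engine) two adjacent windows i, j attempt to
swap their restraining potentials. The change in the combined
Hamiltonian is Δ = [u_i(x_j) + u_j(x_i) − u_i(x_i) − u_j(x_j)]/kT, and
the attempt is accepted if Δ ≤ 0, otherwise with probability exp(−Δ).
Pairing alternates between the (1,2),(3,4),… and (2,3),(4,5),… phases —
a standard non-conflicting schedule; the original description says only
that adjacent simulations attempt swaps, so the alternation is a design
choice here. Swaps exchange bias assignments rather than configurations
(equivalent and cheaper); samples are recorded per *window*, which is
what WHAM consumes. Every propagation call receives a deterministic
per-(replica, cycle) sub-seed, so a run is reproducible from its seed
and, with exchange disabled, bit-identical to independent umbrella
sampling. kT defaults to 0.5962 kcal/mol (300 K) in protein-facing
paths and to 1 in toy paths.

## WHAM and error estimation

`wham_1d()` implements the standard self-consistent weighted-histogram
iteration over `n_bins` (default 200) bins spanning the sampled α range:

p_m = n_m / Σ_i N_i exp[(f_i − u_i(α_m))/kT],
f_i = −kT log Σ_m p_m exp[−u_i(α_m)/kT],

iterated until max|Δf_i| < 1e-8 kT (at most 1e5 iterations; failure to
converge is an error carrying the residual). The profile is
−kT log p, shifted so its minimum is zero. The default 200 bins give
about 7 bins per window spacing in a 30-window layout, balancing
histogram bias against per-bin variance. The first 25% of each window's
series is discarded as equilibration by default, mirroring the
discard-first-quarter convention of the production runs; adjacent
windows whose histograms share no occupied bin trigger a warning.

Errors (`wham_error()`) follow the mean-coordinate scheme: the
uncertainty of each window's mean sampled α is estimated by block
averaging (default 10 contiguous blocks — insensitive to within-block
autocorrelation, unlike the naive σ/√n), converted to a mean-force
uncertainty κ·se(ᾱ_i), propagated across each adjacent-window link with
the trapezoid rule, and accumulated in quadrature along the chain. The
reported errors are therefore free-energy-*difference* errors relative
to the first window and grow monotonically away from it; bin-level
errors are interpolated from the window chain. The precise propagation
formula comes from the cited error-estimation literature rather than
being restated in the original description; the block-averaged
mean-coordinate scheme here follows that reference.

Free-energy profiles are defined only up to an additive constant. All
profile comparisons in the package (`profile_rms()`) therefore fix the
gauge by mean-aligning the two profiles over the compared range;
min-shifting would let a single noisy bin shift the whole comparison.

## Toy systems: what they emulate and what they do not

The toy layer replaces the all-atom molecular-dynamics engine for
validation purposes:

* `run_langevin()` — overdamped Euler–Maruyama dynamics,
  x ← x − (dt/γ)∇V + √(2kT·dt/γ)·ξ. Overdamped (not inertial) dynamics
  suffices because only equilibrium sampling matters for WHAM
  validation. The Euler–Maruyama stationary distribution carries an
  O(k·dt/γ) variance inflation in a harmonic well of stiffness k; the
  pipeline uses dt small enough that this bias is a few per mille of
  the thermal width.
* `curved_valley_potential()` — a 2D surface whose minimum-energy valley
  is a circular arc (radius 3, wall stiffness 25 in kT units by
  default, perpendicular thermal width 0.2), with an optional linear
  tilt along the arc (imposing an exact end-to-end energy difference)
  or a harmonic angular trap (a single-well variant). The polar-angle
  branch cut points along the negative y-axis, far from anything
  sampled. Toy coordinates are raw (no rigid-body alignment): these
  potentials are not translation-invariant, so the rigid-body
  restraints are exercised separately on bead ensembles.
* `make_synthetic_ensemble()` — frames at uniform path parameters along
  a known path (straight line, chord-plus-sine-bulge "arc", or true
  semicircle) plus i.i.d. Gaussian coordinate noise, with the
  generating path retained for assertions. The sine-bulge arc is
  exactly representable in the P = 1 curve basis, so pipeline-recovery
  tests on it isolate pipeline error from basis-representation error;
  the semicircle is *not* representable at P = 1 (the best P = 1 fit
  sags about 13% of the radius at the quarter points) and is used
  precisely to exercise that regime.
* `reference_free_energy()` — the brute-force oracle: F(α) =
  −kT log ∫ exp(−V/kT)·1[Π(x) ∈ bin(α)] dx on a dense spatial grid
  (dims ≤ 3; Monte-Carlo integration with the box volume otherwise).
  Points are deposited with cloud-in-cell weighting between the two
  nearest α-bin centers, which suppresses the aliasing that plain
  nearest-bin assignment produces when the curve runs parallel to a
  grid axis. `check = TRUE` recomputes at half resolution and errors
  out if the RMS change exceeds a tolerance.
* `boltzmann_sample_1d()` — inverse-CDF draws from exp(−V/kT) on a
  32,768-point grid with linear interpolation inside cells; the
  discretization is far below any downstream histogram resolution, so
  the draws serve as exact-reference Boltzmann samples.

What passing toy tests do **not** show: anything about force-field
accuracy, solvent effects, sampling convergence at all-atom time
scales, or the adequacy of a single transition tube for a real protein
— the original study's own discussion notes that multiple pathways and
off-tube metastable states are beyond a single-curve description. The
toys validate the *estimators and the machinery*, not the biology. In
particular, the production-scale results for adenylate kinase (the
free-energy minimum near the open state at α ≈ 0.43 and the ≈ 13
kcal/mol penalty of the closed state) require 30 × 40 ns of all-atom
sampling and are not reproducible at desk scale.

## The packaged validation study

`toy_free_energy_study()` freezes the full-pipeline validation
conditions: tilted (4 kT) or single-well curved valley at kT = 1;
a 4,000-frame semicircle ensemble with σ = 0.2 noise; 100 projection
bins; P = 2 fit (the semicircular valley bends too tightly for one sine
mode; P is a per-system choice and the gently curved production pathway
used P = 1) with tol 1e-9 and up to 2,000 iterations (alternating
descent on noisy nodes needs more than the default budget); 30 windows
with K = 5. K was chosen from sampling theory, before any end-to-end
results were inspected: the statistical error of the mean-force chain
grows as √κ while window overlap needs σ_α = √(kT/κ) comparable to the
spacing, so a κ giving σ_α ≈ 1.5 spacings (κ ≈ 430 here) is the
desk-scale sweet spot — much softer than the production κ/kT ≈ 5,200,
which is affordable only with nanoseconds of sampling per window.
Langevin dt = 0.003, 25 steps per exchange attempt, 8,000 cycles
(2,500 for the single-well variant), first quarter discarded; WHAM on
120 bins; quadrature oracle on a 300² grid. The imposed end-to-end ΔF
is measured between the WHAM values at the projections of the two
valley-floor endpoints: by the mirror symmetry of the valley the
entropic end contributions cancel in that difference, leaving the tilt.

## Numerical choices and degenerate inputs

* Kabsch with < 3 atoms, mismatched dimensions, or a zero-extent
  reference: error. Planar/collinear sets are handled by the
  determinant sign correction.
* `line_project()` with coincident endpoints, `bin_and_average()` with
  zero projection range, `fit_curve()` with fewer than P + 2 nodes,
  `tangent()` on a non-reparametrized curve or vanishing derivative,
  non-monotone arc tables, non-positive spring constants, kT ≤ 0:
  all errors, not warnings.
* `fit_curve()` tie-break: a t_k update is accepted only if it strictly
  improves that node's distance, so the objective is non-increasing
  even when `optimize()` returns a slightly worse interior point.
* Langevin trajectories that leave the finite range abort with the step
  index.
* All file writers emit a header with the package version, a hash of
  the generating configuration, and the seeds involved; α is
  dimensionless, lengths are in Å, energies in kcal/mol on protein
  paths and kT units on toy paths; residue numbering is 1-based and
  coordinates are stored atom-major (x, y, z per atom).

## Limitations

* The orientation-angle gradient is finite-difference, making the full
  rigid-body gradient O(D) energy evaluations; acceptable for analysis
  and toy sampling, not tuned for production MD (the package does not
  integrate with an MD engine by design).
* WHAM is histogram-based; a binless MBAR estimator is used only as an
  independent cross-check oracle in the test suite, per the package's
  scope.
* The salt-bridge detector's hydrogen-free fallback (heavy-atom
  distance plus an antecedent-carbon collinearity proxy, flagged in the
  output) is a geometric surrogate, not a substitute for explicit
  hydrogen-bond geometry. The defaults — donor–acceptor ≤ 3.5 Å,
  donor–H···acceptor angle ≥ 130° — implement the "highly directional
  and specific hydrogen bond" principle with the field's customary
  cutoffs, since no numeric values are fixed by the method description;
  occupancies are reported raw, with no "frequent/occasional" labels.
* Equal per-frame weighting is assumed when several ensembles are
  binned together, and Table-style trailing means expose the averaging
  window as an explicit argument (`last_fraction`) because a fraction
  is ambiguous across runs of different lengths.
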