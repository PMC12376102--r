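---
title: "Models and methods behind metakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`metakin` implements the thermodynamic and kinetic analysis chain used to
study drug--DNA deintercalation with well-tempered metadynamics
(WT-MetaD) over two collective variables: the signed projection `X` of
the ligand--site vector onto a groove-directed unit vector (angstrom) and
the angle `theta` between that vector and the long axis of the ligand's
intercalating ring system (degrees).  The chain is: reconstruct the
free-energy surface (FES) from deposited Gaussian hills; locate basins
and the dividing saddle; reduce to a 1D potential of mean force; compute
the standard binding Gibbs energy by Boltzmann-ratio integration with a
standard-state correction; turn biased trajectories into physical
residence times through the acceleration factor; fit Poisson statistics;
invert the Eyring relation; transfer rates across temperature; and score
states with SASA-based solvation descriptors.

Because no all-atom trajectories accompany the analysis, the package
ships a 2D overdamped Langevin engine on analytic model landscapes.  It
plays the role the molecular dynamics engine plays in production work,
with one decisive advantage: every quantity the analysis estimates has an
exact analytic or brute-force counterpart, so the whole chain is testable
end to end.

# The model landscapes

A `model_potential` is a sum of 2D Gaussians plus a baseline fixed at the
unbound plateau (0 kJ/mol).  `build_three_state_potential()` composes the
canonical deintercalation topology: an intercalated basin at small
`X`/high `theta`, a minor-groove basin at larger `X`/lower `theta`, and a
barrier between them.  Default geometry places the basins at
(2.04 A, 162.0 deg) and (8.20 A, 95.4 deg) with the transition point at
(5.04 A, 146.2 deg), the arrangement characteristic of anthracycline
deintercalation.

The barrier deserves a note.  A single Gaussian bump at the transition
coordinates would be a local *maximum* along the dividing ridge, and
diffusive paths would simply bend around it in `theta`.  The builder
therefore uses an `X`-ridge that is uniform in `theta` (amplitude twice
the requested barrier) plus a negative notch (minus the barrier) at the
transition point.  The ridge blocks every path; the notch makes the
requested point the cheapest crossing.  The saddle then sits at the
requested coordinates, close to `barrier` kJ/mol above the plateau.

Two landscapes ship as defaults:

* `"test"` -- basin depths of -5 and -2.5 kBT, saddle about +1 kBT, at
  310 K; the escape barrier of about 6 kBT makes unbiased escape
  observable in seconds of compute, which is what permits the oracle
  comparisons below.
* `"production"` -- depths of -63 and -31.5 kJ/mol and a +13 kJ/mol
  saddle, magnitudes representative of drug--DNA complexes.  It exists
  for demonstration; unbiased escape over a ~76 kJ/mol effective barrier
  is unobservable at desk scale, exactly as in the real systems.

# The Langevin engine

The collective variables are slow, diffusive modes, so the engine
integrates the overdamped (position) Langevin equation per CV:

    ds = -(D / kBT) * dG/ds * dt + sqrt(2 D dt) * N(0,1)

with reflective walls (`X` in [0, 20] A by default; `theta` in
[0, 180] deg, the arccosine range, treated as non-periodic).  Defaults
`D_X = 0.1 A^2/ps`, `D_theta = 10 deg^2/ps` and `dt = 0.05 ps` keep the
per-step drift a small fraction of the basin width (the basin relaxation
times are 3--4 ps, hundreds of steps).  Inertial dynamics would add a
momentum relaxation scale without changing either the stationary
distribution or the escape statistics, which are all the analysis
consumes.

WT-MetaD deposition follows the standard rule: every `stride` ps a
Gaussian hill of height `h0 * exp(-V(s)/(kB deltaT))` and widths
(`sigma_X`, `sigma_theta`) is added at the current CVs.  The engine
accumulates the bias (value and both analytic derivatives) on a grid of
spacing `sigma/5` with bilinear interpolation, so a step costs O(1)
regardless of the hill count; the hills themselves are kept exactly and
written in the PLUMED text dialect (`#! FIELDS time X theta sigma_X
sigma_theta height biasf`).  Determinism is strict: the R RNG drives the
noise, per-run seeds are `base seed + run index`, and regenerating with
the same seed reproduces trajectories and HILLS files byte for byte.

Hill parameters default to the production values used for the DNA
complexes: `h0 = 0.25` kJ/mol, `sigma_X = 0.25` A, `sigma_theta = 2.06`
deg, `deltaT = 5115` K (bias factor 17.5 at 310 K), six runs.  The
deposition stride is the one parameter that cannot carry over: it must be
scaled to the synthetic time base.  We set it to 20 ps, roughly five
basin correlation times, which preserves the property the residence-time
rescaling depends on -- the bias is quasi-static on the timescale of
basin relaxation, so hills are almost never deposited mid-crossing.

# FES reconstruction and binding free energy

The well-tempered estimator is applied to the final bias:
`G(s) = -(T + deltaT)/deltaT * V(s, t_final)`, i.e. `-gamma/(gamma-1) V`.
No time averaging is applied -- the standard estimator, chosen because a
specific averaging window is not part of the method being reproduced.
The surface is shifted by a constant so its mean over the unbound mask is
zero, the conventional zero of the unbound plateau.  The default grid
(0.1 A by 1 deg over [0, 14] A x [0, 180] deg) resolves the hill widths.

Basins are strict 8-neighbourhood local minima, merged within
0.5 A / 5 deg into the deeper one; because a converged-but-noisy surface
can split one physical basin into near-degenerate grid minima, analyses
that compare basin depths should match minima to expected basin locations
(as the validation suite does) rather than take the two deepest rows
blindly.  The saddle between the two deepest basins is estimated by
bisecting the lowest level at which they become connected on the grid.

The 1D PMF integrates `theta` out by Boltzmann weighting with the
trapezoidal rule, guarded by max-subtraction, and is re-zeroed on the
plateau.

The standard binding Gibbs energy is the two-region Boltzmann ratio

    dG_bind = -RT ln( I_b / I_ub ) - RT ln( C_std / C_site )

with both integrals evaluated by the 2D trapezoidal rule over masked
cells (a cell contributes only when all four corners are inside the
mask).  The estimator is exactly invariant under constant shifts of the
surface.  Default masks derive from the 1D PMF: bound is everything below
the barrier top, unbound everything beyond the last X at which the
profile deviates from zero by more than 0.5 kJ/mol; both are
configurable, and an exclusion mask (for nonstandard-contact regions at
low X and low theta) can be supplied by the user.  `C_site` depends on
the simulation box, not on the FES, so it is a required input; its
default (one site per 10^6 A^3, about 1.66 mM) is a documented
placeholder.  Run-level aggregation reports mean and SEM over `N_run`
independent runs; SEM over runs (not blocks) is used throughout.

# Kinetics

The acceleration factor is the running mean of the exponentiated
instantaneous bias, `alpha(t_n) = (1/n) sum_{i<=n} exp(V_i/kBT)`,
computed per frame (time-weighted if frames are unequally spaced).  This
is the standard infrequent-metadynamics estimator.  A kinetic transition
shows up as an abrupt kink in `log alpha` versus time; the detector fits
two least-squares segments at every candidate split (O(1) per candidate
via cumulative sums) and accepts the best split when it removes at least
20% of the single-line SSR -- a threshold that rejects noise kinks on
flat series and accepts planted kinks, both covered by tests.  The kink
is cross-checked against the first frame at which the CVs leave the
bound region, which backs it up whenever the bias history is too smooth
to pinpoint.  The rescaled physical residence time is
`t* = t_trans * alpha(t_trans)`.

The mean residence time is the SSR-minimising `tau` of the exponential
CDF fitted to the empirical CDF of the rescaled times, scanned on a
logarithmic grid of 1000 points spanning 0.01x to 100x the sample mean
and refined once around the argmin.  A two-sample Kolmogorov--Smirnov
test against an equal-size draw from the fitted exponential (fixed
internal seed, so p-values reproduce) validates the Poisson picture.

The Eyring relation `k = kappa (kBT/h) exp(-dG/RT)` with `kappa = 1` maps
`tau` to an activation free energy; applying it at two temperatures with
the same `dG` and `kappa` transfers residence times across temperature.
Constants are CODATA (`kB = 1.380649e-23` J/K, `h = 6.62607015e-34` J s)
with `R = 8.314` J/mol/K.

# Solvation descriptors

SASA uses Shrake--Rupley sphere-point sampling with a deterministic
golden-spiral point set (960 points/atom by default) against
neighbour-sphere occlusion; radii (C 1.70, N 1.55, O 1.52, P 1.80,
S 1.80, H 1.20 A) and the 1.4 A probe are configurable, since the
production analysis does not pin them down.  Polarity follows the
carbon/phosphorus rule: C, P and hydrogens bonded to carbon are nonpolar,
everything else polar; bonds are inferred by the covalent-radius
criterion (r1 + r2 + 0.4 A) when not supplied.  The hydrophobic model is
the heat-capacity correlation `dCp = 0.382 dSASA_np - 0.121 dSASA_p`
(cal/mol/K) with `dG_hpb = 80 dCp` (cal/mol), converted once to kJ/mol
with 4.184 J/cal.  Proximity counts use an inclusive cutoff from the
reference centre of mass (5.0 A convention for waters and sodium ions,
with the water oxygen as the representative atom).  Hydrogen bonds use
the common 3.5 A donor--acceptor / 30 deg H--D--A convention, flagged as
an assumption because the production criterion is not printed.

# What the synthetic validation shows -- and what it does not

The validation suite establishes, on the `"test"` landscape with three
(FES) and twenty-four (kinetics) independent runs:

* the reconstructed basin-to-basin free-energy difference agrees with
  the analytic landscape within 0.5 kBT per seed (10^7 steps, 25,000
  hills per run);
* the mean rescaled residence time agrees with 200 unbiased
  first-passage runs within overlapping 95% bootstrap intervals, and the
  rescaled times pass the exponential KS test;
* the binding-energy quadrature matches an independently coded 10x-finer
  quadrature to 1e-4 kJ/mol, and is exact on the square-well closed form;
* the SSR estimator recovers the scale of exponential data within 10%
  (and the dense-scan oracle within 2%), and sphere-point SASA matches
  closed-form and dense-grid references within 1--2%.

These demonstrate the correctness of the estimators, not the realism of
the model.  The Langevin landscape has two CVs and no orthogonal slow
modes, no hill-deposition artifacts from hidden degrees of freedom, no
force-field error, and escape barriers of ~6 kBT rather than ~30 kBT.
Agreement here therefore validates the analysis chain; it cannot certify
that two CVs suffice for a particular molecular system, which is a
modelling judgement outside the package's scope.  The published MD-scale
numbers that depend on the all-atom ensemble (basin coordinates of real
complexes, binding energies, the 310 K residence times, descriptor
tables) are inputs or context, not reproduction targets, except where
they follow from printed inputs by closed-form steps (the Eyring
inversions and temperature transfers, which the package reproduces to
print precision).

# Numerical and design choices worth knowing

* Bias-grid spacing `sigma/5` keeps interpolation error in deposited
  heights below 0.5%; the exact hill list, not the grid, is what
  reconstruction uses.
* `evaluate_bias()` performs the exact O(hills x points) sum with no
  distance cutoff, so it doubles as the reference for everything else.
* Dot products are clamped to [-1, 1] before arccosines; Boltzmann
  integrals are max-subtracted; reflective walls fold displacements back
  rather than clipping them.
* Problem sizes in tests and the acceptance script (10^7-step FES runs,
  24 kinetics runs, 200 oracle runs) were chosen as the smallest sizes at
  which the statistical tolerances above are comfortably met; they
  complete in a few minutes on one CPU.
* Whether centres of mass are mass-weighted is not specified for the
  production CVs; mass weighting (the PLUMED convention) is the default,
  with a unit-mass mode for geometric fixtures.
* The kinetics stage of `run_pipeline()` interprets the synthetic clock
  in ps and converts to seconds only at the Eyring step; on model
  landscapes the resulting "activation energies" are properties of the
  model, not of any molecular system.

# Known limitations

* Reweighting with time-dependent bias offsets, multi-walker runs and
  Markov-state analyses are out of scope.
* The FES estimator uses the final bias; for very short runs a
  time-averaged estimator would be less noisy, but also less standard.
* `theta` is treated as non-periodic on [0, 180] with reflective walls,
  which matches its arccosine origin but means basins touching 0 or 180
  are halved; the default landscapes keep basins away from the edges.
* The H-bond and SASA conventions are assumptions where the production
  protocol is silent; both are parameters, not constants.
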