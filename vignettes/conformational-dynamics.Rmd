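---
title: "Models, estimators and design choices in confdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in confdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdyn)
```

`confdyn` implements the analysis layer of a multiscale study of two-domain
protein dynamics: elastic-network modes, mode-guided ensembles, essential
dynamics with convergence diagnostics, collective-variable geometry,
replica-exchange ladder design, and free-energy reweighting. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does not
establish about real data.

## Geometry conventions

All internal lengths are in Angstrom; any nanometre presentation is a
formatting concern of the caller (the bound-state threshold, for instance, is
40 Å = 4 nm). Author PDB residue numbering is kept verbatim. Superposition is
the Kabsch least-squares fit with the determinant correction, so reflections
are always rejected; the fitted rotation and translation are returned so the
same transform can be applied to atoms outside the fitted selection.

One convention deserves a note: `inertia_axes()` orders axes by ascending
principal moment and flips each axis so its largest-magnitude component is
positive. A per-axis sign rule and right-handedness can conflict; when they
do, the largest-moment axis is flipped to restore a right-handed triad. All
angular collective variables built on these axes are insensitive to this
choice as long as it is applied consistently, which is also why eigenvector
sign conventions matter for reporting mode/PC projection tables: signs of
individual projections are only reproducible up to the convention used.

## Anisotropic network model

The ANM models the Cα skeleton as beads joined by identical springs within a
cutoff. Defaults are the field-standard cutoff 15 Å and spring constant 1.0,
and 20 retained non-trivial modes. The zero-mode threshold is
`1e-6 * max(eigenvalue)`, configurable; a connected network has exactly six
eigenvalues below it (the rigid-body motions), and the first non-trivial mode
is numbered 1. Eigenvalues are in arbitrary spring units — only ratios and
mode shapes are meaningful.

Dense symmetric eigendecomposition is used throughout. That is exact and
simple, and adequate into the low thousands of residues; a sparse path would
only matter far beyond the problem sizes this package targets.

## Mode-guided ensemble generation

`run_generations()` iterates deform / cluster / relax. Deformation draws
coefficients uniformly on the unit sphere of the selected mode subspace and
scales them so the Cα RMSD from the parent is exactly the target (1.0 Å
default): for an orthonormal mode basis the displacement norm equals the
coefficient norm, so the scaling is algebraic, not iterative. The cluster
schedule is linear; because "10 to 510 in increments of 10" holds 51 values
while there are 50 generations, the default is `10 * g` for generation
g = 1..50, configurable if the 510th value is wanted.

Clustering is k-medoids (`cluster::pam`) on the pairwise Cα RMSD matrix, so
every representative is a real ensemble member. Children per parent is
`ceiling(2 * schedule[g] / n_parents)` — modest oversampling before
clustering.

The relaxer is pluggable. The built-in `relaxer_elastic()` performs monotone
steepest descent on the reference-network elastic energy plus a soft-sphere
clash penalty; backtracking guarantees the energy never increases. This keeps
the whole cycle testable at desk scale, but it is *not* a force field: it
regularises geometry rather than producing thermodynamically weighted
conformers. An all-atom implicit-solvent minimiser with brief heating can be
supplied through the same interface where that fidelity is needed.

Per-domain distortion uses per-domain superposition before the RMSD — each
domain is fitted onto its own reference before being scored — because global
superposition would mix interdomain motion into the distortion signal.

## Essential dynamics and convergence

`fit_pca()` superposes frames onto a reference over the analysis selection
(Cα by default), then eigendecomposes the sample covariance (denominator
n − 1) of the flattened displacements. Variance fractions are against the full
covariance trace, so they are meaningful even when only 20 components are
kept.

The cosine content uses trapezoidal quadrature for both integrals; at 1000
samples the defining case (a half-period cosine) evaluates to 1 within 10⁻⁶,
comfortably inside the 10⁻³ check.

The covariance overlap is evaluated as
`1 - sqrt(||sqrt(A) - sqrt(B)||_F^2 / (tr A + tr B))` on the truncated
spectral forms. This is algebraically identical to the familiar double-sum
formula but numerically far better behaved: the double sum cancels
catastrophically for near-identical models (an exact identity comparison
comes out ~1e-8 away from 1), while the Frobenius form is exactly 1 for
identical inputs. Models are truncated to their leading 20 eigenpairs by
default, matching the number of components computed.

Block-convergence analysis (`bcom_convergence()`) compares contiguous-block
PCA models against the full-trajectory model and normalises by a bootstrap
baseline at matched sample size — frames sampled with replacement from the
whole trajectory — which removes the finite-sample bias of the overlap
statistic; the bootstrap is plain i.i.d. resampling (not block bootstrap),
which is exactly what makes it a *time-correlation-free* baseline. The
inverse of the normalised curve is fitted with
`c0 - sum a_k exp(-L / t_k)` (three exponentials) by Levenberg-Marquardt from
8 log-spaced timescale starts, because the fit is ill-conditioned and
single-start optimisation is unreliable. The convergence time is the smallest
block length whose fitted value is within `epsilon = 0.05` of the plateau
`c0`; epsilon operationalises "satisfactory convergence" and is exposed as an
argument. If no start converges, the raw curve is returned with a failure
flag rather than an error.

## Collective variables

The membrane frame is defined by a unit normal (default +z) and the mean
projection of phosphate positions onto it. Because "the average plane of the
phosphate heads" is leaflet-ambiguous for a bilayer, `membrane_frame()` can
restrict to the leaflet below or above the bilayer midplane.

Ring orientation works in the reference inertia frame of a chosen domain:
each frame is aligned to the reference over the domain Cα, the ring normal is
the smallest-spread axis of the centred ring atoms, and (γ, θ) are the polar
angles of that normal with γ measured from the largest-moment axis and θ the
azimuth in the plane of the other two. Which axis anchors γ versus θ is a
convention (the source geometry does not force one); the one implemented is
documented here and validated against planted fixtures. The eigen-normal's
sign is arbitrary, so it is fixed to make γ ≤ 90° at the first frame and
propagated by continuity thereafter — single-frame recovery is therefore
exact only for planted γ < 90°, and the fixture generator plants within that
range.

Contact counts use the rational switching function with defaults r₀ = 6 Å,
n = 6, m = 12 (the source protocol does not state them; these are the common
coarse-grained choices), with the removable singularity at r = r₀ evaluated
as n/m. The funnel restraint requires all geometric parameters explicitly —
axis, cone half-angle, cylinder radius, switching height — because no
sensible hidden defaults exist for them. The acceptor-contact distance preset
exists in two published variants (reactive hydroxyl at mannose C2 versus the
reactive oxygen at C1); both are selectable and neither is a silent default.

## Replica-exchange ladder design

Scaling Coulomb, van der Waals and dihedral terms by s makes the potential
quadratic in s, U(s;x) = E0 + s·E1(x) + s²·E2(x), so the exchange exponent
between states a and b is

Δ = β(s_a − s_b)[(E1_b − E1_a) + (s_a + s_b)(E2_b − E2_a)],

in which E0 cancels identically. `fit_state_model()` records per-trial-λ
means and covariances of (E1, E2) and interpolates them linearly in λ
(clamping outside the trial range, with a warning). Treating (E1, E2) as
Gaussian and the two replicas as independent — exact for replica exchange,
where the joint distribution factorises — Δ is Gaussian, and the expected
Metropolis acceptance E[min(1, e^(−Δ))] has the closed form
Φ(−μ/σ) + exp(σ²/2 − μ)Φ((μ − σ²)/σ), with the σ → 0 limit min(1, e^(−μ)).
The exponential term is evaluated through `pnorm(..., log.p = TRUE)` to
avoid overflow when σ is large.

The ladder optimiser bisects downward from λ = 1 for uniform neighbour
acceptance (the uniform-target objective is a design choice; a flux-based
objective would need the full exchange dynamics, not just pairwise
acceptances). The default target 0.30 is consistent with healthy production
exchange rates in the mid-thirties; when the remaining interval to λmin
cannot reach the target the ladder closes with λmin as a clamped final rung.
The optimiser reports however many rungs the model needs — no replica count
is imposed.

A caution the test suite enforces deliberately: arbitrary synthetic moment
functions need not be thermodynamically consistent (E[Δ] ≥ 0 holds for any
*real* pair of equilibrium ensembles but not for made-up moments), so the
oracle tests use a scaled harmonic-bath family — N oscillators with
mean E1 = N·kT/(2λ) and var E1 = N(kT/λ)²/2 — for which acceptance decays
with the λ gap as it does in practice.

## Reweighting and free-energy surfaces

Bias weights are `w ∝ exp(V/kT)` with max-subtraction. The sign convention is
the usual one for adaptive-bias methods: V is the bias potential *added* to
the Hamiltonian, so sampling follows p·e^(−V/kT) and the recorded V undoes it.
The weights use the bias as consumed (final-bias semantics); time-dependent
bias corrections are variants of the reweighting literature deliberately not
layered in here.

Binless WHAM iterates the standard self-consistent equations with log-sum-exp
stabilisation (tolerance 10⁻¹⁰ on the free energies, gauge f₁ = 0, damping
available). The returned frame weights reweight the pooled samples to a
declared *target* ensemble — a state index (default state 1) or an explicit
vector of target reduced energies. This matters: with full reduced potentials
as input, "1 / Σ N_j e^(f_j − u_j)" alone targets a flat distribution, which
is almost never what is wanted; targeting state 1 makes identical-state and
single-state cases give uniform weights, and passing zero target energies
with pure-bias inputs reproduces exponential bias reweighting exactly.
Non-convergence raises an error carrying an overlap diagnostic rather than
returning degenerate weights.

Free-energy surfaces are weighted histograms (bin widths are the user's
choice; kernel estimators trade bias for variance differently and are out of
scope) with F = −kT·ln ρ min-shifted over populated bins and empty bins
masked as NA, never reported as 0. ΔF between populated bins is invariant to
the shift. kT defaults to 300 K in kJ/mol (0.008314462618·T). The effective
sample size 1/Σw² is attached, and accuracy statements in the validation are
conditioned on bins with at least 100 effective samples.

## Synthetic data: what it does and does not show

Every generator returns its ground truth beside the data, and no analysis
function reads the truth. Seeding is local: generators accept a seed, use it
in a restored-RNG scope, and identical seeds give identical output.

* `make_two_domain_structure()` builds two compact bead clusters with their
  surfaces nearly in contact and a linker arcing over the cleft. The
  near-contact geometry is what gives a clean spectral gap between the six
  rigid-body modes and the softest internal modes, and makes those soft modes
  interdomain (hinge/twist) motions — mirroring a closed two-domain fold,
  where interface contacts stiffen the structure. An early design with
  well-separated domains and a straight linker failed both properties: a
  near-collinear bead chain has almost-zero transverse stiffness in an
  elastic network, so linker vibrations contaminated the soft spectrum.
* `make_planted_trajectory()` projects its displacement basis orthogonal to
  the rigid-body space of the reference before use; otherwise superposition
  during analysis removes part of the planted variance and recovery is
  ill-posed by construction, not by estimator fault.
* `make_biased_samples()` runs plain Metropolis on U + V and reports the true
  *bin-averaged* density on the analysis grid — the quantity a histogram
  estimator converges to; comparing a histogram against point densities at
  bin centres fabricates an O((w·dlnp/dx)²) discrepancy (≈ 0.35 kT at the
  steep bins of the default double well) that has nothing to do with the
  estimator. Thinning is declared by the caller; the validation runs use
  thin = 10 at 10⁵ retained samples so residual autocorrelation does not
  inflate the per-bin error above its ~1/sqrt(n_eff) statistical floor.
* `make_replica_energies()` draws i.i.d. bivariate Gaussians per state with
  arbitrary λ-dependent moments — the oracle bed for the closed-form
  acceptance.

Passing against these generators shows the estimators are correct on data
satisfying their assumptions (Gaussian amplitudes, exact quadratic-λ
energies, known biases, clean two-state kinetics). It does not show force-field
realism, membrane physics, or that real trajectories are long enough — the
convergence diagnostics exist precisely because real data regularly are not.

## Problem sizes in the validation suite

The shipped tests and the acceptance script run on bead models of 40-70
residues, trajectories of 2 000-5 000 frames, 10⁵ Metropolis samples, 10⁵
pooled WHAM frames and 10⁶-draw Monte-Carlo oracles. These sizes were chosen
so the full validation runs in about a minute while keeping every statistical
tolerance (10% variance recovery, 0.005 acceptance error, 0.05 kT WHAM error,
0.2 kT FES error) a few standard errors wide of its expected noise level.

## Known limitations

* The built-in relaxer regularises geometry; it does not produce
  Boltzmann-weighted ensembles, and distortion fractions computed with it are
  not comparable to all-atom protocols.
* The quadratic-λ acceptance model assumes Gaussian (E1, E2); strongly
  multimodal energy distributions (e.g. a ligand flipping between poses
  within one replica) violate it, and the trial-ladder fit will smooth over
  the modes.
* WHAM error estimation (beyond the effective sample size) is out of scope;
  pair it with block analysis over independent runs where uncertainties are
  needed.
* mmCIF input, bond perception and any force-field machinery are
  deliberately absent.
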