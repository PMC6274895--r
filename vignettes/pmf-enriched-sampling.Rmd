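---
title: "PMF-enriched sampling: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PMF-enriched sampling: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfenrich)
```

## The idea

Structure databases hold a statistical record of the conformations that
proteins and DNA actually adopt.  If every deposited structure came from one
ensemble at one temperature, pressure and composition, the distributions of
backbone torsions and of inter-atom distances could be Boltzmann-inverted
into genuine potentials of mean force, w = −kT ln g.  They do not: each
entry carries its own Hamiltonian.  This package implements the pragmatic
workaround used in PMF-enriched sampling: pool the data anyway under a
*quasi-homogeneity* approximation (one effective particle number, one
reference volume — here a sphere of radius 2.5 nm), accept that each
resulting *pseudo*-PMF carries an unknown additive offset δw, and then build
the applied bias out of a quantity from which any shared constant offset
cancels exactly.

That quantity is the normalized partition over the active p-PMF values at
the current configuration,

Ω_i = exp(−β w_i) / Σ_j exp(−β w_j),

a softmax over coordinates (pair distances in one set, torsions in a second,
separately normalized set).  Adding the same δw to every w leaves every Ω_i
— and therefore every gradient of Ω — unchanged.  The bias applied to the
dynamics is the per-coordinate derivative dΩ_i/dx_i mapped to Cartesian
forces; the free energy −kT ln Ω is exposed as a diagnostic only and never
propagated.

The bias enters the equations of motion through a renormalized hybrid
gradient

∇H(C) = ∇H(A)/(1+α) + α (‖∇H(A)‖/‖B_rad‖) B_rad + α (‖∇H(A)‖/‖B_ang‖) B_ang,

so each bias term is rescaled to have norm exactly α‖∇H(A)‖: the coupling α
fixes the bias as a *fraction of the reference-force magnitude*, whatever
the raw scale of the Ω gradients.  The instantaneous coupling fluctuates:
α(t) = 2α(1−ξ) with ξ uniform on [0,1] in the default mean-preserving mode,
whose long-run mean is exactly α.  A literal mode α(t) = α(1−ξ)ε is also
provided; its mean is αε/2, which is why mean-preserving is the default —
the stated contract is that time averages recover α.  (In the
mean-preserving form the width parameter ε cancels out of the draw
entirely; it is retained in the interface for compatibility with the
literal mode.)

## What the derivative of Ω is (and is not)

For Ω_i as a function of its own coordinate, the full quotient rule gives

dΩ_i/dx_i = −β Ω_i (1 − Ω_i) dw_i/dx_i,

and the cross-response to another coordinate is dΩ_i/dx_j = +β Ω_i Ω_j
dw_j/dx_j.  Both are implemented and validated against central finite
differences (`omega_gradient(..., jacobian = TRUE)`).  Two design points
deserve a note:

* Summing all cross-responses into the force applied along one coordinate
  would give identically zero, because Σ_i Ω_i = 1.  The engine therefore
  applies, per coordinate, the full derivative of its own weight
  (`gradient_mode = "full"`); a `"numerator"` mode (−β Ω_i dw_i/dx_i,
  i.e. treating the normalizer as constant) is available for comparison.
* The published form of the radial-gradient expression has both
  quotient-rule terms with the same sign; the mathematically correct
  derivative (second term positive) is what this package computes, and the
  finite-difference tests are the arbiter.

## p-PMF construction

Radial histograms are accumulated over all matching atom pairs out to the
fixed 2.5 nm cutoff and normalized against a homogeneous density in the
cutoff sphere: g(r) = counts / (N_pairs × shell_fraction) with
shell_fraction the exact spherical-shell volume over V_cut = (4/3)π(2.5)³
nm³.  Two numerical choices here are deliberate.  First, the shell volume is
the exact difference V(r+δr) − V(r), not (4/3)πδr³ — the latter is
dimensionally a sphere of radius δr and makes g diverge with r.  Second, the
reference density is N_pairs/V_cut; any other constant merely shifts w by
−kT ln(const), which the Ω partition cancels (this is tested directly).
This normalization removes the r² Jacobian of pair distances exactly, so on
synthetic ensembles drawn from a known u(r) the inversion recovers u up to
an additive constant (RMSE below 0.25 kT on well-populated bins at 10⁵
samples).

Torsion histograms are circular (bin convention: −180° and +180° are the
same angle and land in the first bin), normalized to a density per degree.
Zero-count bins are floored at g_min = 10⁻⁶ before inversion, producing
high-but-finite plateaus (≈ 13.8 kT at 300 K) rather than infinite walls;
the flagged `capped` bins mark where the database said nothing and the
reference force field should dominate.  Each table is shifted so min(w) = 0 —
immaterial to Ω, but it makes tables comparable.  Defaults: 0.02 nm radial
bins, 5° angular bins.  Interpolation is by cubic spline (natural for
distances, periodic for torsions), giving a continuous first derivative
that the tests compare against finite differences of the interpolant.

Radial tables are keyed by residue-type pair plus atom-name pair by
default, which makes them transferable across sequence positions; a
per-position keying (the sequence-indexed matrix layout) can be had by
building one table per position pair and mapping it explicitly in the
library.

## The toy engine and its units

The production-scale machinery around the method (explicit water, Ewald
electrostatics, constraint algorithms, Nosé–Hoover chains) is out of scope
here; the dynamics engine is a desk-scale Langevin integrator on bead-chain
topologies with harmonic bonds and angles, cosine and double-well dihedrals
and a short-range pair repulsion.  The integrator is BAOAB with the two
half-kicks merged into one full kick (the position trajectory is identical
to textbook BAOAB); its configurational accuracy is verified by the
equipartition test ⟨x²⟩ = kT/k on a harmonic coordinate to within 5%.

Reduced units: energy in kT of the simulated ensemble (`thermo_context(1,
kB = 1)`), bead masses 1, bond length 1 (≈ 0.38 nm), friction γ = 2 in the
study runs, dt = 0.005 — an analog of the ~1 fs time step of the atomistic
setting relative to the stiffest bond period (ω dt ≈ 0.14).

RNG discipline: every run derives its thermostat stream from the user seed
by a documented splitting rule, and the α(t) draws use a *separate* stream.
Two consequences are load-bearing for the tests: an α = 0 run is bitwise
identical to an unbiased run with the same seed, and an α = 10⁻⁹ run
shadows the unbiased trajectory so closely that unbiased observables are
recovered to well within 2%.

## The escape study conditions

The double-well study ("dialanine analog") uses a 5-bead chain whose first
dihedral carries a symmetric double well U = (h/2)(1 − cos 2φ) with h = 8 kT
(wells at 0° and 180°, barrier at 90°), and whose second dihedral is a soft
cosine spectator — two biasable torsions, mirroring the Φ/Ψ pair of the
smallest real test system.  Bonded terms are stiff (bond k = 400, angle
k = 40 in reduced units) so that the reference gradient is dominated by
bonded forces, as it is in the atomistic case; this matters because the
renormalization ties the bias magnitude to ‖∇H(A)‖.  The run starts in the
trans (180°) well — the well additionally stabilized by the chain's
excluded-volume term — and the torsional prior table is a wrapped Gaussian
(σ = 60°) centred on the cis well: a broad, database-style preference whose
density stays above the g_min floor everywhere, so the bias has a nonzero
gradient even far from its minimum.  Escape is first passage of |φ₁| below
75°, i.e. 15° past the barrier, the same margin convention used for the
Φ-angle transitions in the atomistic study.  The α grid is {0, 10⁻³, 10⁻²,
10⁻¹} — toy-scaled values of the gradient-ratio coupling — with 20 seeds per
α and runs of 20,000 steps; unbiased runs typically do not escape within
the run and are reported as censored at the run length, the toy image of
the "no transition" entry at weakest coupling.  Under these conditions the
median escape at α = 10⁻¹ is several-fold faster than the censored
unbiased median, and medians are non-increasing in α.

These run lengths and seed counts are the package's chosen problem sizes
for its own validation; they keep the full study in the minutes range on a
single core while leaving the statistical conclusions (monotonicity, ≥3×
acceleration) comfortably clear of the seed-to-seed noise of first-passage
times.

## Path sampling

The comparator method biases along the accumulated action-like path
variable L, with per-step increment dL = (p + dp)·dq per atom and Cartesian
axis.  Two history-dependent components act on it, each replicated over NR
parallel biases with coupling times τ1_i = i·τ1 and τ2_i = i·τ2:

* an adaptive-bias force: η′_i(t) times the coarse time derivative of the
  windowed mean path rate, where η′_i is a square wave of amplitude 1
  alternating each τ1_i window.  The published account fixes only that η′
  has zero mean and varies slowly; the square wave is this package's
  deterministic reading of that contract, and the (p+dp)dq-weighted
  derivative term is dropped as stated (≈ 0).
* Gaussian deposition along σ = L on the τ2_i grid, with tick-to-tick
  widths δσ = |σ(t_b) − σ(t_b′)|, well-tempered heights
  W exp(−Φ/ΔE)·|Δσ|/|σ|, and a configured fallback width for the first
  deposit (the width rule is undefined before two ticks exist).  The
  division by σ(t_b) is guarded by a lower clamp (`sigma_clamp`), since the
  height rule is frame-dependent as σ → 0 and the source leaves that case
  open.  Deposits are per-(bias, atom, axis) scalars, so the printed
  product-form kernel reduces to independent scalar Gaussians per
  component.

The combined path force is mapped to atoms through ∂L/∂q = (p + dp) and
renormalized against ∇H(A) exactly as the Ω bias is, with the same α(t)
contract (α = 0 path runs are bitwise identical to plain unbiased runs).
In the package's double-well study the deposition component is the
effective driver (τ1 = 1.0, τ2 = 0.15, W = 3 kT, ΔE = 10 kT, NR = 2,
α = 0.3): the alternating adaptive term is zero-mean by construction and
mostly adds directionless fluctuation at this scale.

## Analysis layer

Free-energy landscapes are −kT ln(P/P_ref) over binned order parameters
with the modal bin as reference, so ΔF ≥ 0 and the minimum sits at 0; the
printed convention "p/p_min" is read as probability relative to the modal
bin (reading p_min literally as the rarest bin would make every ΔF ≤ 0 with
the reference at the least-populated class, which contradicts the plotted
landscapes).  Empty bins are +Inf and flagged.  RMSD uses Kabsch
superposition; Rg is mass-weighted.  The conformer classifier is a
documented nearest-centroid surrogate under wrapped Euclidean distance in
torsion space with a per-class acceptance radius and a non-assigned class
for everything else — the actual dinucleotide-conformer class definitions
are an external resource, and reproducing their assignment protocol is
explicitly not claimed; users supply their own centroid table.  Transition
kinetics use first-passage dwell accounting (mean dwell in class i before a
transition to k), reported as ln ν = −ln τ, with never-observed pairs
absent rather than zero.  Escape times are first-passage times with
censoring at the run length, and the acceleration factor is the ratio of
median reference to median biased escape time.

## What the synthetic data does and does not show

The generators produce polypeptide backbones with exact ideal geometry and
wrapped-Gaussian torsions, pair distances drawn from a stated Boltzmann
density, and bead-chain topologies.  They emulate exactly the statistical
structure the pipeline consumes — known torsion means and widths, a known
u(r), known class centroids, known Markov rates — which is what makes every
stage testable against ground truth.  They do not emulate real structure
databases' heterogeneity (resolution-dependent noise, sequence diversity,
secondary-structure mixing, crystal packing), so green tests here establish
the correctness of the machinery, not the scientific adequacy of any
particular database-derived bias.  In particular the known failure mode of
broad database averaging — minima contributed by conformations foreign to
the system of interest steering the trajectory toward them — is inherited
by construction and only mitigated, as in the source method, by curated
structure selection.

## Known limitations

* The engine is a toy: no solvent, no electrostatics, no constraints, ≤ a
  few dozen beads; quantitative rates are meaningful only within the toy.
* First-passage medians over 20 seeds still carry exponential-tail noise;
  the acceptance checks use monotonicity and a 3× margin rather than point
  estimates.
* The per-position radial keying mode trades transferability for fidelity
  to the sequence-indexed layout; with small synthetic ensembles it is
  easy to under-populate bins, and the g_min plateau then dominates.
* The adaptive-bias component's η′ square wave is one admissible reading of
  an under-specified contract; the seeded random-sign variant changes
  nothing qualitative in the toy study.
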