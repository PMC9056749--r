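---
title: "Layer-resolved interfacial water dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved interfacial water dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aquadyn analyses the structure and dynamics of water near a solute — a
peptide, a small molecule, any atom set tagged `solute` in the topology —
from classical MD trajectories. This vignette explains the models behind
each analysis, the parameters that matter, the numerical choices we made
where the conventions in the literature are genuinely open, and what the
synthetic-trajectory validation does and does not demonstrate.

## Hydration layers

Every water molecule is assigned, frame by frame, to a hydration layer by
its minimum distance to any solute atom. The default edges are
`c(0, 4, 8, 12, 16)` Å — four 4 Å shells, with everything beyond 16 Å
labelled bulk. A 4 Å first shell matches the first peak of typical
water–heavy-atom radial distribution functions; by 16 Å from a small
solute, bulk behaviour is recovered.

Numerical choices:

* **Half-open bins** `[e_k, e_{k+1})`. Boundary handling is almost never
  stated in the literature; we pick one convention and test it (a water at
  exactly 4.0 Å is in the 4–8 Å layer).
* **Water site**: the oxygen atom by default, because the distance
  criterion is atomic; the centre of mass is available via
  `water_site = "com"`. Displacement statistics always use the centre of
  mass (computed from topology masses, not the geometric centre).
* **Membership over a time window**: for layer-restricted MSDs a molecule
  counts toward a layer only if it is in that layer at *every* frame of the
  `[t0, t0 + t]` window (continuous residence). The weaker endpoints-only
  rule is available (`rule = "endpoints"`) because the defining phrase for
  such restrictions is ambiguous in much of the literature; continuous
  residence is the default since it is the only reading under which the
  restricted statistic describes molecules that actually stayed in the
  layer.

## Hydrogen bonds

A hydrogen bond exists between two molecules when the intermolecular
H···O distance is below 2.5 Å and the O···O distance below 3.5 Å — the
standard geometric criteria. Both are strict inequalities. An O–H/O–O
angle criterion (< 30° when enabled) exists but is off by default: for
water geometries that satisfy both distance cutoffs the angle condition is
implied, and tests verify that enabling it never increases a bond count.

`n_HB` per water counts donated plus accepted water–water bonds, averaged
over the waters resident in a layer each frame; the reported spread is the
frame-to-frame standard deviation of the per-frame layer mean. Water–solute
bonds are counted separately and reported under **both** normalizations —
per interfacial water and per solute polar site (N, O, polar H) — because
which denominator is meant is often unstated in the literature.

The bond-population correlation
`C_HB(t) = <h(0) h(t)> / <h(0)>` uses the *intermittent* descriptor: a pair
bonded at 0 and at t counts regardless of breaks in between. The
conditional-probability reading of the descriptor does not forbid
intermediate breaks, and the intermittent form is the one with a clean
two-state-kinetics interpretation (tests check it against the closed-form
telegraph autocorrelation).

## Translational dynamics

The mean-squared displacement is averaged over molecules and time origins,
and fitted to the generalized Einstein form `MSD(t) = D t^α`:
α = 1 diffusive (`D_s = D/6`), α < 1 sub-diffusive, α > 1 super-diffusive,
α = 2 ballistic. Fits are unweighted least squares in log–log space —
the usual convention, and exact for pure power laws; weighted options can
be added at the fit window level but are deliberately not a default.
Two named windows, 0–0.3 ns (`"alpha1"`) and 0.5–3 ns (`"alpha2"`),
bracket the short/long-time crossover seen near peptide interfaces; the
crossover is a fixed window boundary, never auto-detected silently.

`classify_regime()` labels α within a tolerance band (default ±0.05):
note that by this rule an exponent such as 1.99 classifies as ballistic;
with a tighter band it is labelled super-diffusive and carries a
`near_ballistic` note. Regime labels are a reading aid, not a statistic.

The self van Hove function `G_s(r, t)` is the radial probability density
of displacement magnitudes (the 4πr²-weighted form), normalized so that
its radial integral is 1 at every lag (tested to 10⁻⁶). Secondary maxima
beyond the self peak indicate discrete translational jumps (hopping);
the detector reports local maxima with prominence ≥ 5% of the main mode.

## Rotational dynamics

The water dipole is computed from partial charges and minimum-image
geometry and normalized; its first-rank autocorrelation
`C(t) = <u(t0) · u(t0 + t)>` is averaged over origins and molecules.
Two open conventions, and our choices:

* **Legendre rank.** A "dipole-vector correlation" read literally is the
  rank-1 (P₁) correlation; P₂ is available via `rank = 2`.
* **Selection rule.** Molecules are selected by layer membership *at the
  origin frame only*, not by continuous residence: interfacial relaxation
  times of tens of ps would otherwise be truncated by the fast exchange of
  a 4 Å shell. The choice is switchable through an explicit selection
  matrix.
* **τ_R definition.** The time integral of C(t), evaluated by trapezoidal
  integration up to the lag where C first reaches a small floor (default
  0.02) plus an analytic exponential-tail term fitted to the final decade
  before that cut. Integrating the sampled curve far past its decay only
  accumulates correlated Monte-Carlo noise, which is why the truncation
  exists; the tail contribution is reported separately, and a
  single-exponential-fit τ is emitted alongside for comparison. A series
  whose tail is still above 0.5 is rejected as non-decaying rather than
  integrated.

For rotational diffusion with constant `D_r`, `C(t) = exp(-2 D_r t)` and
`τ_R = 1/(2 D_r)`; the rotor generator plus this closed form is the
recovery test for the whole chain.

## Residence times

`C_R(t)` is the probability that a molecule in a region at the origin is
still there a lag t later, with any continuous absence *shorter than* the
tolerance t\* forgiven as a temporary excursion (strict inequality;
absence duration is frames × dt). The default t\* = 2 ps; a built-in
t\*-sweep (`residence_tstar_sweep()`) exposes the sensitivity of the
fitted times to the tolerance, which grows rapidly beyond a few ps. The
average conditions on presence at the origin, so `C_R(0) = 1` by
construction (molecules outside the region at the origin are excluded
rather than counted as zeros — the alternative merely rescales the curve).
Origins whose window extends past the last frame are discarded, not
extrapolated.

`C_R` is fitted with a double exponential; the slow constant is the
residence time, the fast one the escape time of molecules at the region
border.

## Double-exponential fitting

One fitter (`fit_double_exponential()`) serves both the bond-lifetime and
residence analyses: `A exp(-t/τ_fast) + (1-A) exp(-t/τ_slow)` with
A ∈ [0, 1], Levenberg–Marquardt with box constraints, 8 starts spanning
two decades of time constants, ties broken by residual. Two safeguards
matter in practice:

* A **single-exponential comparison fit** is always run; if the second
  component is statistically insignificant (F-test at p = 0.01) the fit is
  collapsed to the single-exponential solution and flagged `degenerate`.
* A slow component is treated as **unidentifiable** — and the fit likewise
  collapsed — when its amplitude is below 0.05 or its time constant
  exceeds 60% of the fit window. A time constant comparable to the
  observation window cannot be measured; on noisy single-exponential data
  the unconstrained biexponential otherwise chases correlated noise in the
  tail with a tiny-amplitude, arbitrarily slow component.

Noiseless biexponential inputs are recovered to well under 1%; under 1%
additive noise the median parameter error stays below 5% (tested over 50
replicates).

## Solute shape

The gyration tensor about the mass-weighted centroid ("inertia tensor"
read literally; a geometric option exists) yields eigenvalues summing to
R_g², the asphericity `b = λ₁ − (λ₂ + λ₃)/2` (plus the dimensionless
b/R_g²: 1 for a rod, 1/4 for a disc, 0 for a sphere), and the long axis.
RMSD to a reference conformation uses optimal superposition by default —
Kabsch with proper rotations only, cross-checked against bio3d — since
unaligned RMSD conflates internal motion with tumbling; the unaligned
variant (centroids removed) is available.

## Synthetic validation: what it shows and what it does not

The `synthetic_data` generators produce trajectories whose ground truth is
known by construction: Brownian walks (increment variance 2 D dt per
axis), exact ballistic motion, rest-and-jump Lévy-hop motion with logged
hop events, rotational diffusion on the sphere, an ice-like diamond-cubic
water lattice obeying the ice rules (every interior molecule exactly 4
bonds), a two-state shell-exchange telegraph process, and a composite
solute-plus-rigid-waters system (O–H 0.9572 Å, H–O–H 104.52°, mirroring a
rigid three-site water geometry). Each generator is reproducible from its
spec and seed alone, uses per-particle frame-major random streams (so
extending a trajectory preserves its earlier increments), and emits its
ground truth separately from the analysis path.

Default study conditions for the recovery suite: 100 ballistic
trajectories × 1000 frames at dt = 0.1 ps; 200 Brownian walkers
(D = 0.2 Å²/ps) × 2000 frames; 400 rotors (D_r = 0.025 ps⁻¹,
τ_R = 20 ps) × 3500–4000 frames; 500 exchange particles
(k_out = 0.05 ps⁻¹, τ = 20 ps) × 1200 frames; hop fixtures with ℓ = 8 Å
and mean wait 10 ps. These sizes put each recovery's Monte-Carlo spread
comfortably inside its stated tolerance (±0.02 on the ballistic exponent,
±0.05 on the Brownian exponent, 5% on D_s, 10% on τ_R and the residence
time) while keeping the whole suite desk-scale.

Passing these recoveries demonstrates that the estimator chain — unwrap,
COM, origin averaging, fitting, integration — is correct for data whose
statistical structure matches the model. It does **not** demonstrate
fidelity on real interfacial water, which mixes all of these processes,
has finite-size and force-field artifacts, and couples translation to
rotation. The generators contain no interactions, no thermostat and no
real water structure; the lattice fixture tests the bond-detection
geometry, not liquid-state bonding statistics.

## Known limitations

* Orthorhombic boxes only; triclinic cells are rejected.
* Unwrapping requires sampling fine enough that no atom crosses half a box
  between frames (violations raise an error naming atom and frame).
* Supported inputs are XYZ (with box lengths on the comment line), DL_POLY
  HISTORY (levcfg 0–2, coordinates only) and PDB; no compressed binary
  trajectory formats.
* The hydration density map assumes the solute is effectively rigid over
  the trajectory (frames are superposed onto one reference conformation).
* No reactive-flux hydrogen-bond kinetics, no angular-jump decomposition,
  no non-Gaussian parameter: the analyses stop at the correlation-function
  level described above.
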