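# aquadyn

Layer-resolved structure and dynamics of interfacial water from molecular
dynamics trajectories.

Water near a solute surface behaves differently from bulk water: hydrogen
bonding is depleted, translation can become anomalous (sub- or
super-diffusive, with discrete hopping between hydration sites), rotation
slows, and molecules reside in the first shell for characteristic times.
aquadyn is for simulators who have such a trajectory — of a peptide, a small
molecule, any tagged solute in water — and want these properties resolved by
hydration layer, with every estimator validated against synthetic
trajectories of known ground truth.

## What it computes

Waters are binned into hydration layers by minimum distance to the solute
(default 4 Å shells out to 16 Å, bulk beyond). Per layer:

* **Hydrogen bonds** under the geometric criteria (H···O < 2.5 Å and
  O···O < 3.5 Å; optional 30° angle test): `n_HB` per water, water–solute
  counts, the intermittent bond-population correlation
  `C_HB(t) = <h(0)h(t)>/<h(0)>`, and double-exponential bond lifetimes.
* **Translational dynamics**: layer-restricted MSD over time origins with a
  continuous-residence membership rule, fitted to the generalized Einstein
  relation `MSD(t) = D t^α` (α = 1 diffusive with `D_s = D/6`, α < 1
  sub-diffusive, α > 1 super-diffusive, α = 2 ballistic), and the self
  van Hove function `G_s(r, t)` with secondary-mode (hop) detection.
* **Rotational dynamics**: the first-rank dipole autocorrelation
  `C(t) = <u(t0)·u(t0+t)>` and its relaxation time
  `τ_R = ∫ C(t) dt`, including site-resolved variants near named solute
  groups.
* **Residence times**: the survival correlation `C_R(t)` with an
  intermittency tolerance t\* (absences shorter than t\* forgiven, default
  2 ps), fitted to a double exponential whose slow constant is the
  residence time.
* **Solute shape**: gyration tensor and radius, asphericity, and RMSD to a
  reference conformation under proper-rotation Kabsch superposition.

A synthetic-trajectory module generates Brownian, ballistic, Lévy-hop,
rotational-diffusion, ice-lattice, shell-exchange and composite
solute-plus-water fixtures with known ground truth; it drives the test suite
and the built-in validation command, and is exported for your own checks.

## Worked example

Generate a composite fixture (rigid three-site waters with Brownian
translation, D = 0.15 Å²/ps, and rotational diffusion, D_r = 0.08 ps⁻¹,
around a dummy solute) and run the full pipeline:

```r
library(aquadyn)

spec <- synthetic_spec("composite", n_particles = 60, n_frames = 200,
                       dt = 0.1, D = 0.15, D_r = 0.08,
                       box = make_box(26), seed = 1)
traj <- gen_composite(spec)

cfg <- analysis_config(msd_windows = list(alpha = c(0.3, 10)),
                       origin_stride = 5, hb_frames = 40)
bundle <- run_analysis(traj, cfg)
bundle$summary
#> # A tibble: 5 × 8
#>   layer   nhb_mean nhb_sd  alpha tau_R tau_residence hb_tau_fast hb_tau_slow
#>   <chr>      <dbl>  <dbl>  <dbl> <dbl>         <dbl>       <dbl>       <dbl>
#> 1 0-4 A      1.13   0.529  0.994  6.67          16.4    0.000001        11.7
#> 2 4-8 A      1.88   0.548  0.974  5.41          NA      0.000001        11.7
#> 3 8-12 A     0.899  0.223  0.939  5.91          NA      0.000001        11.7
#> 4 12-16 A    1.75   1.02   1.00   4.56          NA      0.000001        11.7
#> 5 bulk       0      0     NA     NA             NA      0.000001        11.7
```

Reading the table: the fitted exponent is ≈ 1 in every populated layer, as
it must be for Brownian waters, and `tau_R` scatters around the rotor closed
form 1/(2 D_r) = 6.25 ps. `n_HB` is far below the ≈ 3.9 of liquid water
because this fixture is deliberately dilute; the HB fast lifetime pinned at
the lower bound says bond breaking is unresolved at this frame interval —
both are properties of the fixture, not of water. Each column is also
available as a full object (`bundle$msd`, `bundle$rotational`,
`bundle$residence_corr`, ...), fits come with `tidy()`/`glance()` methods,
and the main result types have `autoplot()` methods.

The built-in recoveries can be run in one call:

```r
run_validation_suite(seed = 1, scale = 0.5)
#>                 statistic expected  recovered tolerance pass
#> 1         ballistic alpha      2.0  2.0000000      0.01 TRUE
#> 2          brownian alpha      1.0  0.9994749      0.05 TRUE
#> 3            brownian D_s      0.2  0.2001234      0.05 TRUE
#> 4             rotor tau_R     20.0 20.2445031      0.10 TRUE
#> 5 exchange residence time     20.0 18.8860108      0.10 TRUE
#> 6   lattice interior n_HB      4.0  4.0000000      0.00 TRUE
```

## Package layout

* `R/` — trajectory I/O and periodic-distance primitives, synthetic
  generators, layer assignment, hydrogen bonds, translational / rotational /
  residence analyses, solute shape, pipeline orchestration.
* `tests/testthat/` — unit and property tests per module, each stochastic
  estimator checked against an independent oracle (brute-force loops, closed
  forms, event logs), plus `test-acceptance.R` with the end-to-end recovery
  checks.
* `vignettes/interfacial-water-dynamics.Rmd` — the models, conventions and
  numerical choices, and what the synthetic validation does and does not
  show.
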