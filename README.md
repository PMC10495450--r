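# carotidwk

Analytical three-element Windkessel (RCR) outlet boundary conditions for
carotid-artery CFD, estimated from the geometry of the downstream
cerebral vasculature.

CFD studies of the carotid bifurcation need outlet boundary conditions
that represent the distal vascular bed — its resistance and its
compliance — but tuning Windkessel parameters against clinical
measurements is slow and requires measurements most studies do not have.
This package implements the analytical alternative: every distal vessel
segment gets a lumped resistance and compliance from closed-form tube
physics,

```
R = 128 μ l / (π D⁴)          (Poiseuille resistance)
C = π D³ l / (4 G h)          (elastic-tube compliance)
```

and the distal tree is collapsed to one `(Rp, C, Rd)` triple per outlet
by series/parallel reduction of the electrical analog (resistances
combine like resistors, compliances like capacitors). A 0D transient
simulator of the resulting RCR outlets predicts outlet pressures and
multi-outlet flow splits and checks its own periodic convergence.

The package is aimed at researchers setting up carotid / cerebral CFD who
need defensible initial Windkessel parameters, and at anyone studying
lumped-parameter haemodynamics of the ICA/ECA/MCA/ACA trees.

## What's inside

* **Per-segment physics** — `poiseuille_resistance()`,
  `elastic_compliance()`, `calibrate_stiffness_product()` (inverse of the
  compliance formula, since only the product G·h is identifiable), and
  the Carreau shear-thinning viscosity law `carreau_viscosity()`.
* **Reduction algebra** — `combine_series()`, `combine_parallel()`
  (fractional multiplicities allowed), named recipe chains evaluated at
  full precision by `evaluate_recipes()`, and `compare_to_printed()` for
  auditing against published tables.
* **A bundled carotid atlas** — `load_atlas()`: 38 branch records
  (ICA trunk, MCA M1–M4, ACA A1–A5, ophthalmic pair, ECA branches) with
  published resistance/compliance values, the full reduction chains in
  two dialects (`"as-published"` and `"self-consistent"`), tree topology,
  `outlet_boundary_conditions()` and a computed `discrepancy_report()`.
* **0D simulator** — `rcr_outlet_pressure()` (implicit Euler, periodic
  spline forcing), `multi_outlet_split()` (exact junction closure, flow
  conserved to round-off), `synth_inflow()` (deterministic Fourier pulse
  with exact cycle mean), `periodic_convergence()`.
* **I/O and CLI** — CSV/JSON segment tables, waveforms, recipes and BC
  exports, plus a command-line tool (`inst/cli/carotidwk`) with
  `compute`, `calibrate`, `reduce`, `atlas`, `bc` and `simulate`
  subcommands.

## Worked example

```r
library(carotidwk)

## proximal ICA segment: D = 5.6 mm, l = 33.1 mm, blood at 0.0035 Pa s
seg <- vessel_segment("B1", diameter = 5.6e-3, length = 33.1e-3)
poiseuille_resistance(seg)
#>      B1
#> 4799589
```

4.80×10⁶ kg m⁻⁴ s⁻¹ — the hydraulic resistance of the ICA trunk, matching
the published value at 3 significant figures.

```r
atlas <- load_atlas()
outlet_boundary_conditions(atlas, outlets = "ECA")$ECA
#> <windkessel_bc> Rp = 1.11e+07, C = 3.89e-13, Rd = 3.19e+07, Pd = 0 Pa (printed)
```

The ECA outlet: proximal resistance from the ECA trunk, distal
resistance and compliance from the 10-step reduction of its eight named
branches.

```r
bcs <- suppressWarnings(
  outlet_boundary_conditions(atlas, outlets = c("ICA", "ECA")))
multi_outlet_split(synth_inflow(), bcs, tol = 1e-6, max_cycles = 10)
#> <wk_sim> 2 outlet(s), 3 cycle(s), converged: TRUE
#>   mean splits: ICA = 40.30%, ECA = 59.70%
```

A purely 0D junction fed by a 5.35 cm³/s carotid pulse sends 40.3% of the
mean flow down the ICA — exactly the inverse total-resistance divider
1/(Rp+Rd) implied by these outlet totals (compliance provably does not
move the mean split). 3D CFD with the same outlet parameters reports
~71.6% ICA because the 3D domain adds the bifurcation geometry itself;
see the methods vignette for why the package reports the 0D value
without adjustment. (The warning notes that the published ICA totals are
internally inconsistent; `source = "recomputed"` selects the re-derived
pair.)

```r
discrepancy_report(atlas)[, 1:4]
#>      id     category value_published value_alternative
#> 1   B11          row    2.360000e+07      5.492214e+07
#> 2   B13          row    4.770000e+08      4.842203e+08
#> 3   C19       recipe    3.790000e-14      2.966554e-14
#> 4   R19       recipe    5.890000e+07      7.877335e+07
#> 5    C1 multiplicity    1.667000e-14      4.142000e-14
#> 6    C7 multiplicity    1.747456e-14      1.783574e-14
#> 7 R9/C9 multiplicity    7.533333e+07      7.062500e+07
#> 8    mu    viscosity    4.000000e-03      3.500000e-03
```

Every place the published atlas cannot be reproduced from its own stated
inputs, with both candidate values — computed at run time, never a
hard-coded list.

## Command line

```sh
inst/cli/carotidwk bc --outlet ECA --quiet
inst/cli/carotidwk atlas --report --out report.csv
inst/cli/carotidwk simulate --bc bcs.json --cycles 7 --out run
```

## The methods vignette

`vignettes/carotid-windkessel-methods.Rmd` documents the model and its
assumptions, the two recipe dialects and why they exist, the numerical
choices in the simulator, what the synthetic inflow does and does not
emulate, and the known limitations.
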