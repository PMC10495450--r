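---
title: "Estimating carotid Windkessel boundary conditions from downstream anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carotid Windkessel boundary conditions from downstream anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidwk)
```

## The problem

Outlet boundary conditions dominate the accuracy of carotid-artery CFD.
The common shortcut — zero pressure, fixed flow splits, constant
resistance — ignores the distal vascular bed entirely. A three-element
Windkessel (RCR) outlet does better: a proximal resistor $R_p$ for the
vasculature just beyond the outlet, a capacitor $C$ for the storage of the
elastic vessel walls, and a distal resistor $R_d$ for the
arteriolar/capillary/venous bed. The catch is parameterising it.
Traditionally $R_p$, $C$, $R_d$ are tuned until the simulation matches
clinical measurements, which requires clinical measurements.

This package implements the alternative: estimate the parameters directly
from the *geometry* of the downstream arterial tree, which is readable
from routine clinical images or from the anatomical literature. Each
distal vessel segment is assigned a lumped resistance and compliance from
closed-form tube physics, and the segments are collapsed to a single RCR
triple per outlet by series/parallel reduction of the electrical analog.

## Per-segment physics

For a segment of lumen diameter $D$ and length $l$ carrying blood of
dynamic viscosity $\mu$:

$$R = \frac{128\,\mu\,l}{\pi D^4}, \qquad
  C = \frac{\pi D^3 l}{4\,G h},$$

the Poiseuille resistance of developed laminar flow in a rigid tube and
the volume compliance of a thin-walled elastic tube with Young's modulus
$G$ and wall thickness $h$. Assumptions worth keeping in mind: steady
laminar flow (no Womersley or entrance effects), no taper or curvature,
Newtonian $\mu$ inside the resistance formula. These are the standard
lumped-parameter idealisations; they are what makes the closed forms
possible.

Only the *product* $Gh$ enters the compliance, and published compliance
tables never state $G$ or $h$ separately, so the package stores the wall
as a single `stiffness_product` (Pa m). `calibrate_stiffness_product()`
inverts the compliance formula; applied to the bundled atlas the products
cluster by subtree (median ≈ 2.7 kPa m for the internal-carotid tree,
≈ 2.3 kPa m for the external tree), and `atlas_wall_defaults()` exposes
those medians as per-group defaults.

Two viscosities circulate in this literature: 0.004 Pa s as a Newtonian
bulk value, and 0.0035 Pa s as the infinite-shear limit of the Carreau
law (`carreau_viscosity()`, with the usual blood parameters
$\lambda = 3.313$ s, $n = 0.3568$, $\mu_0 = 0.056$, $\mu_\infty = 0.0035$
Pa s). The bundled atlas resistances reproduce only under 0.0035 Pa s —
with 0.004 Pa s every row is ~14% high — so 0.0035 Pa s is the package
default, both values are selectable, and the ambiguity is an entry of the
discrepancy report rather than a silent choice.

## Reduction algebra

Resistances combine like resistors; compliances combine like capacitors,
i.e. by the dual rule:

| mode     | resistance              | compliance              |
|----------|-------------------------|-------------------------|
| series   | $\sum R_i$              | $(\sum C_i^{-1})^{-1}$  |
| parallel | $(\sum n_i/R_i)^{-1}$   | $\sum n_i C_i$          |

The capacitor analogy for compliance is not always spelled out in source
tables, but it is forced by their arithmetic, and the package verifies it
against several published combinations in the test suite. Multiplicities
$n_i$ may be fractional: anatomical studies report mean branch counts
such as 7.6 perforators, and the published reductions use them as-is.

`evaluate_recipes()` runs an ordered table of named combination steps
against a base map of per-branch elements, always at full floating
precision — published intermediates are rounded to 3 significant figures,
and feeding rounded intermediates forward would compound the rounding.
Comparisons against published values (`compare_to_printed()`) therefore
use a 1% relative tolerance, which absorbs 3-significant-figure rounding
and nothing else.

## The bundled atlas and its dialects

`load_atlas()` returns a 38-branch carotid tree (proximal ICA trunk; MCA
M1–M4 with lenticulostriate, temporal and cortical branches; ACA A1–A5
with the AComA complex; the ophthalmic pair; and the ECA with its eight
named branches), each row carrying tabulated geometry plus the published
resistance and compliance, together with the named reduction chains for
both quantities and a parent/child topology table. The recipes — not the
topology — are the source of truth for reduction order: the published
arrangement places side-branch fans in parallel with their trunk in ways
a bare topology does not determine.

The published chains are internally inconsistent in two places: step 1
uses 16 lateral-orbitofrontal copies in the resistance chain but one copy
in the compliance chain, and step 9 says "16" copies while reproducing
only with 15. The package refuses to adjudicate silently. The
`"as-published"` dialect reproduces the published arithmetic exactly,
inconsistencies included; the `"self-consistent"` dialect forces the
branch-count column into both chains. Analyses that compare against the
published values use the former; analyses that need internal consistency
use the latter.

`discrepancy_report()` recomputes everything at run time and enumerates
every place the published numbers cannot be reproduced: two geometry rows
(one off by 130% unless a shorter segment length from the source anatomy
is substituted; one off by 1.5%), the whole-tree ICA totals (step 19,
published values reproducible under neither a series nor a parallel
reading of their stated inputs — the report carries both candidates), the
two multiplicity inconsistencies, and the viscosity ambiguity. On a
self-consistent tree the report is empty; it is a computation, not a
curated list.

## Outlet boundary conditions

`outlet_boundary_conditions()` assembles RCR triples for the truncation
sites of a carotid CFD model: the whole ICA and ECA, and the
patient-specific sub-outlets (MCA/M1, M2, ACA, ophthalmic). The rule is
uniform — the trunk segment at the truncation becomes $R_p$, the reduced
subtree distal to it becomes $R_d$ and $C$. Published per-branch values
are the canonical reduction inputs (the wall stiffness behind the
published compliances is not itself published); recomputation from
geometry is available behind explicit wall-property overrides.

Two open points are resolved as follows, as package design choices:

* The published ICA totals conflict with their own inputs, so the ICA
  outlet carries provenance-tagged alternatives: `source = "printed"`
  returns the published pair with a warning, `source = "recomputed"` the
  full-precision reduction.
* The ophthalmic artery has no tabulated trunk geometry — its atlas row
  is already a reduced element — so its BC splits the total resistance
  10% proximal / 90% distal, the common convention when only a total
  resistance is known. The fraction is an explicit argument.

The distal reference pressure defaults to 0 Pa (no venous reference is
stated in the source anatomy or tables) and is configurable per outlet.

## The 0D simulator

A single RCR outlet under prescribed flow $Q(t)$ obeys

$$Q\left(1+\frac{R_p}{R_d}\right) + C R_p \frac{dQ}{dt}
  = \frac{P - P_d}{R_d} + C\frac{dP}{dt}.$$

`rcr_outlet_pressure()` integrates this with implicit (backward) Euler.
The choice is deliberate: distal cerebral beds have $R_d C$ time
constants from microseconds to tenths of a second, and an explicit
scheme's stability limit would be set by the stiffest outlet while
backward Euler is unconditionally stable and settles to the exact
algebraic steady state under constant inflow. The price is first-order
accuracy; the test suite verifies the order against the analytic
integrating-factor solution and the default step of $T/1000$ (0.55 ms on
a 0.55 s cycle) keeps the periodic-state error at the fraction-of-a-
percent level, with finer steps available where sharper agreement is
wanted. $dQ/dt$ comes from a periodic cubic spline of the waveform, not
from finite differences of the samples, since the equation genuinely
needs a derivative and sampled waveforms are sparse.

`multi_outlet_split()` couples several outlets to one junction fed by a
prescribed inflow. Each outlet keeps its capacitor-node pressure as a
state variable; the junction pressure is eliminated exactly at every step
from the constraint that outlet flows sum to the inflow, so mass
conservation holds to round-off by construction rather than to a solver
tolerance. The resulting linear system is advanced with one
pre-factorised matrix per run.

A useful closed form falls out of the cycle average: with equal distal
pressures, capacitors carry no mean current, so the converged mean split
is the inverse *total*-resistance divider
$\mathrm{share}_i \propto 1/(R_{p,i}+R_{d,i})$, independent of compliance
and of waveform shape (`resistive_divider_split()`). The simulator
reproduces it to well under 0.5%, and a tenfold compliance change moves
the mean split by less than that while visibly reshaping the
instantaneous flow traces.

Applied to the published ICA/ECA totals, the 0D junction predicts a mean
ICA share of ≈ 40.3%. Three-dimensional CFD studies with these boundary
conditions report ≈ 71.6%, close to the clinical ~70/30 carotid split.
The package reports the 0D prediction and makes no attempt to force
agreement: the 0D junction sees only the outlet totals, whereas a 3D
domain inserts the branch geometry itself between inlet and outlets, and
the exact solver-side boundary configuration behind the published 3D
number cannot be reconstructed from the published totals. Note also that
the published ICA distal resistance at the centre of that comparison is
exactly the step-19 value the discrepancy report flags.

Periodic steady state (`periodic_convergence()`) is declared when the
per-cycle summaries (mean junction pressure, per-outlet mean flows)
change by less than $10^{-4}$ relative between consecutive cycles; the
default budget of 7 cycles follows common simulation practice and is
ample for physiological $R_d C \ll T$. Capacitor pressures start at the
distal reference; the initial transient is discarded by the detector.

## The synthetic inflow generator

No clinical inflow waveform is bundled — the curves used in the
validation literature are unpublished — so `synth_inflow()` generates a
deterministic truncated-Fourier pulse with an exactly prescribed cycle
mean (default 5.35 cm³/s at the common carotid, cardiac periods 0.55 s or
0.753 s as presets, any period accepted). The default four harmonics give
a carotid-like systolic upstroke and diastolic decay, and their relative
amplitudes sum to 0.78 < 1, so the flow is strictly positive by
construction; parameter sets that cross zero are rejected unless
explicitly allowed.

What this emulates is the *scale and pulsatility* of a carotid inflow;
what it does not emulate is any individual patient's waveform shape,
dicrotic notch, or beat-to-beat variability. Since the simulator's
headline outputs (mean splits, steady pressures) are provably
shape-independent, the property tests carry over to real waveforms; the
instantaneous pressure traces are only as patient-specific as the inflow
fed in.

## Numerical choices, in one place

* SI units everywhere internally; millimetres only in files, converted at
  I/O. Exports serialise at 15 significant digits (round-trip exact for
  table-derived values, idempotent under the unit conversion) plus a
  3-significant-figure display block.
* Reduction intermediates at full precision; 1% comparison tolerance
  against 3-significant-figure published values.
* Backward Euler, default $dt = T/1000$, capped at $T/64$; divergence
  (non-finite pressure) is an error naming the step size.
* Convergence tolerance $10^{-4}$ relative per cycle, 7-cycle default
  budget, both overridable.
* Degenerate inputs rejected at construction: non-positive geometry,
  zero compliance in series, zero resistance in parallel, junctions with
  zero proximal resistance.

## Problem sizes used in the checks

The bundled analyses are small by design: a 38-row table, 58 reduction
steps, and 0D simulations of $10^3$–$10^4$ steps per cycle over at most a
few tens of cycles. The full test suite and the acceptance script each
run in seconds on a single core.

## Known limitations

* Lumped tube physics only: no pulse-wave propagation (1D), no inertance
  (4-element Windkessel), no fluid–structure interaction, no
  non-Newtonian correction inside the resistance formula.
* The atlas is an anatomical composite from published means, not a
  patient; small M2/ophthalmic branches are deliberately dropped, and no
  claim of anatomical completeness is made.
* The published step-19 ICA totals remain unexplained; the package
  surfaces both candidate values and defaults to printed-with-warning
  rather than guessing which the upstream 3D studies actually used.
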