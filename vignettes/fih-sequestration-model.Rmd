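---
title: "Methods: kinetic models of FIH sequestration by ankyrin-repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic models of FIH sequestration by ankyrin-repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fihcomp)
```

## The biological system and the modelling assumptions

HIFα is continuously synthesised and degraded. In normoxia, PHD-catalysed
prolyl hydroxylation of the ODD accelerates degradation; FIH-catalysed
asparaginyl hydroxylation of the CAD switches off CAD-dependent
transcription without affecting stability. FIH additionally hydroxylates
asparagines in ankyrin repeats (ARs); unhydroxylated ARs bind FIH and
sequester it, while hydroxylation weakens that binding, so FIH activity
releases FIH. The package models this network under the standard
simplifications for healthy cells: HIFβ, 2-oxoglutarate and Fe(II) are
non-limiting; degradation of ODD-hydroxylated HIFα and DNA binding of HIF
are fast compared to ODD hydroxylation; asparaginyl hydroxylation is
irreversible, so hydroxylated ARD proteins are replaced only by turnover
and de novo synthesis. The FIH·ARD complex is not an explicit dynamical
species: its formation is taken at quasi-steady state and folded into the
AR-hydroxylation rate function. Stochastic and spatial effects are out of
scope.

Because the enzymes are not in trace amounts relative to HIFα, the HIFα
hydroxylation rates use tight-binding (free-substrate) kinetics: the free
substrate is the positive root of the binding quadratic
(`free_substrate()`), valid without substrate excess. AR hydroxylation
uses the Michaelis–Menten approximation, justified by the expected excess
of ARD proteins over FIH. Competition enters twice: ARs inflate the
apparent FIH/HIFα dissociation constant (`ki_fh()`), and free HIFα
competitively inhibits AR hydroxylation.

## Parameters, units and defaults

Everything is dimensionless (`nondimensionalize()` maps dimensional rate
constants onto these groups): concentrations are relative to the maximal
HIFα level reached in anoxia, rates relative to the basal HIFα
degradation rate constant, time in mean HIFα lifetimes (τ), and oxygen
relative to the PHD Michaelis constant for oxygen (Õ₂). The FIH/ARD
reduction (SKM2) instead normalises the repeat pool to `A_tot` (so its
state is the unhydroxylated fraction), measures time in mean ARD-protein
lifetimes (σ) and oxygen relative to the FIH Michaelis constant (Ō₂);
`oxygen_tilde_to_bar()` converts so cross-model comparisons cannot
silently mix conventions.

Fixed defaults in `full_params()`: `P_tot = 0.2`, `KD_P = 1`,
`kcat_P = 500`, `F_tot = 1`, `KD_FH = 1`, `kcat_FH = 500`, `omega = 1`,
`alpha = 0.33`, `KD_FA = 1`, `KD_HRE = 0.3`. FIH binding and turnover
match PHD's; the five-fold excess of FIH activity needed for appreciable
CAD hydroxylation is carried entirely by the concentration ratio
`F_tot/P_tot = 5`. Whether that excess enters through concentration,
affinity or turnover does not change the qualitative conclusions, so we
do not re-derive it. One documentational ambiguity deserves note: the
turnover ratio `omega` is described in words as CAD- over
ODD-hydroxylation turnover but defined by its formula as
`kcat_FH / kcat_FA`. We implement the formula (`kcat_FA = kcat_FH /
omega`); at the default `omega = 1` the two readings coincide, and the
discrepancy is flagged here rather than resolved.

The three parameters that the analyses scan — the FIH-target pool
`A_tot` (0–500), the product-binding ratio `gamma` (0–0.1) and the ARD
stability ratio `epsilon` (1–10) — default to the reference time-course
set `A_tot = 100`, `gamma = 0.02`, `epsilon = 5`, chosen because it is
the configuration the memory-effect analysis is defined at; scans
override them explicitly. `SKM2` takes `kappa = A_tot/KD_FA` and
`beta = kcat_FA·F_tot/(kd_A·A_tot)` directly. `A_tot = 0` is legal in
the Full Model (no FIH/AR interaction) but rejected when constructing
SKM2 parameters from dimensional values, since `beta` has `A_tot` in its
denominator.

## Numerical choices

*Integration.* `kcat' = 500` makes the HIFα equations stiff at high
oxygen, so all time courses use `deSolve::ode` with `lsoda` (default
tolerances `rtol = 1e-8`, `atol = 1e-10`, configurable). Oxygen
protocols are piecewise constant only; integration restarts exactly at
each breakpoint so steps are sharp.

*Steady states.* Computed by relaxation — integrating until
`max |dX/dt| < 1e-9` — the same procedure used to generate the original
steady-state analyses, with internal tolerances tightened to
`rtol = 1e-10`, `atol = 1e-12` so the residual criterion is meaningful.
Chunks grow geometrically up to a time cap of 10⁴ time units, which
covers well over 10³ ARD-protein lifetimes, the slowest mode of the
system; non-convergence raises an error carrying the residual. The
solver is validated against two independent closed forms in the test
suite: a bisection solution of the binding conservation equation
(agreement to 1e-10) and the quadratic root of the SKM2 steady-state
balance (agreement to better than 1e-8 over a 10×10×10 grid of κ, β,
Ō₂). Oxygen scans warm-start each solve from the neighbouring grid
point. These solver settings were fixed by the oracle-agreement
requirement, not inherited from any published configuration, which
reports no integrator tolerances.

*Response metrics.* Oxygen grids default to 60 log-spaced points on
[1e-4, 1] (tilde units), since the interesting behaviour spans decades
of hypoxia. The "oxygen threshold" of a sigmoid response is
operationalised as the half-range crossing (level 0.5), located by
linear interpolation in log-oxygen between bracketing grid points;
ultrasensitivity as the classical 10–90% apparent Hill exponent
`ln(81)/ln(o90/o10)`. The alternative local response coefficient was
rejected as too sensitive to grid noise. Peaks are refined by a
quadratic through the three bracketing points in log-oxygen, with an
interior-peak flag. All three metrics are checked to be stable under
two-fold grid refinement to 1%. The reoxygenation delay is the time
after the step at which an observable crosses half the distance from
its value at the step to its final value; these 50% levels are our
choices — the figures the quantities summarise print no defining
numbers.

*Free FIH in the Full Model.* The Full Model does not integrate free
FIH; the observable is defined from the same equilibrium-binding algebra
as the rate laws, `F_free = KD_FH / (Ki_FH + H_F)`, i.e.
`1/(1 + H_F/KD_FH + A/KD_FA + γA_OH/KD_FA)`, which reduces exactly to
the SKM2 expression `1/(1 + κÂ)` when HIFα is absent and `γ = 0`.

*Degenerate inputs.* The discriminant of the binding quadratic is
clamped at zero to absorb rounding when `s_tot ≈ e_tot` and `kd → 0`,
and the cancellation-free form of the root is selected by the sign of
`kd + e_tot − s_tot`. States are clamped to their physical ranges inside
the right-hand sides so integrator excursions of order the absolute
tolerance cannot produce negative rates.

## The ankyrin census

`classify_repeat()` implements the motif rules on 1-based positions from
the repeat's N-terminus: a repeat is a potential FIH target if it has an
asparagine in the loop region (positions 25–33); it carries the L⁻⁸N
motif if any loop asparagine at position p has leucine at p − 8 (the
rule is evaluated against every loop asparagine, not only the canonical
Asn-29, because the motif is defined relative to the hydroxylated
asparagine without fixing it); and it matches the stringent consensus if
positions 21–29 read `L(X)₄(AC)(DEN)(ILV)N`. N-terminal numbering for
the 32/34-residue repeats is our alignment convention — the simplest
reproducible one, affecting under 10% of repeats. Repeats shorter than
29 residues are reported unclassifiable. Consensus and
position-frequency summaries are restricted to lengths 32–34; shorter
retained repeats are padded with `X`, which occupies its own matrix row
and never enters the consensus; consensus ties break alphabetically and
are flagged. Database redundancy is removed on the key
(protein identifier, repeat position), matching how entries from
multiple source databases were collapsed.

## The synthetic repeat database

The curated human AR database the census was originally computed on is a
supplementary file not redistributed here, so `generate_ar_database()`
builds a synthetic stand-in whose default composition equals the
published census: 1505 repeats over 252 proteins, 472 L⁻⁸N repeats (166
strict) in 182 proteins (105 with a strict repeat), 449 further
loop-asparagine repeats, 584 repeats without one, and an out-of-range
length tail of 6% (the published filter excluded just under 10%). Note
the published class counts are internally inconsistent by one (the
Asn-repeat count is quoted as 922, but the per-class rows sum to 921 of
1505); the generator follows the per-class rows, and the census
consequently reports 921. Sequence backgrounds are uniform over the
amino-acid alphabet with loop asparagines and motif-region leucines
scrubbed before the class motif is overlaid, so construction labels and
classifier output agree exactly (a property the tests assert). This is
what the generator emulates — the composition; it does **not** emulate
real AR sequence statistics (per-position residue preferences, the TPLH
tetrapeptide, realistic repeat counts per protein), so census tests
demonstrate the correctness of the classification pipeline, not
biological conclusions about real ARD proteins. Conservation contrasts
between subgroups hold on the synthetic data by construction (motif
positions are constrained in L⁻⁸N repeats) and serve only to validate
the entropy computation.

## Problem sizes and known limitations

The shipped analyses use 60-point oxygen grids, 10×10×10 oracle grids
and time courses of 30–60 τ sampled at 0.02 τ; a full scan of the Full
Model takes about two seconds on one core, so the complete test suite
and the reproduction script each run in well under a minute.

Limitations worth keeping in mind: all conclusions are qualitative —
the dimensionless parameters are order-of-magnitude estimates, and no
dimensional calibration (μM, %O₂) is attempted; the model has a single
lumped AR pool, whereas real ARD proteins differ in affinity,
accessibility and expression; bifurcation analysis is not provided (the
system is assumed, and numerically observed, to have a single
attractor — steady states are cross-checked from two initial
conditions); and one published qualitative claim is only partially
sharp: the SKM2 release threshold is insensitive to the sequestration
capacity κ in the strong-sequestration regime (κ ≳ 10; spread well
under 1%), but at κ = 3 the half-range threshold shifts by several
percent because sequestration is weak enough that `κÂ` is of order one
at release.
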