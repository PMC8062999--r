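---
title: "Bistable switches from mRNA-miRNA titration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable switches from mRNA-miRNA titration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmiswitch)
```

## The circuit and its reduction

The core object of this package is a mass-action reaction system in which one
mRNA species `R` carries `n` binding sites (`n` = 1, 2 or 3) for a cognate
miRNA `r`. Binding is stepwise: the complex carrying `i` miRNAs, `C_i`, binds
a further miRNA to form `C_{i+1}` and releases one to fall back. Both species
are synthesized at constant rates (`s_R`, `s_r`) and degrade with first-order
kinetics, at basal rate constants (`k_R`, `k_r`) when free and at multiples of
those rates when complexed: the mRNA in `C_i` degrades at `a_i * k_R`, and
each bound miRNA at `b_i * k_r`. Degradation of one partner releases the
other intact (multiple turnover): mRNA decay inside `C_i` frees its `i`
miRNAs, and decay of one miRNA steps the complex down to `C_{i-1}`. There is
no transcriptional regulation anywhere in the core circuit — every reaction
is an elementary mass-action step.

Because binding and unbinding are much faster than synthesis and turnover,
the package analyzes the circuit under the total quasi-steady-state
assumption (tQSSA): the binding steps are treated as equilibrated, and the
dynamics are written in the two slow variables, total mRNA
`R_T = R + sum(C_i)` and total miRNA `r_T = r + sum(i * C_i)`. At binding
equilibrium the complexes obey

    C_i = w_i * R * (r/K)^i

with a single per-site dissociation constant `K` and multiplicity weights
`w_i`. Under the default `statistical_factors` convention `w_i =
choose(n, i)`, the equilibrium of `n` equivalent, independent sites; the
`plain` convention (`w_i = 1`) is retained as a configuration alternative.
The default was fixed by a numerical calibration against the two published
bistable fractions for the two- and three-site screens (see below): the
statistical-factors convention reproduces both, the plain convention
underestimates the three-site fraction by eight percentage points.

Substituting the equilibrium into the conservation laws leaves one polynomial
of degree `n + 1` in the free miRNA whose unique root in `[0, r_T]` is the
physical branch (`solve_complexes()`); the reduced system is then

    dR_T/dt = s_R - k_R * R * phi_a(x),   phi_a(x) = 1 + sum w_i a_i x^i
    dr_T/dt = s_r - k_r * (r + R * psi_b(x)),  psi_b(x) = sum i w_i b_i x^i

with `x = r/K`. The factor `i` in `psi_b` reflects the `per_molecule` miRNA
loss convention — each of the `i` bound miRNAs decays independently — and is
what places the factor 2 in the analytic bistability condition below;
`per_complex` is available for sensitivity analysis but does not reproduce
the published results.

Everything is nondimensionalized: concentrations in units of `s_R / k_R`,
time in units of `1 / k_R`, so the only surviving scales are `s_r`, the
multipliers `a_i`, `b_i`, and the scaled dissociation constant
`K_scaled = K * k_R / s_R` (default `1e-5`, strong binding).

## Steady states, folds and the closed-form classifier

At a fixed point the mRNA balance gives `R = (s_R/k_R) / phi_a(x)`, and the
miRNA balance becomes a closed-form expression for the control parameter:

    s_r(r) = k_r * ( r + (s_R/k_R) * psi_b(x) / phi_a(x) )

Every steady state is therefore a root of a low-degree polynomial
(`steady_states_at()`), and the whole bifurcation structure of the circuit is
the graph of `s_r(r)`: saddle-node folds are its interior extrema, found
exactly as positive roots of the numerator polynomial of `ds_r/dr`
(`bifurcation_diagram()` sweeps `r`, the natural parameter along the
S-curve, so folds are never stepped over). Stability is computed from the
reduced two-variable Jacobian, obtained by implicit differentiation through
the binding algebra, and cross-checked in the test suite against the full
mass-action system at fast binding and against forward integration from
random initial states.

The fold polynomial is

    N(x) = phi_a(x)^2 + (1/K_scaled) * [ psi_b'(x) phi_a(x) - psi_b(x) phi_a'(x) ]

and for the two-site circuit the bracket collapses to
`2 * (b1 + 2 b2 x + (2 a1 b2 - a2 b1) x^2)`: with strong binding
(`1/K_scaled` large) the curve is non-monotonic — and the circuit bistable —
exactly when the quadratic coefficient is negative, i.e. when

    a1 / b1 < a2 / (2 * b2)

(`analytic_condition()`): the per-mRNA degradation gain of the doubly
occupied complex must exceed twice that of the singly occupied one. This is
the hidden feedback: two stoichiometric inhibitors with occupancy-dependent
degradation asymmetry form a net double-negative loop even though the wiring
diagram contains no regulatory arrow. `critical_ratio()` verifies the
threshold `2 * a1 / b1` numerically by bisection; because the threshold is
exact only in the strong-binding limit, the bisection uses
`K_scaled = 1e-9` by default (at `1e-5` the finite-affinity threshold is
about 4% higher; the convergence is recorded in the test suite).

The random screen (`run_screen()`) classifies 10,000 parameter sets per call
by this closed-form test — no continuation, no integration — which takes
seconds. A set is called bistable when the control curve is non-monotonic
with the fold interval overlapping the observable control window
`[0, 10]`; an attractor-census audit by direct integration confirms the
classifier on random subsets in the tests. Switch magnitudes are measured at
the up-switch fold: the log10 ratio of free (and of total) mRNA between the
upper-branch fold state and the lower branch at the same control value.

## Chemical reaction network indices

`build_network()` writes the canonical mass-action network of the circuit
(shared empty complex for synthesis and decay, stepwise binding chain,
complex-resolved degradations with partner release), and `deficiency()`
computes `delta = n_complexes - n_linkage_classes - rank(S)` with the rank
taken in exact integer arithmetic. For the canonical one-site network the
package obtains `n = 5, l = 1, s = 3`, hence deficiency 1, and deficiency 3
for the two-site network. Published analyses of this circuit family report
deficiency 0 and 1 respectively; the discrepancy traces to how the
complex-degradation reactions are written (the recycling arcs `C_1 -> R` and
`C_1 -> r` join the binding chain to the synthesis/decay linkage class,
changing both `l` and the complex count). The package reports the indices of
the canonical network as constructed and makes the construction explicit
rather than forcing agreement with a network file that is not reproduced
here. The monostability of the one-site circuit is established directly (its
control curve is strictly monotone for all positive parameters) and verified
on 10,000 broadly sampled parameter sets.

## The tissue models

`simulate_tissue()` integrates 400 autonomous cells (10 columns x 40
rostrocaudal positions) under antiparallel retinoic-acid (RA, rostral) and
FGF (caudal) gradients with exponential spatial decay (length scale 12
positions) and a shared amplitude that rises over 5 time units, plateaus to
t = 20, and recedes with time constant 10 to a low plateau at 40% of peak.
Cells sense the gradient multiplied by white noise (Euler-Maruyama; the
per-step factor is `1 + sigma * z / sqrt(dt)`, clipped at zero, so the
sensed-signal variance is `sigma^2 * backbone^2 / dt`). Defaults:
`sigma = 0.1`, `dt = 0.02` (tests and multi-seed comparisons use
`dt = 0.05`), horizon 60 time units. These choices emulate transient, noisy
morphogen exposure during axis elongation; they do not attempt to model
diffusion explicitly (uniform degradation makes the steady gradient
exponential), cell division, migration, or cell-cell signaling, so passing
tests speak to the gene-regulatory layer only.

Six cell-level variants share this scaffold. All transcriptional edges are
Hill functions with per-edge threshold and coefficient, declared in each
spec's regulation table:

* `T_CR` — canonical cross-repression (Hoxa5 and Hoxc8 repress each other,
  Hill n = 4 on the protein edges). The repressor shuts the whole promoter.
* `T_UR` — unilateral repression only (Hoxc8 represses Hoxa5), with very
  high cooperativity (n = 4) on morphogen and repression edges; no feedback
  loop exists.
* `Tmi_UR` — `T_UR` plus morphogen-driven miRNAs forming coherent
  feed-forward loops (FGF activates miR-27 which titrates Hoxa5 mRNA; RA
  activates miR-196 against Hoxc8), with balanced complex degradation:
  titration thresholds without feedback.
* `Tmi_FB` — `T_UR` plus miRNAs transcriptionally repressed by their own
  targets, the canonical TF-miRNA double-negative loop.
* `mmi_S` — the noncanonical architecture: each Hox mRNA binds its miRNA at
  two sites with cooperative miRNA protection (`a = (1, 1)`,
  `b = (1, 0.1)`), making each pair a bistable titration switch; miR-27 is
  constitutive and spatially uniform, miR-196 is FGF-activated and therefore
  broadly expressed caudally. Hoxc8 represses the RA-driven part of Hoxa5
  transcription but not its basal term — the knockout phenotype (see below)
  requires caudal Hoxa5 transcription to persist under Hoxc8, with its
  silencing delegated to miR-27.
* `mmi_S_nofeedback` — `mmi_S` with balanced complex degradation
  (`b = (1, 1)`); titration without memory, the negative control.

Proteins follow free mRNA with first-order kinetics (`k_p = 0.5`), so
miRNA-bound mRNA is translationally silent. Fate calls threshold each
protein at 10% of its maximal attainable level; for miRNA-bearing variants
"attainable" accounts for the miRNA pool (the free mRNA of the pair at full
transcriptional drive), since the bare transcription ceiling is never
reachable while the miRNA is expressed. The transition width counts
positions holding at least one cell that is double-positive,
double-negative, within 10-fold of protein-ratio parity, or whose fate call
flips between protein checkpoints recorded over the final ten time units —
the last term is what distinguishes architectures that merely look sharp in
a snapshot from those whose decisions are stable in time.

Under these defaults the wild-type `mmi_S` tissue resolves into a rostral
Hoxa5-only block and a caudal Hoxc8-only block with no double-positive
cells, while both total mRNAs remain co-expressed across a broad band
spanning the boundary; the segregation index (protein-to-mRNA ratio of
boundary steepness along the axis) is well above 1. With position as the
control parameter and the morphogens frozen at their final plateau, the
single-cell model is tristable over a contiguous mid-domain window
(both-off, Hoxa5-on, Hoxc8-on), which is what confers robustness to the
receding gradients. Median transition widths over matched noise realizations
order the architectures as: cross-repression and the two feedback-bearing
miRNA circuits sharp, unilateral repression and the feed-forward circuit
blurred, and the feedback-less titration control much wider still.

Silencing a miRNA (`knockout()`) sets its synthesis to zero in all cells.
Loss of miR-27 leaves caudal Hoxa5 transcription untitrated, producing
double-positive cells throughout the caudal domain and, in the positional
analysis, replacing the caudal exclusive state with a double-positive stable
state. Loss of miR-196 lowers the drive needed for Hoxc8 protein to register
as on, moving the Hoxa5/Hoxc8 boundary rostrally.

## The single-cell RA-pulse protocol

`ra_pulse_experiment()` drives one cell carrying a three-site Hoxa5/miR-27
circuit with a high-then-low RA schedule after a burn-in at zero RA (so the
miRNA pool is equilibrated, as in progenitors that express the miRNA before
morphogen exposure). The sensed RA relaxes toward the protocol target with a
wash-in/washout time constant, making passages through the bistable window
adiabatic. With miR-27 active the RA response curve has a bistable window
covering the low level: a pulsed cell stays Hoxa5-high after the switch
while an unpulsed cell stays low (hysteresis); with miR-27 silenced the
response is monotone and the pulse leaves no memory.

One limitation is worth stating plainly: in a pure titration circuit the
knockout's steady-state Hoxa5 is always at least as high as the wild type's
at the same transcription rate (the miRNA only removes target mRNA), so no
single protein threshold can simultaneously read the wild-type memory state
as "on" and the knockout at the same low RA as "off". The package therefore
expresses loss of hysteresis as what it is — identical pulsed and unpulsed
outcomes and a vanished bistable window — rather than as a threshold
crossing. The "on" gate for the bimodal readout is 10% of the level
attainable at the low RA condition.

## Motif enumeration

`count_motifs()` bounds the number of circuit instances in a miRNA
target-site catalog: the lower bound counts gene-family pairs with at least
`k` conserved sites; the upper bound counts all distinct `k`-subsets of
sites (conserved and nonconserved) sharing gene and family, without merging
overlapping sites. Published genome-wide counts from this procedure depend
on the catalog release and are therefore documented as reference points, not
asserted; `generate_catalog()` produces synthetic catalogs with
generation-time ground truth for exact testing, and the Poisson closed-form
expectations of both bounds are verified on large draws.

## Numerical choices

* Binding-equilibrium root solves: polynomial root extraction with a bisection
  fallback and Newton polish; conservation residuals audited at `1e-9`
  relative. The tissue simulator uses a warm-started vectorized Newton
  iteration over all cells (tolerance `1e-10`).
* Fold degeneracy: steady-state roots closer than `1e-8` (relative, on the
  scaled miRNA) are merged and flagged.
* Reduced-versus-full agreement: the tQSSA totals match the full system to
  1% at association rate `kon = 1e8` (nondimensional); at `kon = 1e4` the
  high branch still deviates by several percent, so "fast binding" in the
  tests means `1e8`.
* Separatrices: backward-time integration from the saddle along its stable
  eigendirections.
* Screens: one master seed; the draw is a single block, so records are
  independent of evaluation order.
* Problem sizes: screens use 10,000 sets; integration oracles use 25-40
  random sets with a handful of initial conditions each; tissue comparisons
  use 5-20 seeds at `dt = 0.05`. The vignette's defaults are the package's
  standard study conditions.

## Experiment runner

`run_experiment()` dispatches a flat YAML configuration (experiment name,
seed, output directory, parameters) to the screen, bifurcation, phase-plane,
CRNT, tissue, motif, RA-pulse or fixture-export workflows, and writes CSV
tables, a JSON summary, the echoed configuration and a log with seed and
package version, so every output directory is regenerable from its own
contents. A thin command-line wrapper over this function is installed under
`inst/scripts/`.
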