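# mmiswitch

Elementary mRNA–miRNA reaction circuits — one mRNA with 1–3 binding sites
for a cognate miRNA, mass-action synthesis, stepwise binding, and
complex-resolved degradation — can behave as bistable switches even though
their wiring contains no regulatory arrow. The hidden feedback comes from a
pair of stoichiometric inhibitors whose degradation rates depend on complex
occupancy: writing `a_i` and `b_i` for the degradation multipliers of mRNA
and miRNA in the 1:i complex, the two-site circuit admits three positive
steady states only when

```
a1 / b1  <  a2 / (2 * b2)
```

`mmiswitch` implements this theory end to end in R:

* **Core models** — the full mass-action systems and their total
  quasi-steady-state (tQSSA) reduction to two totals coupled through an
  algebraic binding equilibrium, plus a competitor-mRNA (ceRNA) extension.
* **Steady-state analysis** — exhaustive root extraction of the closed-form
  steady-state polynomial, Jacobian stability, one-parameter bifurcation
  diagrams with exact saddle-node folds, nullclines and separatrices.
* **Bistability screening** — a closed-form classifier that handles 10,000
  random kinetic parameter sets in seconds, switch-magnitude metrics, and a
  numerically bisected critical degradation ratio.
* **Reaction-network structure** — deficiency, linkage classes and weak
  reversibility of the canonical networks, with exact integer rank.
* **Tissue patterning** — a 10 × 40 cell grid of autonomous cells under
  transient, noisy antiparallel RA/FGF gradients, comparing six
  gene-regulatory architectures for Hoxa5/Hoxc8 motor-neuron boundary
  formation, with miRNA-knockout, positional-bifurcation and single-cell
  RA-pulse hysteresis protocols.
* **Motif enumeration** — lower/upper bounds on multi-site circuit
  instances in miRNA target-site catalogs (TargetScan-style TSV layout),
  with a synthetic-catalog generator carrying exact ground truth.

## Worked example

```r
library(mmiswitch)

# a two-site circuit with cooperative mRNA degradation in the full complex
p <- mmi_parameters(n_sites = 2, a = c(1, 10), b = c(1, 1))
bd <- bifurcation_diagram(p, control_range = c(0, 4))
bd
#> bifurcation diagram in s_r: 401 branch points, 2 folds
#>   bistable for s_r in [0.20253, 0.33334]

steady_states_at(p, control_value = 0.27)[, c("R", "r", "stability")]
#>              R            r            stability
#> 1 5.461969e-01 2.050970e-06 stable_node_or_focus
#> 2 2.490422e-02 1.881258e-05               saddle
#> 3 2.042092e-09 6.997714e-02 stable_node_or_focus
```

For miRNA synthesis rates between the two folds the circuit holds two stable
states whose free mRNA differs by more than eight orders of magnitude — an
all-or-none switch — separated by a saddle. Sweeping random kinetics:

```r
run_screen(n_sites = 2, n = 10000, seed = 1)
#> bistability screen, mmi-2: 3330 / 10000 bistable (33.30% +- 0.47%)
```

About a third of uniformly drawn degradation-multiplier sets form bistable
switches, with no constraint on any individual rate — only on the ratios.
The tissue layer turns the same mechanism into robust boundary formation:

```r
field <- make_morphogen_field(noise_sigma = 0.1, seed = 3)
tissue <- simulate_tissue(cell_model_spec("mmi_S"), field, t_end = 60,
                          dt = 0.05, seed = 3)
table(fate_calls(tissue))
#> A5off_C8on A5on_C8off double_off
#>        293         89         18
transition_width(tissue)
#> [1] 5
segregation_index(tissue)
#> [1] 4.58
```

Rostral cells commit to Hoxa5, caudal cells to Hoxc8, no cell expresses both
proteins, and the protein boundary is several-fold sharper than the
underlying (broadly overlapping) mRNA profiles.

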