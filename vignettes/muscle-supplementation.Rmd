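---
title: "Constraint-based analysis of amino-acid supplementation in skeletal muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of amino-acid supplementation in skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleflux)
```

## The model

`muscleflux` implements steady-state flux balance analysis (FBA) for the
question: which amino-acid supplements, singly or in combination, can
raise the synthesis flux of the muscle contractile protein complex?

A stoichiometric model collects metabolites and reactions into the
matrix $S$ (metabolite rows, reaction columns, signed coefficients).
Steady state requires $S v = 0$ for the flux vector $v$, and every
reaction carries bounds $l \le v \le u$. The analysis maximizes the flux
of a single *demand* reaction that consumes amino acids and
ATP/GTP-equivalents and produces one unit of the contractile complex:

$$\max\; v_{\mathrm{demand}} \quad \text{s.t.}\quad S v = 0,\; l \le v \le u.$$

The optimal *value* of this linear program is unique even when the
optimal flux *vector* is degenerate; `solve_fba()` flags degenerate
optima, and all downstream comparisons rest on objective values only.
Per-reaction flux differences between two optima
(`flux_difference()`) should therefore be read qualitatively.

### The contractile complex

The objective demand is built from per-protein amino-acid compositions
and the sarcomeric stoichiometry 7 actin : 7 myosin : 1 tropomyosin
dimer : 1 troponin complex. Myosin expands to a fiber-type-specific
heavy chain plus the light chain kinase and the phosphorylatable light
chain (each ×7); the tropomyosin dimer contributes two chains of the
type-appropriate isoform; troponin contributes its C, I and T subunits
once each. That makes 33 polypeptide chains per complex, so a complex
of $R$ total residues requires $R - 33$ peptide bonds. Each bond costs
`energy_cost_per_bond` ATP-equivalents — default 4, read as 2 ATP for
amino-acid activation plus 2 GTP for ribosomal elongation, split evenly
by `build_demand_reaction(gtp_fraction = 0.5)`. The packaged
composition table (`contractile_compositions()`) is a clearly labelled
*synthetic* stand-in: residue counts drawn once from average proteome
amino-acid frequencies at realistic chain lengths (actin 375, myosin
heavy chain ≈1940, tropomyosin 284, ...), not database-verified
sequences. Quantitative conclusions about real fiber types need real
compositions via `read_compositions_tsv()` or
`read_compositions_fasta()`.

### Conditions: concentration as a flux proxy

Measured uptake fluxes for all 20 amino acids into muscle are not
available, so the model adopts the standard proxy: the uptake upper
bound of each exchanged metabolite equals its plasma concentration
(mmol/L), applied numerically with an arbitrary shared time unit. The
two packaged profiles (`plasma_condition()`) are the overnight-fasting
and the post-absorptive (≈2 h after a protein meal) means; the reported
inter-subject variability ships in the condition file but is never
applied as a bound, since the analysis uses single control profiles.
Uptake lower bounds are zero (no forced uptake); secretion runs through
separate `SEC_` reactions so that amino acids produced in excess (the
glutamine pattern) can leave the tissue.

### Supplementation

`supplement()` raises the uptake bound of chosen amino acids to the
conventional "unlimited" cap of 99999 — effectively removing the
constraint while keeping the LP bounded, which in turn keeps every
subproblem's optimum finite and the bound-relaxation monotonicity
property exact. `sweep_supplements()` enumerates all subsets of size
1..`k_max` (default 7; the count grows as $\sum_k \binom{20}{k}$, about
137,979 LPs at `k_max = 7`). `best_per_size()` reports the per-size
argmax with alphabetical tie-breaking, flagged in a `tie` column. The
optional prune uses one proven bound — the optimum under relaxing *all*
candidates at once dominates every subset — purely to short-circuit
saturated sweeps; pruned and exhaustive runs agree on every best-per-size
entry by construction, and the tests assert it.

### Expected versus actual effect

`availability_counts()` divides each plasma concentration by the
control objective flux, giving the number of complexes' worth of each
amino acid the plasma could supply. Subtracting the per-complex residue
need and ranking ascending gives the *expected* effect (rank 1 = most
limiting). The *actual* effect orders amino acids by the smallest
subset size at which they first appear in a best-per-size subset — an
explicit design choice, stated in the export header.
`compare_expected_actual()` joins the two rankings and reports a
Spearman-footrule statistic over the co-ranked amino acids. On pure
assembly models the two rankings provably coincide (availability is the
only mechanism); divergence requires catabolic or biosynthetic routes,
and the test suite exhibits both regimes.

## The synthetic generator

Because the analysis needs models with known answers, `toy_spec()` +
`make_assembly_model()` build minimal networks — amino-acid uptakes
feeding one demand — whose optimum has the closed form

$$v^\ast = \min_{aa:\, c_{aa} > 0} \frac{\mathrm{conc}(aa)}{c_{aa}},$$

with $c_{aa}$ the per-complex residue count. `make_muscle_like_model()`
adds the structural features the real analysis assumes: a lumped
glucose→ATP route (30 ATP/glucose by default — a deliberate
simplification of glycolysis plus oxidative phosphorylation, not a full
electron-transport reconstruction), fatty-acid oxidation (100
ATP/palmitate, 90 for the C14 acid), ATP-yielding catabolism of the
muscle-oxidizable amino acids (default yield 20 ATP each), optional
biosynthesis of non-essential amino acids from a glutamate hub at 1 ATP
apiece, and secretion routes. Generator defaults are the fasting plasma
means (glucose 5, palmitate 0.125, tetradecanoate 0.230 mmol/L);
random compositions are uniform on 1..60 residues and random
concentrations log-normal around 0.12 mmol/L — the order of magnitude
of plasma amino-acid levels — floored at the smallest observed plasma
value (0.003). All randomness flows from the spec's single `seed`, and
generation restores the caller's RNG state.

What the toys do *not* emulate: compartmentation (everything lumped
into one cytosol besides the formal compartment tags), explicit
cofactor chemistry beyond the ATP/ADP/Pi cycle, oxygen/CO2 balancing,
and the curated reaction-level detail of a real muscle reconstruction.
Passing tests on these models therefore validate the *machinery* —
solver, sweep, rankings — not physiological predictions.
`synthetic_muscle_model()` composes the two layers: the full 20-amino-
acid muscle-like network whose demand is the canonical type-2a complex
built from the packaged compositions, bounded by a packaged plasma
profile. It is the package's stand-in study system, and the quantities
the acceptance script reports are computed on it.

## Numerical choices

* **LP solver.** `solve_fba()` uses a bounded-variable revised simplex
  written for this package: nonbasic variables rest on a bound, the
  basis system is re-factorized every iteration (so tableau error
  cannot accumulate), phase 1 drives signed artificial columns to zero
  and then freezes them, which copes with rank-deficient $S$ (redundant
  mass-balance rows) without special-casing. Dantzig pricing switches
  to Bland's rule after a stall to guarantee escape from degenerate
  cycling; ties in the ratio test prefer the largest pivot magnitude.
  Pivot tolerance 1e-9; steady-state residuals are re-checked after the
  final refinement step and warned about above 1e-6. Correctness is
  pinned by an exhaustive vertex-enumeration oracle
  (`brute_force_vertex_optimum()`, refused above 10 reactions) and by
  the assembly closed form.
* **Rank.** `model_stats()` counts singular values above
  `max(dim(S)) * eps * max(sv)` (overridable). Degrees of freedom are
  reported as the *conserved-pool count*, `n_metabolites - rank` — the
  left-null-space dimension, i.e. invariant metabolite combinations at
  steady state — rather than the flux-space nullity
  `n_reactions - rank`.
* **Bounds.** Infinite bounds are capped at 99999 before solving, the
  same cap used for "unlimited" supplementation, so every LP is a
  bounded polytope and the infeasible/unbounded distinction stays
  clean. SBML reactions without explicit bounds fall back on the
  reversibility flag: reversible → (−99999, 99999), irreversible →
  (0, 99999).
* **Improvement threshold.** A supplement counts as improving when its
  optimum exceeds the control by more than 1e-9 — far below any
  physiologically meaningful difference at the 1e-5 flux scale, far
  above solver noise (the LP-versus-oracle deviations measure below
  1e-12).
* **Tie-breaks.** Everywhere alphabetical on amino-acid names, flagged
  where a tie was broken, so re-runs are deterministic.

## Problem sizes

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: sweeps to `k_max = 3` on the 20-amino-acid
synthetic muscle model (1,350 LPs, a few seconds), 100 seeded
closed-form specs, 1,000 bound-relaxation monotonicity trials and 20
planted-bottleneck recoveries. A full `k_max = 7` sweep on the same
model is ~138,000 LPs, roughly a quarter-hour at the measured ~7 ms per
solve, and is left to users who want it.

## Known limitations

* The packaged compositions and the lumped energy pathways are
  synthetic; headline fluxes from `synthetic_muscle_model()`
  characterize the method, not human muscle.
* Flux vectors at degenerate optima are solver-dependent; only
  objective values are contract-guaranteed.
* No gene/signaling regulation, no flux-variability or parsimonious-FBA
  post-processing, no non-amino-acid supplements — the scope is the
  uptake-bound-relaxation experiment around the contractile demand.
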