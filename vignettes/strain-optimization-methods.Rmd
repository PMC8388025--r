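---
title: "Methods: phenotype simulation and evolutionary strain design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype simulation and evolutionary strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainopt)
```

This vignette records the modelling choices behind `strainopt`: the
mathematical form of each phenotype-prediction method, the parameters a
user can tune, what the synthetic fixtures do and do not emulate, and
the numerical decisions that make the results reproducible.

## Constraint-based phenotype prediction

All methods operate on the steady-state flux cone
`{v : S v = 0, lb <= v <= ub}` of a metabolic model. Fluxes are in
mmol/gDW/h by convention; biomass flux in 1/h. The assumptions are the
usual ones of constraint-based modelling: the metabolic quasi-steady
state, a linear biomass objective as a proxy for fitness, and bounds as
the only representation of regulation, capacity and medium composition.

* **FBA** maximizes the biomass flux. Optimal flux *vectors* are
  generally not unique; only the objective value is. Tests therefore
  assert objective values and invariants, never full flux vectors,
  except where the optimum is provably unique.
* **pFBA** re-solves with the objective flux pinned to
  `fraction × optimum` (default `fraction = 1`) and minimizes
  `sum |v|` through split variables `v = v⁺ − v⁻`. The reported
  objective value is the stage-1 optimum; the reported flux vector is
  the parsimonious one.
* **FVA** pins the objective to at least `objective_fraction ×
  optimum` and minimizes/maximizes each reaction in turn (two LPs per
  reaction).
* **lMOMA** minimizes `sum |v − w|` against a reference distribution
  `w`; **MOMA** minimizes `sum (v − w)²` as a strictly convex QP
  (via `quadprog`). The reported objective value is the biomass flux of
  the solution, which is what strain-design objectives consume.
* **ROOM** minimizes the number of fluxes outside the window
  `[w − δ|w| − ε, w + δ|w| + ε]` as a MILP with one binary per
  reaction. Defaults `δ = 0.03`, `ε = 0.001` are the canonical values
  from the ROOM literature.

The reference `w` for lMOMA, MOMA and ROOM defaults to the *wild-type
pFBA* distribution under the problem's environmental conditions: pFBA
picks a biologically parsimonious representative among the typically
degenerate FBA optima, which makes the reference (and everything
downstream of it) deterministic. Passing an explicit `reference`
overrides this.

## From gene modifications to flux bounds

Gene-level modifications reach reactions through GPR rules. Deletions
use Boolean evaluation; expression levels use algebraic evaluation with
`and → min` (a complex is limited by its scarcest subunit) and
`or → max` (isozymes are interchangeable). Both reductions are
injectable; `sum` for `or` is shipped for users who prefer additive
isozyme capacity.

A reaction-level fold `γ` is encoded against the wild-type reference
flux `w`:

* `γ = 0` closes the reaction; `γ = 1` is a no-op.
* Under-expression (`γ < 1`) caps the flux magnitude at `γ·w`
  preserving the wild-type direction.
* Over-expression (`γ > 1`) *forces* flux by raising the bound on the
  wild-type side toward `γ·w` (clamped into the original range),
  rather than merely widening the range — merely widening would leave
  the optimum unchanged and make over-expression invisible to FBA-type
  methods.
* Over-expression of a reaction unused in the wild type (`w = 0`) is a
  no-op: there is no direction along which flux could be forced
  without inventing one. This is a genuine modelling choice; decoders
  treat it as "modification without effect" rather than an error.

For enzyme targets the fold scales the reaction's permitted enzyme
usage `(MW/kcat)·v` relative to its wild-type usage; the shared pool
`sum (MW/kcat)·v ≤ P_pool` (g/gDW; kcat in 1/h, MW in kDa) continues
to bind globally, so over-expressing one enzyme redistributes, never
grows, the budget. The wild-type reference for enzyme problems is
computed *with* the pool attached, so folds are relative to the
enzyme-constrained wild type. The single-pool formulation is
deliberately chosen over per-enzyme pseudo-metabolites: at the model
scales this package addresses the constraint semantics are identical
and the surface is far smaller. Parameterized reactions must be
irreversible; `split_reversible()` performs the explicit forward /
backward split (implicit model surgery is error-prone).

## Regulatory integration

Boolean rules (`target = expression` over regulators, `env_`-prefixed
signals, `not/and/or`) are iterated synchronously — the classical rFBA
choice. On a cycle the steady state is the element-wise AND over the
cycle's states: conservative, a gene counts as ON only if it stays ON
throughout. `rfba()` is single-step (steady state, then one FBA), the
form useful inside optimization loops, not the time-stepped dynamic
variant.

`srfba()` solves one joint MILP instead: rule satisfaction is
linearized with standard AND/OR/NOT indicator rows, gene binaries gate
reaction bounds via `lb·b ≤ v ≤ ub·b`, and biomass is maximized over
the joint flux/Boolean space. Cyclic binaries are left *free*
(optimistic): the MILP may certify states the conservative collapse
discards. On acyclic networks the two coincide, which is exactly what
the test suite asserts; the divergence on cycles is documented
behaviour, not a bug. Only reactions whose GPR touches a regulated or
frozen gene receive binaries, which keeps the MILP small.

Regulatory strain-design problems freeze modified regulators in the
network (level 0 → pinned FALSE, level > 1 → pinned TRUE), compute the
steady state, and merge its OFF metabolic genes with the candidate's
direct gene modifications — regulation first, expression levels second.
The deletion-only variant over metabolic genes and TFs corresponds to
the OptORF vocabulary; allowing levels corresponds to OptRAM's
up/down-regulation vocabulary (its TRN activity-scoring model is out of
scope).

## Objectives

`BPCY` uses the substrate-normalized form
`v_biomass · v_product / |v_substrate|` when a substrate is configured
and the bare product–growth product otherwise; both are standard and
the choice is visible in the objective spec. Non-growing strains score
0 rather than negative or undefined values. `WYIELD` evaluates the
product's FVA range with biomass pinned to `objective_fraction`
(default 1.0) of the *mutant's* optimum and returns
`α·v_max + (1−α)·v_min`; `α` defaults to 0.5 as the unbiased midpoint
between the optimistic and pessimistic yield. Infeasible mutants score
0 and are flagged infeasible, and the dominance comparator lets any
feasible candidate dominate any infeasible one, so infeasibility can
never be an attractor.

## Evolutionary engine

Candidates are variable-length sets of `(target, level)` pairs, kept
sorted by target id so that equal sets have equal representations. The
expression-level grid defaults to powers of two around the wild type,
`{0, 1/32, …, 1/2, 2, …, 32}`; knockout problems pin it at `{0}`.
Default operator rates (add 0.3, remove 0.3, swap-target 0.2,
swap-level 0.2, renormalized over the applicable moves; crossover 0.9)
balance exploration over the set representation; they are configuration
fields, not constants. Crossover sends targets shared by both parents
to both children (levels drawn from either parent) and splits
parent-unique modifications uniformly — so identical parents reproduce
exactly.

NSGA-II uses (μ+λ) environmental selection with fast non-dominated
sorting and crowding distance; the GA is generational with binary
tournaments and elitism 1; SA runs a single Metropolis chain with
geometric cooling (`T₀ = 1`, factor 0.9, 10 moves per level by
default). All three maintain a nondominated archive deduplicated by
*decoded constraints* (two candidates with identical effects are one
solution) and truncated by crowding beyond 100 entries. Every random
draw flows from the config seed through one RNG stream owned by the
run, which is what makes archives byte-reproducible. Evaluations are
cached by decoded constraint map in a bounded LRU (10 000 entries),
keyed on effects rather than genotypes so redundant candidates hit the
cache.

## Numerical choices

* Feasibility/equality tolerance is `1e-6` flux units throughout; LP
  solutions are not rounded.
* Infinite bounds clamp to ±1000 at load, the standard convention that
  keeps every LP bounded; consequently the solver layer never needs an
  unbounded status in practice.
* The LP solver is a dense two-phase tableau simplex with Bland's rule
  (guaranteed termination under degeneracy, which knockout-heavy
  problems produce constantly). A presolve substitutes out fixed
  variables (`lb = ub`), both for speed and because zero-width
  variables are exactly what knockouts and branch-and-bound fixing
  create. MILPs use deterministic depth-first branch-and-bound,
  branching on the most fractional binary, down-branch first — adequate
  for the ≤ ~15 binaries that ROOM and srFBA generate on the intended
  model scale, and deterministic so results are reproducible.
* Ties among alternate LP optima are resolved by the deterministic
  pivoting rule; nothing downstream depends on which optimum is
  returned beyond the invariants stated above.

## What the fixtures emulate — and what they do not

`toy_model()` is a minimal branched network with a substrate split
between two biomass precursors and a product branch competing for one
of them: the smallest structure in which growth-product trade-offs,
isozyme GPR logic, knockout lethality and expression tuning all have
visible, hand-derivable consequences. `toy_regulatory()` adds a
one-TF repression cascade; `toy_enzymatic()` a two-enzyme pool tight
enough to bind. `random_model(n, seed)` generates parallel linear
pathways (lengths 1–3, capacities 0.5–8, uptake 2–12 flux units) with
one-gene GPRs and a guaranteed feasible wild type, for property tests
across sizes.

These fixtures exercise the machinery, not the biology of genome-scale
reconstructions: they have no cofactor coupling, no redundant cycles,
no thermodynamically infeasible loops, and trivial GPR depth. Passing
tests therefore certify algorithmic correctness (agreement with
independent LP oracles, exact Pareto fronts on enumerable spaces,
reproducibility), not predictive accuracy on real organisms. Problem
sizes in the tests — toy networks of ~6 reactions, random models up to
~45 reactions, candidate spaces up to a few hundred — were chosen so
every expected value is re-derivable by brute force.

## Known limitations

* No SBML writing; the JSON dialect is the round-trip format.
* rFBA is the single-step variant; no time-course simulation.
* No OptKnock-style bilevel MILP, no growth-coupling certificates.
* The branch-and-bound is not meant for genome-scale ROOM/srFBA; a
  dedicated MILP solver would be the right backend there.
* Enzymatic constraints are the single-pool formulation; published
  GECKO/sMOMENT model files are not ingested.
* SPEA2 and NSGA-III are deliberately not implemented; configs
  requesting them fail with a clear error naming the supported
  algorithms.
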