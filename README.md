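# strainopt

Computational strain optimization over constraint-based metabolic models,
in R.

Metabolic engineering asks which genetic modifications — deletions,
over- or under-expression of reactions, genes, enzymes or regulatory
variables — make a microbe over-produce a target compound while staying
viable. `strainopt` is a workbench for that search. It is organised in
three layers:

1. **Problem definition** — a genome-scale or toy metabolic model (SBML
   Level 3 + FBC, or a plain JSON dialect), the modification target space
   and strategy (knockout vs expression tuning), the target product, the
   growth medium, and optionally a Boolean transcriptional-regulatory
   network and enzyme kinetic parameters.
2. **Phenotype simulation** — flux balance analysis (FBA) and its
   mutant-prediction variants: parsimonious FBA (pFBA), flux variability
   analysis (FVA), linear and quadratic minimization of metabolic
   adjustment (lMOMA / MOMA), regulatory on/off minimization (ROOM), and
   the regulatory integrations rFBA and srFBA, plus sMOMENT-style
   protein-pool enzymatic constraints.
3. **Optimization** — single-objective GA and simulated annealing, and
   multi-objective NSGA-II, evolving variable-length sets of
   `(target, expression level)` modifications and returning a
   nondominated solution archive.

## The models in brief

FBA solves the LP

    max  c'v   s.t.  S v = 0,   lb <= v <= ub

where `S` is the stoichiometric matrix, `v` the flux vector
(mmol/gDW/h) and `c` selects the biomass reaction. pFBA fixes the
objective flux at its optimum and minimizes `sum |v_i|`; FVA reports
`[min, max]` of each flux at a fixed fraction of the optimum; lMOMA
minimizes `sum |v_i - w_i|` against a wild-type reference `w`; ROOM
minimizes the *number* of fluxes leaving a window
`w_i ± delta|w_i| ± epsilon` (a MILP). Gene modifications reach
reactions through GPR rules: Boolean evaluation for knockouts, and for
expression levels the (AND, OR) operators are replaced by (min, max)
over gene expression folds; the resulting reaction-level fold rescales
the flux bounds relative to the wild-type flux. A shared protein pool
adds `sum (MW_j / kcat_j) v_j <= P_pool`. Boolean regulation is
iterated to a steady state and coupled to the metabolic layer either
sequentially (rFBA) or as one joint MILP (srFBA).

Candidate designs are scored by production objectives, chiefly the
biomass-product coupled yield

    BPCY = v_biomass * v_product / |v_substrate|

and the weighted yield `WYIELD = alpha * v_max + (1 - alpha) * v_min`,
where `v_min, v_max` are the FVA extremes of the product flux at the
mutant's predicted growth.

All linear programs run on an internal two-phase simplex with Bland's
anti-cycling rule; mixed-integer programs (ROOM, srFBA) use a
deterministic branch-and-bound over that LP; quadratic MOMA uses
`quadprog`.

## Worked example

The four-step workflow — load a model, choose objectives, instantiate
the problem, run — on the bundled toy network (substrate A splits into
biomass precursors B and C; a product branch competes for B):

```r
library(strainopt)

model <- toy_model()                                   # (i)   load
f1 <- objective_spec("BPCY", biomass_id = "R_biomass", # (ii)  objectives
                     product_id = "EX_P", substrate_id = "R_up",
                     method = "lMOMA")
f2 <- objective_spec("WYIELD", biomass_id = "R_biomass",
                     product_id = "EX_P", alpha = 0.5)
problem <- cso_problem(model, list(f1, f2),            # (iii) problem
                       target_space = "genes", strategy = "OU",
                       level_grid = c(0, 0.5, 2), max_modifications = 2)
archive <- run_ea(problem, ea_config("NSGAII",         # (iv)  run
                                     population_size = 20,
                                     generations = 15, seed = 42))
archive_to_dataframe(archive, problem)
```

which prints

```
  modifications      BPCY WYIELD feasible
1        g2:0.5 0.8333333    2.5     TRUE
5   g2:0.5;g3:2 0.8333333    2.5     TRUE
4     g1:2;g2:0 0.0000000   10.0     TRUE
3   g1:2;g2:0.5 0.0000000   10.0     TRUE
2     g1:2;g3:0 0.0000000   10.0     TRUE
6     g1:2;g3:2 0.0000000   10.0     TRUE
```

Each row is one nondominated design. `g2:0.5` halves the expression of
the gene feeding the competing biomass precursor: growth drops to 2.5
and the freed substrate lets up to 5 flux units reach the product
(WYIELD 2.5 at alpha 0.5), giving the best growth-coupled yield
(BPCY 2.5 × 2.5 / 10 ≈ 0.83). The `g1:2` designs instead force the
product branch at the cost of all growth — the opposite end of the
trade-off front.

The same run is available from a shell:

```sh
Rscript inst/cli/strainopt.R optimize --config run.yaml
Rscript inst/cli/strainopt.R simulate --config run.yaml
Rscript inst/cli/strainopt.R enumerate --config run.yaml   # brute force
Rscript inst/cli/strainopt.R export-fixture --out fixtures
```

with the YAML schema documented in `?read_run_config`.

## GPR grammar

```
expr   := term { ("or" | "|") term }
term   := factor { ("and" | "&") factor }
factor := GENE | "(" expr ")"
```

Operators are case-insensitive; `and` binds tighter than `or`.
Regulatory rule files additionally support `not` and the constants
`true`/`false`, one `target = expression` rule per line, with
environment signals prefixed `env_`.

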