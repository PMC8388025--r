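# Minimal gene over-/under-expression (GOU) strain-design workflow:
# (i) load a model, (ii) choose the optimization objectives,
# (iii) instantiate the problem, (iv) run the optimization.
library(strainopt)

# (i) load a model -- here the bundled toy network; any SBML L3+FBC or
# JSON-dialect model path works the same way via load_model()
model <- toy_model()

# (ii) objectives: biomass-product coupled yield evaluated under lMOMA,
# and the weighted min/max product flux at predicted growth
f1 <- objective_spec("BPCY", biomass_id = "R_biomass", product_id = "EX_P",
                     substrate_id = "R_up", method = "lMOMA")
f2 <- objective_spec("WYIELD", biomass_id = "R_biomass", product_id = "EX_P",
                     alpha = 0.5)

# (iii) the problem: tune gene expression (deletion, 2-fold down, 2-fold
# up) with at most two simultaneous modifications
problem <- cso_problem(model, list(f1, f2),
                       target_space = "genes", strategy = "OU",
                       level_grid = c(0, 0.5, 2), max_modifications = 2)

# (iv) run the optimization (multi-objective NSGA-II)
archive <- run_ea(problem, ea_config("NSGAII", population_size = 20,
                                     generations = 15, seed = 42))

solutions <- archive_to_dataframe(archive, problem)
print(solutions)
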