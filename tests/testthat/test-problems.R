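# Problem definition, candidate decoding and objective functions.

toy <- toy_model()
bpcy_obj <- objective_spec("BPCY", product_id = "EX_P",
                           substrate_id = "R_up", method = "pFBA")
wy_obj <- objective_spec("WYIELD", product_id = "EX_P", alpha = 0.5)

gko <- function(max_mod = 2)
  cso_problem(toy, list(bpcy_obj, wy_obj), target_space = "genes",
              strategy = "KO", max_modifications = max_mod)

test_that("the wild-type reference is the cached pFBA distribution", {
  pr <- gko()
  w <- wild_type_reference(pr)
  expect_equal(w, c(R_up = 10, R1 = 5, R2 = 5, R3 = 0, R_biomass = 5,
                    EX_P = 0), tolerance = 1e-6)
  expect_identical(wild_type_reference(pr), w)  # cached object
  # a substrate-closed environment is rejected up front
  bad <- cso_problem(toy, list(bpcy_obj), target_space = "genes",
                     env = environmental_conditions(list(R_up = c(0, 0))))
  expect_error(wild_type_reference(bad), "zero growth|not solvable")
})

test_that("problem construction validates spaces, levels and objectives", {
  expect_error(cso_problem(toy, list(), target_space = "genes"), "length")
  expect_error(cso_problem(toy, list(bpcy_obj), targets = "gX"), "gX")
  expect_error(cso_problem(toy, list(objective_spec("BPCY",
                                                    product_id = "EX_X"))),
               "EX_X")
  expect_error(cso_problem(toy, list(bpcy_obj),
                           target_space = "regulatory"), "network")
  # KO problems pin the level grid at 0
  expect_identical(gko()$level_grid, 0)
  # default non-targets: exchanges, biomass, GPR-less genes excluded
  pr <- cso_problem(toy, list(bpcy_obj), target_space = "reactions")
  expect_false(any(c("R_up", "EX_P", "R_biomass") %in% pr$targets))
})

test_that("candidates validate and decode deterministically", {
  pr <- gko()
  expect_error(validate <- evaluate_candidate(pr, candidate(c("g1", "g2", "g3"))),
               NA) # size 3 > max 2 -> infeasible sentinel, not an error
  expect_false(validate$feasible)
  d1 <- decode_candidate(pr, candidate("g1"))
  expect_equal(d1, list(R1 = c(0, 0)))
  d2 <- decode_candidate(pr, candidate("g1"))
  expect_identical(d1, d2)
  # g3 deletion alone disables nothing (isozyme g1 and g4 remains)
  expect_length(decode_candidate(pr, candidate("g3")), 0)
})

test_that("gene-level OU decoding routes through the GPR algebra", {
  pr <- cso_problem(toy, list(bpcy_obj, wy_obj), target_space = "genes",
                    strategy = "OU", level_grid = c(0, 0.5, 2),
                    max_modifications = 2)
  d <- decode_candidate(pr, candidate("g2", 0.5))
  expect_equal(d, list(R2 = c(0, 2.5)))
  # over-expression of g1 pushes R1's lower bound to fold * w
  d2 <- decode_candidate(pr, candidate("g1", 2))
  expect_equal(d2, list(R1 = c(10, 10)))
  # deleting both isozyme branches disables R3
  prk <- gko()
  d3 <- decode_candidate(prk, candidate(c("g3", "g4")))
  expect_equal(d3, list(R3 = c(0, 0)))
})

test_that("regulatory decoding merges steady state with direct levels", {
  net <- toy_regulatory()
  pr <- cso_problem(toy, list(bpcy_obj), target_space = "regulatory",
                    strategy = "KO", network = net,
                    signals = c(env_s1 = TRUE), max_modifications = 2)
  # no TF touched: signal on -> g2 off -> R2 disabled
  d <- decode_candidate(pr, candidate("g2"))
  expect_equal(d$R2, c(0, 0))
  # deleting the TF restores g2: nothing disabled
  d2 <- decode_candidate(pr, candidate("t1"))
  expect_length(d2, 0)
})

test_that("BPCY follows its formula including edge cases", {
  r <- list(status = "optimal",
            fluxes = c(R_biomass = 2.5, EX_P = 5, R_up = -10))
  expect_equal(bpcy(r, "R_biomass", "EX_P", "R_up"), 1.25)
  expect_equal(bpcy(r, "R_biomass", "EX_P"), 12.5)
  r0 <- list(status = "optimal",
             fluxes = c(R_biomass = 2.5, EX_P = 0, R_up = -10))
  expect_equal(bpcy(r0, "R_biomass", "EX_P", "R_up"), 0)
  rneg <- list(status = "optimal",
               fluxes = c(R_biomass = 0, EX_P = 5, R_up = -10))
  expect_equal(bpcy(rneg, "R_biomass", "EX_P", "R_up"), 0)
  rz <- list(status = "optimal",
             fluxes = c(R_biomass = 2.5, EX_P = 5, R_up = 0))
  expect_equal(bpcy(rz, "R_biomass", "EX_P", "R_up"), 0)
})

test_that("WYIELD combines the product FVA extremes at fixed growth", {
  v <- apply_conditions(toy, extra = list(R2 = c(0, 2.5)))
  expect_equal(wyield(v, "R_biomass", "EX_P", 0.5), 2.5, tolerance = 1e-6)
  expect_equal(wyield(v, "R_biomass", "EX_P", 0), 0, tolerance = 1e-6)
  expect_equal(wyield(v, "R_biomass", "EX_P", 1), 5, tolerance = 1e-6)
  # wild type: product range degenerate at the optimum
  expect_equal(wyield(apply_conditions(toy), "R_biomass", "EX_P", 0.5), 0,
               tolerance = 1e-6)
  # infeasible mutant: sentinel 0
  dead <- apply_conditions(toy)
  dead$bounds["R_biomass", ] <- c(5, 2)
  expect_equal(wyield(dead, "R_biomass", "EX_P", 0.5), 0)
})

test_that("evaluation assembles fitness with documented semantics", {
  pr <- cso_problem(toy, list(bpcy_obj, wy_obj), target_space = "genes",
                    strategy = "OU", level_grid = c(0, 0.5, 2),
                    max_modifications = 2)
  f <- evaluate_candidate(pr, candidate("g2", 0.5))
  expect_true(f$feasible)
  expect_equal(f$values[1], 0, tolerance = 1e-6)   # pFBA kills product
  expect_equal(f$values[2], 2.5, tolerance = 1e-6)
  # deleting the biomass-essential g1: feasible with zero growth
  f2 <- evaluate_candidate(pr, candidate("g1", 0))
  expect_true(f2$feasible)
  expect_equal(f2$values[1], 0, tolerance = 1e-6)
  # repeated evaluation hits the cache and agrees
  expect_equal(evaluate_candidate(pr, candidate("g2", 0.5))$values,
               f$values)
})

test_that("redundant KO targets do not change fitness", {
  pr <- gko()
  base <- evaluate_candidate(pr, candidate("g1"))
  padded <- evaluate_candidate(pr, candidate(c("g1", "g3")))  # g3 inert
  expect_equal(padded$values, base$values, tolerance = 1e-9)
})

test_that("gene knockouts equal the reaction knockouts they induce", {
  prg <- gko()
  prr <- cso_problem(toy, list(bpcy_obj, wy_obj),
                     target_space = "reactions", strategy = "KO",
                     max_modifications = 2)
  fg <- evaluate_candidate(prg, candidate("g2"))       # disables R2
  fr <- evaluate_candidate(prr, candidate("R2"))
  expect_equal(fg$values, fr$values, tolerance = 1e-9)
})

test_that("exhaustive enumeration covers the candidate space", {
  pr <- gko()
  tab <- enumerate_candidates(pr)
  expect_equal(nrow(tab), 4 + 6)      # singles + unordered pairs
  expect_true(all(tab$feasible))
  expect_true(all(tab$BPCY >= 0 & tab$WYIELD >= 0))
  expect_error(enumerate_candidates(pr, limit = 3), "limit")
})
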