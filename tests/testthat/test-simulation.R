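# Phenotype simulators against hand-derived values and the independent
# LP oracle (pracma::linprog reformulation + vertex enumeration).

toy <- toy_model()

test_that("FBA reproduces the documented toy optima and statuses", {
  expect_equal(fba(toy)$objective, 5.0, tolerance = 1e-9)
  closed <- apply_conditions(toy, extra = list(R_up = c(0, 0)))
  expect_equal(fba(closed)$objective, 0.0, tolerance = 1e-9)
  bad <- apply_conditions(toy)
  bad$bounds["R1", ] <- c(5, 2)       # conflicting bounds injected
  expect_identical(fba(bad)$status, "infeasible")
  expect_error(fba(toy, "nope"), "nope")
})

test_that("FBA matches vertex enumeration and a second LP formulation", {
  expect_equal(fba(toy)$objective, oracle_vertex_fba(toy),
               tolerance = 1e-6)
  scenarios <- list(NULL, list(R2 = c(0, 2.5)), list(R1 = c(0, 0)),
                    list(R_up = c(0, 5)))
  for (sc in scenarios) {
    mine <- fba(apply_conditions(toy, extra = sc))$objective
    expect_equal(mine, oracle_fba(toy, extra_bounds = sc)$objective,
                 tolerance = 1e-6)
    expect_equal(mine, oracle_vertex_fba(toy, extra_bounds = sc),
                 tolerance = 1e-6)
  }
})

test_that("pFBA fixes the optimum and minimizes total absolute flux", {
  r <- pfba(toy)
  expect_equal(r$objective, 5.0, tolerance = 1e-9)
  expect_equal(unname(r$fluxes[c("R1", "R2", "EX_P")]), c(5, 5, 0),
               tolerance = 1e-6)
  capped <- apply_conditions(toy, extra = list(R2 = c(0, 2.5)))
  rc <- pfba(capped)
  expect_equal(rc$objective, 2.5, tolerance = 1e-9)
  expect_equal(unname(rc$fluxes["EX_P"]), 0, tolerance = 1e-6)
  orc <- oracle_pfba_total_flux(toy, extra_bounds = list(R2 = c(0, 2.5)))
  expect_equal(rc$total_flux, orc$total_flux, tolerance = 1e-6)
  # total |v| never exceeds the plain FBA solution's
  f <- fba(capped)
  expect_lte(rc$total_flux, sum(abs(f$fluxes)) + 1e-6)
  # single chain: pFBA fluxes equal FBA fluxes (unique optimum)
  chain <- metabolic_model(c("A"), list(
    R_in = list(stoichiometry = c(A = 1), lb = 0, ub = 4),
    R_out = list(stoichiometry = c(A = -1), lb = 0, ub = 10)),
    objective = "R_out")
  expect_equal(pfba(chain)$fluxes, fba(chain)$fluxes, tolerance = 1e-6)
  # fraction 0: growth unconstrained, all-zero flux is minimal
  expect_equal(pfba(toy, fraction = 0)$total_flux, 0, tolerance = 1e-6)
})

test_that("FVA ranges bracket the optimum and match the oracle", {
  r <- fva(toy, "EX_P", 1.0)
  expect_equal(c(r$min, r$max), c(0, 0), tolerance = 1e-6)
  capped <- apply_conditions(toy, extra = list(R2 = c(0, 2.5)))
  r2 <- fva(capped, "EX_P", 1.0)
  expect_equal(c(r2$min, r2$max),
               oracle_fva_range(toy, "EX_P",
                                extra_bounds = list(R2 = c(0, 2.5))),
               tolerance = 1e-6)
  # fraction 0 gives the widest feasible range
  r3 <- fva(toy, "R3", 0)
  expect_equal(c(r3$min, r3$max), c(0, 10), tolerance = 1e-6)
  all_r <- fva(toy, objective_fraction = 1.0)
  expect_true(all(all_r$min <= all_r$max + 1e-9))
  # the FBA-optimal flux lies within every range at fraction 1
  v <- fba(toy)$fluxes
  expect_true(all(v[all_r$reaction_id] >= all_r$min - 1e-6 &
                  v[all_r$reaction_id] <= all_r$max + 1e-6))
})

test_that("lMOMA minimizes absolute deviation from the reference", {
  wt <- pfba(toy)$fluxes
  same <- lmoma(toy, wt)
  expect_equal(same$deviation, 0, tolerance = 1e-6)
  expect_equal(same$fluxes, wt, tolerance = 1e-6)
  ko <- apply_conditions(toy, extra = list(R1 = c(0, 0)))
  r <- lmoma(ko, wt)
  expect_equal(r$objective, 0.0, tolerance = 1e-6)   # B unavailable
  expect_equal(r$deviation,
               oracle_lmoma_deviation(toy, wt, list(R1 = c(0, 0))),
               tolerance = 1e-6)
  # empty reference behaves as minimization of total |v|
  r0 <- lmoma(toy, NULL)
  expect_equal(r0$deviation, 0, tolerance = 1e-6)
})

test_that("ROOM counts significant flux changes and respects windows", {
  wt <- pfba(toy)$fluxes
  expect_equal(room(toy, wt)$changes, 0)
  ko <- apply_conditions(toy, extra = list(R1 = c(0, 0)))
  r <- room(ko, wt)
  expect_gte(r$changes, 1)
  # huge windows cover all bounds: no significant change for any mutant
  expect_equal(room(ko, wt, delta = 100, epsilon = 1000)$changes, 0)
  # y-count monotone non-increasing in delta and epsilon
  grid <- expand.grid(delta = c(0.03, 0.5, 2), epsilon = c(0.001, 1, 10))
  counts <- mapply(function(d, e) room(ko, wt, d, e)$changes,
                   grid$delta, grid$epsilon)
  for (d in unique(grid$delta)) {
    sub <- counts[grid$delta == d][order(grid$epsilon[grid$delta == d])]
    expect_true(all(diff(sub) <= 0))
  }
  for (e in unique(grid$epsilon)) {
    sub <- counts[grid$epsilon == e][order(grid$delta[grid$epsilon == e])]
    expect_true(all(diff(sub) <= 0))
  }
})

test_that("quadratic MOMA finds the closest feasible flux state", {
  wt <- pfba(toy)$fluxes
  expect_equal(moma(toy, wt)$deviation, 0, tolerance = 1e-6)
  ko <- apply_conditions(toy, extra = list(R1 = c(0, 0)))
  r <- moma(ko, wt)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, 0, tolerance = 1e-5)
  # squared deviation of MOMA <= squared deviation of the lMOMA solution
  lm <- lmoma(ko, wt)
  expect_lte(r$deviation,
             sum((lm$fluxes - wt[names(lm$fluxes)])^2) + 1e-6)
})

test_that("every returned flux vector is mass balanced", {
  wt <- pfba(toy)$fluxes
  views <- list(apply_conditions(toy),
                apply_conditions(toy, extra = list(R2 = c(0, 2.5))),
                apply_conditions(toy, extra = list(R1 = c(0, 0))))
  for (v in views) {
    for (r in list(fba(v), pfba(v), lmoma(v, wt), room(v, wt))) {
      expect_identical(r$status, "optimal")
      expect_flux_balanced(r, toy)
    }
  }
})

test_that("simulate_phenotype dispatches consistently", {
  expect_equal(simulate_phenotype(toy, "FBA")$objective,
               fba(toy)$objective)
  expect_error(simulate_phenotype(toy, "SPEA2"), "available")
  # lMOMA with no reference auto-computes the wild-type pFBA reference
  ko <- apply_conditions(toy, extra = list(R1 = c(0, 0)))
  auto <- simulate_phenotype(ko, "lMOMA")
  expect_equal(auto$objective, lmoma(ko, pfba(toy)$fluxes)$objective,
               tolerance = 1e-6)
})

test_that("simulators agree with the LP oracle on seeded random models", {
  for (seed in 1:8) {
    m <- random_model(1 + (seed %% 6) * 3, seed)
    mine <- fba(m)$objective
    orc <- oracle_fba(m)$objective
    expect_equal(mine, orc, tolerance = 1e-6, label = paste("seed", seed))
    # pFBA total flux against the split-variable oracle
    p <- pfba(m)
    po <- oracle_pfba_total_flux(m)
    expect_equal(p$total_flux, po$total_flux, tolerance = 1e-6)
    expect_flux_balanced(p, m)
  }
})

test_that("flux distributions round-trip through TSV", {
  wt <- pfba(toy)$fluxes
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(wt, tmp)
  expect_equal(read_flux_tsv(tmp), wt)
})
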