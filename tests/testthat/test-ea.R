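# Evolutionary engine: operators, dominance machinery, drivers.

toy <- toy_model()
lmoma_bpcy <- objective_spec("BPCY", product_id = "EX_P",
                             substrate_id = "R_up", method = "lMOMA")
wy <- objective_spec("WYIELD", product_id = "EX_P", alpha = 0.5)

two_obj_problem <- function()
  cso_problem(toy, list(lmoma_bpcy, wy), target_space = "genes",
              strategy = "OU", level_grid = c(0, 0.5, 2),
              max_modifications = 2)

test_that("mutation respects candidate size and level constraints", {
  pr <- two_obj_problem()
  set.seed(5)
  for (rep in 1:200) {
    sz <- sample(1:2, 1)
    c0 <- candidate(sample(pr$targets, sz),
                    c(0, 0.5, 2)[sample.int(3, sz, replace = TRUE)])
    c1 <- mutate_candidate(c0, pr)
    expect_gte(length(c1$targets), 1)
    expect_lte(length(c1$targets), pr$max_modifications)
    expect_true(all(c1$levels %in% pr$level_grid))
    expect_true(all(c1$targets %in% pr$targets))
    expect_false(anyDuplicated(c1$targets) > 0)
  }
  # at max size the add move is never selected
  full <- candidate(c("g1", "g2"), c(0, 0))
  set.seed(6)
  for (rep in 1:50)
    expect_lte(length(mutate_candidate(full, pr)$targets), 2)
  # KO single-target problems can still swap targets
  prk <- cso_problem(toy, list(wy), target_space = "genes",
                     strategy = "KO", max_modifications = 1)
  set.seed(7)
  kinds <- replicate(50, format(mutate_candidate(candidate("g1"), prk)))
  expect_true(any(kinds != "g1:0"))
})

test_that("crossover recombines parent sets within bounds", {
  pr <- two_obj_problem()
  a <- candidate(c("g1", "g2"), c(0, 0.5))
  set.seed(8)
  kids <- crossover_candidates(a, a, pr)
  expect_identical(format(kids[[1]]), format(a))
  expect_identical(format(kids[[2]]), format(a))
  b <- candidate(c("g3", "g4"), c(2, 0))
  for (rep in 1:50) {
    kids <- crossover_candidates(a, b, pr)
    for (k in kids) {
      expect_gte(length(k$targets), 1)
      expect_lte(length(k$targets), 2)
      expect_true(all(k$targets %in% c(a$targets, b$targets)))
    }
  }
  # deterministic under a fixed seed
  set.seed(9); k1 <- crossover_candidates(a, b, pr)
  set.seed(9); k2 <- crossover_candidates(a, b, pr)
  expect_identical(k1, k2)
})

test_that("Pareto dominance respects directions and feasibility", {
  fit <- function(v, feas = TRUE) list(values = v, feasible = feas)
  expect_true(dominates(fit(c(2, 2)), fit(c(1, 2)), c("max", "max")))
  expect_false(dominates(fit(c(2, 1)), fit(c(1, 2)), c("max", "max")))
  expect_false(dominates(fit(c(1, 2)), fit(c(2, 1)), c("max", "max")))
  expect_true(dominates(fit(c(1, 2)), fit(c(2, 2)), c("min", "max")))
  expect_true(dominates(fit(c(0, 0)), fit(c(-Inf, -Inf), FALSE),
                        c("max", "max")))
  expect_false(dominates(fit(c(9, 9), FALSE), fit(c(0, 0)),
                         c("max", "max")))
  expect_error(dominates(fit(c(1, 2)), fit(c(1, 2, 3)),
                         c("max", "max")), "mismatch")
})

test_that("nondominated sorting matches brute force and ranks fronts", {
  fit <- function(v) list(values = v, feasible = TRUE)
  pop <- lapply(list(c(1, 4), c(4, 1), c(2, 2), c(1, 1)), fit)
  sc <- nondominated_sort(pop, c("max", "max"))
  expect_identical(sc$rank, c(0L, 0L, 0L, 1L))
  # degenerate front: all identical
  same <- lapply(1:4, function(i) fit(c(1, 1)))
  sc2 <- nondominated_sort(same, c("max", "max"))
  expect_true(all(sc2$rank == 0L))
  expect_true(all(is.infinite(sc2$crowding) | sc2$crowding == 0))
  # single individual
  sc3 <- nondominated_sort(list(fit(c(1, 2))), c("max", "max"))
  expect_identical(sc3$rank, 0L)
  expect_true(is.infinite(sc3$crowding))
  # random populations against the O(n^2) classifier
  set.seed(10)
  for (rep in 1:25) {
    m <- sample(2:3, 1)
    dirs <- sample(c("max", "min"), m, replace = TRUE)
    popr <- lapply(1:30, function(i)
      fit(round(stats::runif(m, 0, 4))))
    expect_identical(nondominated_sort(popr, dirs)$rank,
                     brute_force_ranks(popr, dirs))
  }
})

test_that("NSGA-II recovers the exhaustively enumerated Pareto front", {
  pr <- two_obj_problem()
  tab <- enumerate_candidates(pr)
  fits <- lapply(seq_len(nrow(tab)), function(i)
    list(values = c(tab$BPCY[i], tab$WYIELD[i]), feasible = tab$feasible[i]))
  true_front <- sort(unique(vapply(
    which(brute_force_ranks(fits, c("max", "max")) == 0L),
    function(i) paste(round(fits[[i]]$values, 9), collapse = ","), "")))
  arch <- run_ea(pr, ea_config("NSGAII", population_size = 20,
                               generations = 20, seed = 3))
  got_front <- sort(unique(vapply(arch, function(ind)
    paste(round(ind$fitness$values, 9), collapse = ","), "")))
  expect_identical(got_front, true_front)
})

test_that("archive members stay mutually nondominated through the run", {
  pr <- two_obj_problem()
  dirs <- c("max", "max")
  violations <- 0L
  log_fn <- function(gen, pop, archive) {
    fits <- lapply(archive, `[[`, "fitness")
    for (i in seq_along(fits)) for (j in seq_along(fits))
      if (i != j && dominates(fits[[i]], fits[[j]], dirs))
        violations <<- violations + 1L
  }
  run_ea(pr, ea_config("NSGAII", population_size = 12, generations = 8,
                       seed = 4), log_fn = log_fn)
  expect_identical(violations, 0L)
})

test_that("GA and SA find the single-objective optimum of a small space", {
  pr1 <- cso_problem(toy, list(wy), target_space = "genes",
                     strategy = "OU", level_grid = c(0, 0.5, 2),
                     max_modifications = 2)
  tab <- enumerate_candidates(pr1)
  best <- max(tab$WYIELD)
  ga <- run_ea(pr1, ea_config("GA", population_size = 20,
                              generations = 15, seed = 5))
  expect_equal(max(vapply(ga, function(i) i$fitness$values[1], 0)), best,
               tolerance = 1e-6)
  sa <- run_ea(pr1, ea_config("SA", generations = 30, sa_steps = 10,
                              seed = 6))
  expect_equal(max(vapply(sa, function(i) i$fitness$values[1], 0)), best,
               tolerance = 1e-6)
})

test_that("SA at near-zero temperature never accepts a worse move", {
  pr1 <- cso_problem(toy, list(wy), target_space = "genes",
                     strategy = "OU", level_grid = c(0, 0.5, 2),
                     max_modifications = 2)
  trace <- numeric()
  # spy on acceptance through the per-generation log of current score
  log_fn <- function(gen, pop, archive) {
    trace <<- c(trace, pop[[1]]$fitness$values[1])
  }
  run_ea(pr1, ea_config("SA", generations = 20, sa_steps = 5,
                        sa_t0 = 1e-12, seed = 7), log_fn = log_fn)
  expect_true(all(diff(trace) >= -1e-12))
})

test_that("runs are bit-reproducible from the seed", {
  pr <- two_obj_problem()
  cfg <- ea_config("NSGAII", population_size = 10, generations = 5,
                   seed = 11)
  a1 <- run_ea(pr, cfg)
  a2 <- run_ea(pr, cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_archive_csv(a1, pr, f1)
  write_archive_csv(a2, pr, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero-generation budget returns the evaluated initial pool", {
  pr <- two_obj_problem()
  arch <- run_ea(pr, ea_config("NSGAII", population_size = 8,
                               generations = 0, seed = 12))
  expect_s3_class(arch, "solution_archive")
  expect_gte(length(arch), 1)
})
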