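# Set-based evolutionary optimization over candidates: variation
# operators, Pareto dominance machinery (fast non-dominated sorting and
# crowding distance), and the GA / SA / NSGA-II drivers with a shared
# nondominated solution archive. Every random draw flows from the
# config seed through one RNG stream owned by the run.

#' Evolutionary-algorithm configuration
#'
#' @param algorithm `"NSGAII"`, `"GA"` or `"SA"`
#' @param population_size population size (>= 4 for NSGA-II)
#' @param generations number of generations (SA: chain segments)
#' @param mutation_rates named numeric: probabilities of the `add`,
#'   `remove`, `change_target` and `change_level` moves (renormalized
#'   over the applicable ones)
#' @param crossover_rate probability of recombining a parent pair
#' @param seed integer RNG seed (mandatory for reproducible runs)
#' @param sa_t0,sa_cooling,sa_steps simulated-annealing schedule: initial
#'   temperature, geometric cooling factor, moves per temperature
#' @param archive_size nondominated-archive cap (crowding truncation)
#' @return an `ea_config`
#' @export
ea_config <- function(algorithm = c("NSGAII", "GA", "SA"),
                      population_size = 20, generations = 20,
                      mutation_rates = c(add = 0.3, remove = 0.3,
                                         change_target = 0.2,
                                         change_level = 0.2),
                      crossover_rate = 0.9, seed = 1,
                      sa_t0 = 1.0, sa_cooling = 0.9, sa_steps = 10,
                      archive_size = 100) {
  algorithm <- match.arg(algorithm)
  stopifnot(population_size >= 1, generations >= 0,
            all(mutation_rates >= 0), all(mutation_rates <= 1),
            crossover_rate >= 0, crossover_rate <= 1,
            sa_t0 > 0, sa_cooling > 0, sa_cooling < 1, sa_steps >= 1)
  if (algorithm == "NSGAII" && population_size < 4)
    stop("NSGA-II requires population_size >= 4")
  structure(list(algorithm = algorithm,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rates = mutation_rates,
                 crossover_rate = crossover_rate,
                 seed = as.integer(seed),
                 sa_t0 = sa_t0, sa_cooling = sa_cooling,
                 sa_steps = as.integer(sa_steps),
                 archive_size = as.integer(archive_size)),
            class = "ea_config")
}

# draw one (or k) elements safely, also for length-1 numeric vectors
sample_from <- function(x, k = 1, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

random_candidate <- function(problem) {
  sz <- sample.int(min(problem$max_modifications, length(problem$targets)), 1)
  tg <- sample_from(problem$targets, sz)
  lv <- sample_from(problem$level_grid, sz, replace = TRUE)
  candidate(tg, lv)
}

#' Mutate a candidate
#'
#' Applies exactly one of the applicable moves, drawn by the renormalized
#' rates: add a random `(target, level)` (if below max size), remove one
#' modification (if above size 1), swap a modification's target, or swap
#' its level (OU problems only). The result is always valid for the
#' problem; if no move applies the candidate is returned unchanged.
#'
#' @param cand a `candidate`
#' @param problem a `cso_problem`
#' @param rates see [ea_config()]
#' @return a `candidate`
#' @export
mutate_candidate <- function(cand, problem,
                             rates = c(add = 0.3, remove = 0.3,
                                       change_target = 0.2,
                                       change_level = 0.2)) {
  sz <- length(cand$targets)
  free <- setdiff(problem$targets, cand$targets)
  moves <- c(
    add = if (sz < problem$max_modifications && length(free)) rates[["add"]] else 0,
    remove = if (sz > 1) rates[["remove"]] else 0,
    change_target = if (length(free)) rates[["change_target"]] else 0,
    change_level = if (length(problem$level_grid) > 1) rates[["change_level"]] else 0)
  if (sum(moves) == 0) return(cand)
  move <- sample(names(moves), 1, prob = moves)
  tg <- cand$targets; lv <- cand$levels
  switch(move,
    add = {
      tg <- c(tg, sample_from(free))
      lv <- c(lv, sample_from(problem$level_grid))
    },
    remove = {
      k <- sample.int(sz, 1)
      tg <- tg[-k]; lv <- lv[-k]
    },
    change_target = {
      k <- sample.int(sz, 1)
      tg[k] <- sample_from(free)
    },
    change_level = {
      k <- sample.int(sz, 1)
      lv[k] <- sample_from(setdiff(problem$level_grid, lv[k]))
    })
  candidate(tg, lv)
}

#' Uniform set crossover of two candidates
#'
#' Each modification of the parents' union is assigned to child A or B
#' with probability 1/2 (duplicate targets keep one level at random);
#' children are truncated uniformly at random to the size cap and padded
#' back to size >= 1 from a parent modification.
#'
#' @param a,b parent `candidate`s
#' @param problem a `cso_problem`
#' @return list of two `candidate`s
#' @export
crossover_candidates <- function(a, b, problem) {
  shared <- intersect(a$targets, b$targets)
  la <- stats::setNames(a$levels, a$targets)
  lb <- stats::setNames(b$levels, b$targets)
  # shared targets go to both children, each child drawing its level from
  # either parent; parent-unique modifications are split uniformly
  child_t <- list(shared, shared)
  child_l <- lapply(1:2, function(i) vapply(shared, function(t)
    if (stats::runif(1) < 0.5) la[[t]] else lb[[t]], 0))
  uniq_t <- c(setdiff(a$targets, shared), setdiff(b$targets, shared))
  uniq_l <- c(la[setdiff(a$targets, shared)], lb[setdiff(b$targets, shared)])
  to_a <- stats::runif(length(uniq_t)) < 0.5
  child_t[[1]] <- c(child_t[[1]], uniq_t[to_a])
  child_l[[1]] <- c(child_l[[1]], uniq_l[to_a])
  child_t[[2]] <- c(child_t[[2]], uniq_t[!to_a])
  child_l[[2]] <- c(child_l[[2]], uniq_l[!to_a])
  pool_t <- c(a$targets, b$targets)
  pool_l <- c(a$levels, b$levels)
  fix <- function(tg, lv) {
    if (length(tg) > problem$max_modifications) {
      sel <- sample.int(length(tg), problem$max_modifications)
      tg <- tg[sel]; lv <- lv[sel]
    }
    if (!length(tg)) {
      k <- sample.int(length(pool_t), 1)
      tg <- pool_t[k]; lv <- pool_l[k]
    }
    candidate(tg, unname(lv))
  }
  list(fix(child_t[[1]], child_l[[1]]),
       fix(child_t[[2]], child_l[[2]]))
}

#' Pareto dominance between two fitness vectors
#'
#' Respects per-objective directions; a feasible fitness always dominates
#' an infeasible one, and two infeasibles are incomparable.
#'
#' @param f1,f2 `fitness` objects (or lists with `values` and `feasible`)
#' @param directions character vector of `"max"`/`"min"` per objective
#' @return logical: does f1 dominate f2?
#' @export
dominates <- function(f1, f2, directions) {
  if (length(f1$values) != length(f2$values) ||
      length(f1$values) != length(directions))
    stop("fitness/direction length mismatch")
  if (f1$feasible && !f2$feasible) return(TRUE)
  if (!f1$feasible) return(FALSE)
  d1 <- ifelse(directions == "max", f1$values, -f1$values)
  d2 <- ifelse(directions == "max", f2$values, -f2$values)
  all(d1 >= d2) && any(d1 > d2)
}

#' Fast non-dominated sorting with crowding distance
#'
#' Sorts an evaluated population into nondomination fronts (rank 0 =
#' nondominated) and assigns the crowding distance within each front,
#' with boundary individuals at +Inf. The resulting total order is
#' (rank ascending, crowding descending).
#'
#' @param fitnesses list of `fitness` objects
#' @param directions `"max"`/`"min"` per objective
#' @return list with integer `rank` and numeric `crowding`
#' @export
nondominated_sort <- function(fitnesses, directions) {
  n <- length(fitnesses)
  if (!n) return(list(rank = integer(), crowding = numeric()))
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (dominates(fitnesses[[i]], fitnesses[[j]], directions))
      dominated_by[[i]] <- c(dominated_by[[i]], j)
    else if (dominates(fitnesses[[j]], fitnesses[[i]], directions))
      dom_count[i] <- dom_count[i] + 1L
  }
  rank <- integer(n)
  front <- which(dom_count == 0L)
  r <- 0L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer()
    for (i in front) for (j in dominated_by[[i]]) {
      dom_count[j] <- dom_count[j] - 1L
      if (dom_count[j] == 0L) nxt <- c(nxt, j)
    }
    front <- sort(unique(nxt))
    r <- r + 1L
  }
  crowding <- numeric(n)
  m <- length(directions)
  vals <- do.call(rbind, lapply(fitnesses, function(f) {
    v <- f$values
    v[!is.finite(v)] <- sign(v[!is.finite(v)]) * 1e12
    v
  }))
  for (fr in unique(rank)) {
    idx <- which(rank == fr)
    if (length(idx) <= 2) { crowding[idx] <- Inf; next }
    cd <- numeric(length(idx))
    for (k in seq_len(m)) {
      o <- order(vals[idx, k])
      span <- vals[idx[o[length(o)]], k] - vals[idx[o[1]], k]
      cd[o[1]] <- Inf
      cd[o[length(o)]] <- Inf
      if (span > 0) {
        for (t in 2:(length(o) - 1)) {
          cd[o[t]] <- cd[o[t]] +
            (vals[idx[o[t + 1]], k] - vals[idx[o[t - 1]], k]) / span
        }
      }
    }
    crowding[idx] <- cd
  }
  list(rank = rank, crowding = crowding)
}

make_individual <- function(problem, cand) {
  list(candidate = cand, fitness = evaluate_candidate(problem, cand))
}

directions_of <- function(problem) {
  vapply(problem$objectives, `[[`, "", "direction")
}

archive_update <- function(archive, individuals, directions, cap) {
  pool <- c(archive, individuals)
  pool <- pool[vapply(pool, function(ind) ind$fitness$feasible, NA)]
  if (!length(pool)) return(list())
  keys <- vapply(pool, function(ind) {
    cs <- ind$fitness$constraints
    if (is.null(cs) || !length(cs)) return("")
    paste(names(cs), vapply(cs, paste, "", collapse = ","),
          sep = "=", collapse = ";")
  }, "")
  pool <- pool[!duplicated(keys)]
  fits <- lapply(pool, `[[`, "fitness")
  nd <- vapply(seq_along(pool), function(i)
    !any(vapply(seq_along(pool), function(j)
      i != j && dominates(fits[[j]], fits[[i]], directions), NA)), NA)
  pool <- pool[nd]
  if (length(pool) > cap) {
    sc <- nondominated_sort(lapply(pool, `[[`, "fitness"), directions)
    pool <- pool[order(-sc$crowding)][seq_len(cap)]
  }
  pool
}

scalar_fitness <- function(ind, problem, weights = NULL) {
  f <- ind$fitness
  dirs <- directions_of(problem)
  v <- ifelse(dirs == "max", f$values, -f$values)
  if (!f$feasible) return(-Inf)
  if (is.null(weights)) v[1] else sum(weights * v)
}

#' Run a strain-optimization search
#'
#' Drives the configured algorithm over the problem's candidate space:
#' * `GA` — generational single-objective GA (first objective, or a
#'   weighted sum via `weights`) with binary tournament selection and
#'   elitism of 1;
#' * `SA` — single-candidate simulated annealing with Metropolis
#'   acceptance `exp(delta / T)` and geometric cooling;
#' * `NSGAII` — (mu + lambda) multi-objective search with environmental
#'   selection by nondomination rank and crowding distance.
#'
#' All algorithms maintain a deduplicated nondominated archive across
#' generations and return it. The run is fully reproducible from the
#' config seed.
#'
#' @param problem a `cso_problem`
#' @param config an `ea_config`
#' @param weights optional objective weights for GA scalarization
#' @param log_fn optional callback `(generation, population, archive)`
#' @return a `solution_archive`: list of individuals (candidate +
#'   fitness), mutually nondominated
#' @export
run_ea <- function(problem, config, weights = NULL, log_fn = NULL) {
  set.seed(config$seed)
  dirs <- directions_of(problem)
  wild_type_reference(problem)   # fail fast on unsolvable wild type
  switch(config$algorithm,
         NSGAII = run_nsga2(problem, config, dirs, log_fn),
         GA = run_ga(problem, config, dirs, weights, log_fn),
         SA = run_sa(problem, config, dirs, weights, log_fn))
}

init_population <- function(problem, n) {
  lapply(seq_len(n), function(i) make_individual(problem,
                                                 random_candidate(problem)))
}

tournament <- function(pop, better) {
  i <- sample.int(length(pop), 1)
  j <- sample.int(length(pop), 1)
  if (better(i, j)) pop[[i]] else pop[[j]]
}

offspring_pair <- function(pop, problem, config, better) {
  pa <- tournament(pop, better)
  pb <- tournament(pop, better)
  kids <- if (stats::runif(1) < config$crossover_rate)
    crossover_candidates(pa$candidate, pb$candidate, problem)
  else list(pa$candidate, pb$candidate)
  lapply(kids, function(k)
    mutate_candidate(k, problem, config$mutation_rates))
}

run_nsga2 <- function(problem, config, dirs, log_fn) {
  n <- config$population_size
  pop <- init_population(problem, n)
  archive <- archive_update(list(), pop, dirs, config$archive_size)
  sc <- nondominated_sort(lapply(pop, `[[`, "fitness"), dirs)
  for (gen in seq_len(config$generations)) {
    better <- function(i, j) {
      sc$rank[i] < sc$rank[j] ||
        (sc$rank[i] == sc$rank[j] && sc$crowding[i] > sc$crowding[j])
    }
    kids <- list()
    while (length(kids) < n) {
      kids <- c(kids, offspring_pair(pop, problem, config, better))
    }
    kids <- kids[seq_len(n)]
    off <- lapply(kids, function(k) make_individual(problem, k))
    combined <- c(pop, off)
    scc <- nondominated_sort(lapply(combined, `[[`, "fitness"), dirs)
    o <- order(scc$rank, -scc$crowding)
    pop <- combined[o[seq_len(n)]]
    sc <- nondominated_sort(lapply(pop, `[[`, "fitness"), dirs)
    archive <- archive_update(archive, off, dirs, config$archive_size)
    if (!is.null(log_fn)) log_fn(gen, pop, archive)
  }
  structure(archive, class = "solution_archive")
}

run_ga <- function(problem, config, dirs, weights, log_fn) {
  n <- config$population_size
  pop <- init_population(problem, n)
  archive <- archive_update(list(), pop, dirs, config$archive_size)
  score <- vapply(pop, scalar_fitness, 0, problem = problem,
                  weights = weights)
  for (gen in seq_len(config$generations)) {
    better <- function(i, j) score[i] >= score[j]
    kids <- list()
    while (length(kids) < n - 1) {
      kids <- c(kids, offspring_pair(pop, problem, config, better))
    }
    kids <- kids[seq_len(n - 1)]
    off <- lapply(kids, function(k) make_individual(problem, k))
    elite <- pop[[which.max(score)]]
    pop <- c(list(elite), off)
    score <- vapply(pop, scalar_fitness, 0, problem = problem,
                    weights = weights)
    archive <- archive_update(archive, off, dirs, config$archive_size)
    if (!is.null(log_fn)) log_fn(gen, pop, archive)
  }
  structure(archive, class = "solution_archive")
}

run_sa <- function(problem, config, dirs, weights, log_fn) {
  cur <- make_individual(problem, random_candidate(problem))
  archive <- archive_update(list(), list(cur), dirs, config$archive_size)
  cur_score <- scalar_fitness(cur, problem, weights)
  temp <- config$sa_t0
  for (gen in seq_len(config$generations)) {
    for (s in seq_len(config$sa_steps)) {
      cand <- mutate_candidate(cur$candidate, problem,
                               config$mutation_rates)
      nxt <- make_individual(problem, cand)
      nxt_score <- scalar_fitness(nxt, problem, weights)
      delta <- nxt_score - cur_score
      accept <- if (delta >= 0) TRUE
      else if (!is.finite(delta)) FALSE
      else stats::runif(1) < exp(delta / temp)
      if (accept) {
        cur <- nxt
        cur_score <- nxt_score
      }
      archive <- archive_update(archive, list(nxt), dirs,
                                config$archive_size)
    }
    temp <- temp * config$sa_cooling
    if (!is.null(log_fn)) log_fn(gen, list(cur), archive)
  }
  structure(archive, class = "solution_archive")
}

#' @export
print.solution_archive <- function(x, ...) {
  cat("<solution_archive> ", length(x), " nondominated solution(s)\n",
      sep = "")
  invisible(x)
}

#' Convert a solution archive to a data.frame
#'
#' One row per solution: semicolon-joined `target:level` modifications,
#' one column per objective, and the feasibility flag. Rows are sorted by
#' the first objective (descending for maximization).
#'
#' @param archive a `solution_archive`
#' @param problem the `cso_problem` it was produced from
#' @return data.frame
#' @export
archive_to_dataframe <- function(archive, problem) {
  kinds <- make.unique(vapply(problem$objectives, `[[`, "", "kind"))
  if (!length(archive)) {
    cols <- c(list(modifications = character()),
              stats::setNames(rep(list(numeric()), length(kinds)), kinds),
              list(feasible = logical()))
    return(as.data.frame(cols, stringsAsFactors = FALSE))
  }
  rows <- lapply(archive, function(ind) {
    as.data.frame(c(list(modifications = format(ind$candidate)),
                    stats::setNames(as.list(ind$fitness$values), kinds),
                    list(feasible = ind$fitness$feasible)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dir1 <- problem$objectives[[1]]$direction
  out[order(out[[kinds[1]]], out$modifications,
            decreasing = c(dir1 == "max", FALSE), method = "radix"), ,
      drop = FALSE]
}

#' Write a solution archive as CSV
#' @param archive a `solution_archive`
#' @param problem its `cso_problem`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_archive_csv <- function(archive, problem, path) {
  utils::write.csv(archive_to_dataframe(archive, problem), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
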