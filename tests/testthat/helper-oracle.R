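# Independent brute-force oracles used to verify the simulators. These
# deliberately re-formulate every problem from scratch on top of
# pracma::linprog (a separate simplex implementation) and, for small
# models, exhaustive vertex enumeration of the flux polytope. They share
# no code with the package's solver layer.

oracle_lp <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                      lb, ub, maximize = TRUE) {
  # shift to x >= 0 for linprog robustness: v = x + lb
  n <- length(cc)
  shift <- lb
  A2 <- rbind(A, diag(n))
  b2 <- c(if (is.null(b)) numeric() else b - as.numeric(A %*% shift),
          ub - lb)
  beq2 <- if (is.null(beq)) NULL else beq - as.numeric(Aeq %*% shift)
  # linprog breaks pivot ties with sample(): pin its RNG so the oracle is
  # deterministic given its inputs, and on degenerate failures retry with
  # a permuted column order (changes tie-breaking, not the optimum)
  for (try_seed in 1:10) {
    perm <- if (try_seed == 1) seq_len(n)
            else withr::with_seed(7000 + try_seed, sample.int(n))
    r <- withr::with_seed(1000 + try_seed, suppressWarnings(
      pracma::linprog(cc = cc[perm], A = A2[, perm, drop = FALSE], b = b2,
                      Aeq = if (is.null(Aeq)) NULL
                            else Aeq[, perm, drop = FALSE],
                      beq = beq2, maximize = maximize, maxiter = 4000)))
    if (!is.null(r$x) && !any(is.na(r$x))) {
      x <- numeric(n)
      x[perm] <- r$x
      x <- x + shift
      return(list(objective = sum(cc * x), x = x))
    }
  }
  NULL
}

oracle_fba <- function(model, objective_id = NULL, maximize = TRUE,
                       extra_bounds = NULL) {
  model <- base_model(model)
  if (is.null(objective_id)) objective_id <- model$objective
  S <- stoichiometric_matrix(model)
  bnds <- effective_bounds(model)
  for (rid in names(extra_bounds)) bnds[rid, ] <- extra_bounds[[rid]]
  cc <- as.numeric(names(model$reactions) == objective_id)
  oracle_lp(cc, Aeq = S, beq = rep(0, nrow(S)),
            lb = bnds[, 1], ub = bnds[, 2], maximize = maximize)
}

# minimal total |v| at a fixed objective value, via explicit split
# variables formulated directly for linprog
oracle_pfba_total_flux <- function(model, objective_id = NULL,
                                   extra_bounds = NULL, fraction = 1.0) {
  model <- base_model(model)
  if (is.null(objective_id)) objective_id <- model$objective
  stage1 <- oracle_fba(model, objective_id, TRUE, extra_bounds)
  if (is.null(stage1)) return(NULL)
  S <- stoichiometric_matrix(model)
  bnds <- effective_bounds(model)
  for (rid in names(extra_bounds)) bnds[rid, ] <- extra_bounds[[rid]]
  # at fraction 1 the maximum forces equality, and the >= form is far
  # kinder to linprog's big-M phase than an explicit equality row
  # a hair of slack absorbs stage-1 rounding at the 1e-12 scale, far
  # below the 1e-6 comparison tolerance
  tgt <- fraction * stage1$objective
  bnds[objective_id, 1] <- tgt - 1e-9 * max(1, abs(tgt))
  n <- ncol(S)
  if (all(bnds[, 1] >= 0)) {
    # irreversible network: |v| = v, minimize the plain sum
    r <- oracle_lp(rep(1, n), Aeq = S, beq = rep(0, nrow(S)),
                   lb = bnds[, 1], ub = bnds[, 2], maximize = FALSE)
  } else {
    # split variables (p, q), v = p - q, p,q >= 0
    Aeq <- cbind(S, -S)
    beq <- rep(0, nrow(S))
    A <- rbind(cbind(diag(n), -diag(n)),     # v <= ub
               cbind(-diag(n), diag(n)))     # -v <= -lb
    b <- c(bnds[, 2], -bnds[, 1])
    r <- oracle_lp(rep(1, 2 * n), A = A, b = b, Aeq = Aeq, beq = beq,
                   lb = rep(0, 2 * n), ub = rep(2000, 2 * n),
                   maximize = FALSE)
  }
  if (is.null(r)) return(NULL)
  list(objective = stage1$objective, total_flux = r$objective)
}

oracle_fva_range <- function(model, reaction_id, objective_fraction = 1.0,
                             extra_bounds = NULL) {
  model <- base_model(model)
  opt <- oracle_fba(model, extra_bounds = extra_bounds)
  bnds2 <- extra_bounds
  bnds2[[model$objective]] <- c(
    objective_fraction * opt$objective,
    effective_bounds(model)[model$objective, 2])
  lo <- oracle_fba(model, reaction_id, FALSE, bnds2)
  hi <- oracle_fba(model, reaction_id, TRUE, bnds2)
  c(lo$objective, hi$objective)
}

# minimal sum |v - w| under mutant bounds, split-variable formulation
oracle_lmoma_deviation <- function(model, w, extra_bounds = NULL) {
  model <- base_model(model)
  S <- stoichiometric_matrix(model)
  bnds <- effective_bounds(model)
  for (rid in names(extra_bounds)) bnds[rid, ] <- extra_bounds[[rid]]
  n <- ncol(S)
  wv <- rep(0, n)
  wv[match(names(w), colnames(S))] <- as.numeric(w)
  # variables (v, d); constraints d >= v - w, d >= w - v
  Aeq <- cbind(S, matrix(0, nrow(S), n))
  beq <- rep(0, nrow(S))
  A <- rbind(cbind(diag(n), -diag(n)),    # v - d <= w
             cbind(-diag(n), -diag(n)))   # -v - d <= -w
  b <- c(wv, -wv)
  r <- oracle_lp(c(rep(0, n), rep(1, n)), A = A, b = b, Aeq = Aeq,
                 beq = beq,
                 lb = c(bnds[, 1], rep(0, n)),
                 ub = c(bnds[, 2], rep(4000, n)), maximize = FALSE)
  if (is.null(r)) return(NULL)
  r$objective
}

# exhaustive vertex enumeration of {v : S v = 0, lb <= v <= ub} for
# low-dimensional polytopes; returns the maximum of cc over all vertices
oracle_vertex_fba <- function(model, objective_id = NULL,
                              extra_bounds = NULL) {
  model <- base_model(model)
  if (is.null(objective_id)) objective_id <- model$objective
  S <- stoichiometric_matrix(model)
  bnds <- effective_bounds(model)
  for (rid in names(extra_bounds)) bnds[rid, ] <- extra_bounds[[rid]]
  n <- ncol(S)
  stopifnot(n <= 8)
  r <- qr(S)
  dof <- n - r$rank
  cc <- as.numeric(colnames(S) == objective_id)
  best <- -Inf
  Srows <- S[qr(t(S))$pivot[seq_len(qr(t(S))$rank)], , drop = FALSE]
  for (vars in utils::combn(n, dof, simplify = FALSE)) {
    sides <- expand.grid(rep(list(c(1, 2)), dof))
    for (si in seq_len(nrow(sides))) {
      fixvals <- vapply(seq_len(dof), function(k)
        bnds[vars[k], as.integer(sides[si, k])], 0)
      E <- matrix(0, dof, n)
      for (k in seq_len(dof)) E[k, vars[k]] <- 1
      M <- rbind(Srows, E)
      rhs <- c(rep(0, nrow(Srows)), fixvals)
      if (abs(det(M)) < 1e-10) next
      v <- solve(M, rhs)
      if (all(v >= bnds[, 1] - 1e-8) && all(v <= bnds[, 2] + 1e-8))
        best <- max(best, sum(cc * v))
    }
  }
  best
}

# brute-force Pareto classification used against nondominated_sort
brute_force_ranks <- function(fitnesses, directions) {
  n <- length(fitnesses)
  rank <- rep(NA_integer_, n)
  left <- seq_len(n)
  r <- 0L
  while (length(left)) {
    nd <- left[vapply(left, function(i)
      !any(vapply(left, function(j)
        i != j && dominates(fitnesses[[j]], fitnesses[[i]], directions),
        NA)), NA)]
    rank[nd] <- r
    left <- setdiff(left, nd)
    r <- r + 1L
  }
  rank
}

expect_flux_balanced <- function(result, model, tol = 1e-6) {
  S <- stoichiometric_matrix(model)
  v <- result$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), tol)
}
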