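# Phenotype-prediction methods over model views: FBA, pFBA, FVA, lMOMA,
# ROOM and quadratic MOMA, plus the generic simulate() dispatcher.

simulation_result <- function(status, objective = NA_real_, fluxes = NULL,
                              method = NA_character_, extra = list()) {
  structure(c(list(status = status, objective = objective,
                   fluxes = fluxes, method = method), extra),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$method, ": ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", format(x$objective, digits = 7), sep = "")
  cat("\n")
  invisible(x)
}

# Build the core FBA LP for a view: variables = fluxes, S v = 0, bounds,
# plus any attached pool constraints (rows over reaction fluxes).
build_fba_problem <- function(view, objective_id, maximize = TRUE) {
  model <- view$base
  rids <- names(model$reactions)
  S <- stoichiometric_matrix(model)
  A <- S
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  for (pc in view$pool_constraints) {
    row <- stats::setNames(rep(0, length(rids)), rids)
    row[names(pc$coef)] <- pc$coef
    A <- rbind(A, row)
    sense <- c(sense, pc$sense)
    rhs <- c(rhs, pc$rhs)
  }
  obj <- stats::setNames(rep(0, length(rids)), rids)
  if (!is.na(objective_id)) obj[objective_id] <- 1
  solver_problem(n = length(rids),
                 lb = view$bounds[, 1], ub = view$bounds[, 2],
                 obj = as.numeric(obj), maximize = maximize,
                 A = A, sense = sense, rhs = rhs)
}

flux_distribution <- function(values, rids) {
  stats::setNames(as.numeric(values), rids)
}

#' Flux balance analysis
#'
#' Solves `max (or min) c'v  s.t.  S v = 0, lb <= v <= ub` with `c`
#' selecting the objective reaction, and returns the optimum together with
#' one optimal flux distribution. Infeasible or conflicting-bound inputs
#' are reported through `status`, never as errors.
#'
#' @param model a `metabolic_model` or model view
#' @param objective_id reaction id to optimize; defaults to the model's
#'   objective (biomass)
#' @param maximize direction (default TRUE)
#' @return a `simulation_result`
#' @export
fba <- function(model, objective_id = NULL, maximize = TRUE) {
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  if (is.na(objective_id))
    stop("no objective: the model defines none and none was given")
  if (!objective_id %in% names(view$base$reactions))
    stop("unknown objective reaction '", objective_id, "'")
  if (any(view$bounds[, 1] > view$bounds[, 2] + FEAS_TOL))
    return(simulation_result("infeasible", method = "FBA"))
  p <- build_fba_problem(view, objective_id, maximize)
  r <- solve_lp(p)
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "FBA"))
  simulation_result("optimal", r$objective,
                    flux_distribution(r$x, names(view$base$reactions)),
                    "FBA")
}

# split-variable LP minimizing sum |v - w| (w = 0 gives pFBA stage 2)
# subject to S v = 0, view bounds, pool rows, and optional extra rows.
min_abs_deviation <- function(view, w, extra_rows = NULL) {
  model <- view$base
  rids <- names(model$reactions)
  n <- length(rids)
  S <- stoichiometric_matrix(model)
  # variables: v (n), dpos (n), dneg (n);  v - dpos + dneg = w
  A <- cbind(S, matrix(0, nrow(S), 2 * n))
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  dev <- cbind(diag(n), -diag(n), diag(n))
  A <- rbind(A, dev)
  sense <- c(sense, rep("=", n))
  rhs <- c(rhs, w)
  for (pc in view$pool_constraints) {
    row <- stats::setNames(rep(0, n), rids)
    row[names(pc$coef)] <- pc$coef
    A <- rbind(A, c(row, rep(0, 2 * n)))
    sense <- c(sense, pc$sense)
    rhs <- c(rhs, pc$rhs)
  }
  if (!is.null(extra_rows)) {
    A <- rbind(A, cbind(extra_rows$A, matrix(0, nrow(extra_rows$A), 2 * n)))
    sense <- c(sense, extra_rows$sense)
    rhs <- c(rhs, extra_rows$rhs)
  }
  big <- 2 * DEFAULT_BOUND + max(abs(w), 1)
  p <- solver_problem(n = 3L * n,
                      lb = c(view$bounds[, 1], rep(0, 2 * n)),
                      ub = c(view$bounds[, 2], rep(big, 2 * n)),
                      obj = c(rep(0, n), rep(1, 2 * n)),
                      maximize = FALSE, A = A, sense = sense, rhs = rhs)
  r <- solve_lp(p)
  if (r$status != "optimal") return(r)
  r$fluxes <- flux_distribution(r$x[seq_len(n)], rids)
  r$deviation <- r$objective
  r
}

#' Parsimonious FBA
#'
#' Two-stage procedure: (1) FBA gives the optimal objective value; (2) the
#' objective flux is fixed to `fraction` times that optimum and the total
#' absolute flux `sum |v_i|` is minimized through split variables. The
#' reported `objective` is the stage-1 optimum; `fluxes` come from stage 2.
#'
#' @inheritParams fba
#' @param fraction fraction of the FBA optimum enforced in stage 2
#'   (default 1.0)
#' @return a `simulation_result` with extra field `total_flux`
#' @export
pfba <- function(model, objective_id = NULL, fraction = 1.0) {
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  s1 <- fba(view, objective_id)
  if (s1$status != "optimal") return(simulation_result(s1$status, method = "pFBA"))
  target <- fraction * s1$objective
  view2 <- apply_conditions(view, extra = stats::setNames(
    list(c(target, target)), objective_id))
  r <- min_abs_deviation(view2, rep(0, length(view$base$reactions)))
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "pFBA"))
  simulation_result("optimal", s1$objective, r$fluxes, "pFBA",
                    extra = list(total_flux = r$deviation))
}

#' Flux variability analysis
#'
#' Constrains the objective flux to at least `objective_fraction` times
#' its FBA optimum, then minimizes and maximizes each requested reaction
#' flux (two LPs per reaction).
#'
#' @inheritParams fba
#' @param reaction_ids reactions to scan (default: all)
#' @param objective_fraction fraction of the optimum to retain, in \[0, 1\]
#' @return data.frame with columns `reaction_id`, `min`, `max`; reactions
#'   whose sub-LP fails carry `NA` and a `status` note
#' @export
fva <- function(model, reaction_ids = NULL, objective_fraction = 1.0,
                objective_id = NULL) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  if (is.null(reaction_ids)) reaction_ids <- names(view$base$reactions)
  s1 <- fba(view, objective_id)
  if (s1$status != "optimal")
    stop("FVA: baseline FBA not optimal (", s1$status, ")")
  lo <- objective_fraction * s1$objective
  view2 <- apply_conditions(view, extra = stats::setNames(
    list(c(lo, view$bounds[objective_id, 2])), objective_id))
  out <- data.frame(reaction_id = reaction_ids, min = NA_real_,
                    max = NA_real_, status = "optimal",
                    stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    rid <- reaction_ids[k]
    rmin <- fba(view2, rid, maximize = FALSE)
    rmax <- fba(view2, rid, maximize = TRUE)
    if (rmin$status == "optimal" && rmax$status == "optimal") {
      out$min[k] <- rmin$objective
      out$max[k] <- rmax$objective
    } else {
      out$status[k] <- paste0("min:", rmin$status, ";max:", rmax$status)
    }
  }
  out
}

complete_reference <- function(reference, rids) {
  w <- stats::setNames(rep(0, length(rids)), rids)
  if (!is.null(reference)) {
    keep <- intersect(names(reference), rids)
    w[keep] <- as.numeric(reference[keep])
  }
  w
}

#' Linear minimization of metabolic adjustment (lMOMA)
#'
#' Predicts the mutant flux state as the one minimizing the absolute
#' deviation `sum |v_i - w_i|` from a reference (wild-type) distribution,
#' subject to steady state and the mutant's bounds. Reactions missing from
#' the reference default to 0. The reported `objective` is the flux
#' through the model's biomass reaction in the solution.
#'
#' @inheritParams fba
#' @param reference named flux distribution (wild type); typically pFBA
#' @return a `simulation_result` with extra field `deviation`
#' @export
lmoma <- function(model, reference = NULL, objective_id = NULL) {
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  rids <- names(view$base$reactions)
  w <- complete_reference(reference, rids)
  r <- min_abs_deviation(view, w)
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "lMOMA"))
  obj <- if (is.na(objective_id)) NA_real_ else r$fluxes[[objective_id]]
  simulation_result("optimal", obj, r$fluxes, "lMOMA",
                    extra = list(deviation = r$deviation))
}

#' Quadratic minimization of metabolic adjustment (MOMA)
#'
#' Minimizes the squared Euclidean deviation `sum (v_i - w_i)^2` from the
#' reference via a strictly convex quadratic program.
#'
#' @inheritParams lmoma
#' @return a `simulation_result` with extra field `deviation` (the squared
#'   distance)
#' @export
moma <- function(model, reference = NULL, objective_id = NULL) {
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  rids <- names(view$base$reactions)
  n <- length(rids)
  w <- complete_reference(reference, rids)
  p <- build_fba_problem(view, objective_id %||% NA_character_)
  # min (v-w)'(v-w) = 0.5 v'(2I)v - (2w)'v + const
  r <- solve_qp(p, D = 2 * diag(n), d = 2 * w)
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "MOMA"))
  v <- flux_distribution(r$x, rids)
  obj <- if (is.na(objective_id)) NA_real_ else v[[objective_id]]
  simulation_result("optimal", obj, v, "MOMA",
                    extra = list(deviation = sum((r$x - w)^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regulatory on/off minimization (ROOM)
#'
#' MILP minimizing the number of reactions whose flux leaves a window
#' around the reference: for each reaction the window is
#' `[w_i - delta*|w_i| - epsilon, w_i + delta*|w_i| + epsilon]` and a
#' binary y_i is forced to 1 when v_i exits it. The reported `objective`
#' is the biomass flux of the solution; `changes` counts the y_i = 1.
#'
#' @inheritParams lmoma
#' @param delta relative window half-width (default 0.03)
#' @param epsilon absolute window half-width (default 0.001)
#' @return a `simulation_result` with extra field `changes`
#' @export
room <- function(model, reference = NULL, delta = 0.03, epsilon = 0.001,
                 objective_id = NULL) {
  stopifnot(delta >= 0, epsilon >= 0)
  view <- as_view(model)
  if (is.null(objective_id)) objective_id <- view$base$objective
  rids <- names(view$base$reactions)
  n <- length(rids)
  w <- complete_reference(reference, rids)
  wu <- w + delta * abs(w) + epsilon
  wl <- w - delta * abs(w) - epsilon
  lb <- view$bounds[, 1]; ub <- view$bounds[, 2]
  p0 <- build_fba_problem(view, NA_character_)
  # variables: v (n) then y (n, binary)
  A <- cbind(p0$A, matrix(0, nrow(p0$A), n))
  sense <- p0$sense; rhs <- p0$rhs
  for (i in seq_len(n)) {
    up <- rep(0, 2 * n); up[i] <- 1; up[n + i] <- -(ub[i] - wu[i])
    A <- rbind(A, up); sense <- c(sense, "<="); rhs <- c(rhs, wu[i])
    lo <- rep(0, 2 * n); lo[i] <- 1; lo[n + i] <- -(lb[i] - wl[i])
    A <- rbind(A, lo); sense <- c(sense, ">="); rhs <- c(rhs, wl[i])
  }
  p <- solver_problem(n = 2L * n,
                      lb = c(lb, rep(0, n)), ub = c(ub, rep(1, n)),
                      obj = c(rep(0, n), rep(1, n)), maximize = FALSE,
                      A = A, sense = sense, rhs = rhs,
                      binary = n + seq_len(n))
  r <- solve_milp(p)
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "ROOM"))
  v <- flux_distribution(r$x[seq_len(n)], rids)
  obj <- if (is.na(objective_id)) NA_real_ else v[[objective_id]]
  simulation_result("optimal", obj, v, "ROOM",
                    extra = list(changes = sum(round(r$x[n + seq_len(n)]))))
}

#' Run a phenotype simulation method by name
#'
#' Uniform dispatcher used by objective functions: `method` is one of
#' `"FBA"`, `"pFBA"`, `"lMOMA"`, `"MOMA"`, `"ROOM"` (case-insensitive).
#' Reference-based methods auto-compute a wild-type pFBA reference on the
#' unmodified view when none is supplied.
#'
#' @inheritParams fba
#' @param method simulation method name
#' @param reference reference flux distribution for lMOMA/MOMA/ROOM
#' @param fraction pFBA objective fraction
#' @param delta,epsilon ROOM window parameters
#' @return a `simulation_result`
#' @export
simulate_phenotype <- function(model, method = "FBA", objective_id = NULL,
                               reference = NULL, fraction = 1.0,
                               delta = 0.03, epsilon = 0.001,
                               maximize = TRUE) {
  m <- toupper(method)
  known <- c("FBA", "PFBA", "LMOMA", "MOMA", "ROOM")
  if (!m %in% known)
    stop("unknown simulation method '", method, "'; available: ",
         "FBA, pFBA, lMOMA, MOMA, ROOM")
  if (m %in% c("LMOMA", "MOMA", "ROOM") && is.null(reference)) {
    base <- as_view(base_model(model))
    wt <- pfba(base, objective_id)
    if (wt$status != "optimal")
      return(simulation_result(wt$status, method = method))
    reference <- wt$fluxes
  }
  switch(m,
         FBA = fba(model, objective_id, maximize),
         PFBA = pfba(model, objective_id, fraction),
         LMOMA = lmoma(model, reference, objective_id),
         MOMA = moma(model, reference, objective_id),
         ROOM = room(model, reference, delta, epsilon, objective_id))
}

#' Write a flux distribution as a two-column TSV
#' @param fluxes named numeric vector (reaction_id -> flux)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_flux_tsv <- function(fluxes, path) {
  utils::write.table(data.frame(reaction_id = names(fluxes),
                                flux = as.numeric(fluxes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux distribution from a two-column TSV
#' @param path input path
#' @return named numeric vector
#' @export
read_flux_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$flux, tab$reaction_id)
}
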