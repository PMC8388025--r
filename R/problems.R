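# Problem-definition layer: modification target spaces and strategies,
# candidate decoding into simulator constraints, objective functions
# (BPCY, WYIELD, target flux, growth, modification count) and fitness
# evaluation with caching.

#' Default over-/under-expression level grid
#'
#' Symmetric powers of two around the wild type (1): 0 encodes deletion,
#' values below 1 under-expression, above 1 over-expression.
#' @export
DEFAULT_LEVEL_GRID <- c(0, 1/32, 1/16, 1/8, 1/4, 1/2, 2, 4, 8, 16, 32)

#' Specify an optimization objective
#'
#' @param kind one of `"BPCY"`, `"WYIELD"`, `"target_flux"`, `"growth"`,
#'   `"modification_count"`
#' @param biomass_id biomass reaction id (defaults to model objective)
#' @param product_id product exchange/drain reaction id
#' @param substrate_id substrate uptake reaction (BPCY normalization,
#'   optional)
#' @param method phenotype simulation method for this objective (FBA,
#'   pFBA, lMOMA, MOMA, ROOM)
#' @param direction `"max"` or `"min"`
#' @param alpha WYIELD weight on the FVA maximum, in \[0, 1\]
#' @param objective_fraction WYIELD growth fraction retained during FVA
#' @return an `objective_spec`
#' @export
objective_spec <- function(kind = c("BPCY", "WYIELD", "target_flux",
                                    "growth", "modification_count"),
                           biomass_id = NULL, product_id = NULL,
                           substrate_id = NULL, method = "pFBA",
                           direction = c("max", "min"), alpha = 0.5,
                           objective_fraction = 1.0) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  stopifnot(alpha >= 0, alpha <= 1)
  if (kind %in% c("BPCY", "WYIELD") && is.null(product_id))
    stop(kind, " objective requires a product_id")
  structure(list(kind = kind, biomass_id = biomass_id,
                 product_id = product_id, substrate_id = substrate_id,
                 method = method, direction = direction, alpha = alpha,
                 objective_fraction = objective_fraction),
            class = "objective_spec")
}

#' Biomass-product coupled yield (BPCY)
#'
#' `(v_biomass * v_product) / |v_substrate|` when a substrate is given
#' (and its uptake is nonzero), `v_biomass * v_product` otherwise.
#' Returns 0 for non-growing strains (`v_biomass <= 0`) and for zero
#' substrate uptake when a substrate is specified.
#'
#' @param result an optimal `simulation_result`
#' @param biomass_id,product_id,substrate_id reaction ids
#' @return non-negative numeric
#' @export
bpcy <- function(result, biomass_id, product_id, substrate_id = NULL) {
  stopifnot(result$status == "optimal")
  v <- result$fluxes
  growth <- v[[biomass_id]]
  if (growth <= 0) return(0)
  num <- growth * v[[product_id]]
  if (is.null(substrate_id)) return(num)
  sub <- abs(v[[substrate_id]])
  if (sub < FEAS_TOL) return(0)
  num / sub
}

#' Weighted product yield (WYIELD)
#'
#' Fixes biomass to at least `objective_fraction` times the mutant's FBA
#' optimum, runs FVA on the product flux and returns
#' `alpha * v_max + (1 - alpha) * v_min`: a convex combination of the
#' optimistic and pessimistic production at the predicted growth.
#'
#' @param view model view already carrying the candidate's constraints
#' @param biomass_id,product_id reaction ids
#' @param alpha weight on the FVA maximum
#' @param objective_fraction growth fraction retained
#' @return numeric; 0 when the mutant is infeasible
#' @export
wyield <- function(view, biomass_id, product_id, alpha = 0.5,
                   objective_fraction = 1.0) {
  g <- fba(view, biomass_id)
  if (g$status != "optimal") return(0)
  rng <- tryCatch(
    fva(view, product_id, objective_fraction, objective_id = biomass_id),
    error = function(e) NULL)
  if (is.null(rng) || rng$status[1] != "optimal") return(0)
  alpha * rng$max[1] + (1 - alpha) * rng$min[1]
}

#' Define a strain-optimization problem
#'
#' Binds a model to a modification target space, a strategy, objective
#' functions and environmental conditions. Candidates are variable-length
#' sets of `(target, level)` modifications: level 0 is a deletion, levels
#' from `level_grid` scale expression for OU problems.
#'
#' @param model a `metabolic_model`
#' @param objectives list of [objective_spec()]s (1 to 4)
#' @param target_space `"reactions"`, `"genes"`, `"enzymes"` or
#'   `"regulatory"`
#' @param strategy `"KO"` (deletions; level grid pinned at 0) or `"OU"`
#'   (over/under-expression over `level_grid`)
#' @param max_modifications maximum candidate size (>= 1)
#' @param level_grid allowed expression levels for OU problems
#' @param env an `environmental_conditions` object
#' @param targets explicit target id list; defaults to the full space
#' @param non_targets excluded ids; defaults to exchange reactions, the
#'   biomass reaction, and genes absent from every GPR
#' @param network a `regulatory_network` (required for `"regulatory"`)
#' @param enzymes an `enzyme_params` (required for `"enzymes"`)
#' @param signals environment signal values for regulatory problems
#' @return a `cso_problem`
#' @export
cso_problem <- function(model, objectives,
                        target_space = c("genes", "reactions", "enzymes",
                                         "regulatory"),
                        strategy = c("KO", "OU"),
                        max_modifications = 2,
                        level_grid = DEFAULT_LEVEL_GRID,
                        env = NULL, targets = NULL, non_targets = NULL,
                        network = NULL, enzymes = NULL,
                        signals = logical()) {
  target_space <- match.arg(target_space)
  strategy <- match.arg(strategy)
  stopifnot(max_modifications >= 1)
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  stopifnot(length(objectives) >= 1, length(objectives) <= 4)
  model <- base_model(model)
  if (target_space == "regulatory" && is.null(network))
    stop("regulatory problems require a network")
  if (target_space == "enzymes" && is.null(enzymes))
    stop("enzyme problems require enzyme parameters")
  if (strategy == "KO") level_grid <- 0
  level_grid <- sort(unique(level_grid))

  for (ob in objectives) {
    for (id in c(ob$biomass_id, ob$product_id, ob$substrate_id))
      if (!is.null(id) && !id %in% names(model$reactions))
        stop("objective references unknown reaction '", id, "'")
  }

  exchange <- names(model$reactions)[vapply(model$reactions, function(r)
    length(r$stoichiometry) <= 1, NA)]
  gpr_present <- unique(unlist(lapply(model$reactions, function(r)
    if (is.null(r$gpr)) character() else gpr_genes(r$gpr))))

  space_ids <- switch(target_space,
    reactions = setdiff(names(model$reactions),
                        c(exchange, model$objective)),
    genes = intersect(model$genes, gpr_present),
    enzymes = enzymes$table$reaction_id,
    regulatory = unique(c(network$regulators,
                          intersect(network$targets, model$genes))))
  if (!is.null(targets)) {
    bad <- setdiff(targets, switch(target_space,
      reactions = names(model$reactions),
      genes = model$genes,
      enzymes = enzymes$table$reaction_id,
      regulatory = c(network$regulators, network$targets)))
    if (length(bad))
      stop("unknown target id(s): ", paste(bad, collapse = ", "))
    space_ids <- targets
  }
  if (!is.null(non_targets)) space_ids <- setdiff(space_ids, non_targets)
  if (!length(space_ids)) stop("empty target space")

  structure(list(model = model, objectives = objectives,
                 target_space = target_space, strategy = strategy,
                 max_modifications = max_modifications,
                 level_grid = level_grid, env = env,
                 targets = space_ids, network = network,
                 enzymes = enzymes, signals = signals,
                 cache = new.env(parent = emptyenv()),
                 cache_max = 10000L),
            class = "cso_problem")
}

#' @export
print.cso_problem <- function(x, ...) {
  cat("<cso_problem> ", x$strategy, " over ", x$target_space, " (",
      length(x$targets), " targets, max ", x$max_modifications,
      " modifications, ", length(x$objectives), " objective(s))\n",
      sep = "")
  invisible(x)
}

#' Construct a candidate solution
#'
#' @param targets character vector of modification targets
#' @param levels numeric expression levels aligned with `targets`
#'   (0 = deletion); defaults to all-0
#' @return a `candidate`: the pairs sorted by target id for determinism
#' @export
candidate <- function(targets, levels = rep(0, length(targets))) {
  stopifnot(length(targets) == length(levels), !anyDuplicated(targets))
  o <- order(targets)
  structure(list(targets = as.character(targets)[o],
                 levels = as.numeric(levels)[o]),
            class = "candidate")
}

candidate_key <- function(cand) {
  paste(cand$targets, cand$levels, sep = ":", collapse = ";")
}

#' @export
format.candidate <- function(x, ...) {
  if (!length(x$targets)) return("<wild type>")
  paste(paste0(x$targets, ":", x$levels), collapse = ";")
}

#' @export
print.candidate <- function(x, ...) {
  cat("<candidate> ", format(x), "\n", sep = "")
  invisible(x)
}

validate_candidate <- function(problem, cand) {
  if (length(cand$targets) < 1 ||
      length(cand$targets) > problem$max_modifications)
    stop("candidate size out of range")
  bad <- setdiff(cand$targets, problem$targets)
  if (length(bad)) stop("candidate targets outside the problem space: ",
                        paste(bad, collapse = ", "))
  if (any(!cand$levels %in% problem$level_grid))
    stop("candidate level outside the level grid")
  invisible(TRUE)
}

problem_view <- function(problem, with_pool = FALSE) {
  view <- apply_conditions(problem$model, env = problem$env)
  if (with_pool && !is.null(problem$enzymes))
    view <- attach_protein_pool(view, problem$enzymes)
  view
}

#' Wild-type reference flux distribution of a problem
#'
#' The pFBA distribution of the unmodified model under the problem's
#' environmental conditions. Used as the reference for over-/under-
#' expression decoding and for lMOMA/MOMA/ROOM. Computed once and cached.
#'
#' @param problem a `cso_problem`
#' @return named flux vector
#' @export
wild_type_reference <- function(problem) {
  if (!is.null(problem$cache$wt_reference))
    return(problem$cache$wt_reference)
  wt <- pfba(problem_view(problem, with_pool = TRUE))
  if (wt$status != "optimal")
    stop("wild type is not solvable under the problem conditions (",
         wt$status, ")")
  if (wt$objective <= FEAS_TOL)
    stop("wild type has zero growth under the problem conditions")
  problem$cache$wt_reference <- wt$fluxes
  wt$fluxes
}

#' Decode a candidate into reaction bound constraints
#'
#' Translates a candidate's `(target, level)` modifications into the
#' bound overrides the simulators consume:
#' * reactions: the level acts directly through
#'   [reaction_fold_to_bounds()] against the wild-type reference flux;
#' * genes: KO deletions go through Boolean GPR evaluation, OU levels
#'   through algebraic (min/max) GPR evaluation, then per-reaction folds
#'   become bounds;
#' * enzymes: per-reaction usage caps via [enzyme_modification_bounds()];
#' * regulatory: modified regulators are frozen in the network (level 0 ->
#'   pinned FALSE, level > 1 -> pinned TRUE), the Boolean steady state is
#'   computed, its OFF metabolic genes are merged with any direct gene
#'   modifications, and decoding proceeds as for genes.
#'
#' @param problem a `cso_problem`
#' @param cand a `candidate`
#' @return named list of `c(lb, ub)` overrides (possibly empty)
#' @export
decode_candidate <- function(problem, cand) {
  validate_candidate(problem, cand)
  w <- wild_type_reference(problem)
  bounds <- effective_bounds(problem_view(problem))
  model <- problem$model

  gene_fold_bounds <- function(levels) {
    out <- list()
    touched <- names(levels)[levels != 1]
    for (rid in names(model$reactions)) {
      g <- model$reactions[[rid]]$gpr
      if (is.null(g) || !length(intersect(gpr_genes(g), touched))) next
      fold <- eval_algebraic(g, levels)
      if (fold == 1) next
      out[[rid]] <- reaction_fold_to_bounds(fold, w[[rid]],
                                            bounds[rid, 1], bounds[rid, 2])
    }
    out
  }

  switch(problem$target_space,
    reactions = {
      out <- list()
      for (k in seq_along(cand$targets)) {
        rid <- cand$targets[k]
        nb <- reaction_fold_to_bounds(cand$levels[k], w[[rid]],
                                      bounds[rid, 1], bounds[rid, 2])
        if (!identical(nb, unname(bounds[rid, ]))) out[[rid]] <- nb
      }
      out
    },
    genes = {
      levels <- stats::setNames(cand$levels, cand$targets)
      gene_fold_bounds(levels)
    },
    enzymes = {
      out <- list()
      for (k in seq_along(cand$targets)) {
        rid <- cand$targets[k]
        nb <- enzyme_modification_bounds(rid, cand$levels[k],
                                         problem$enzymes, w[[rid]],
                                         bounds[rid, 1], bounds[rid, 2])
        if (!is.null(nb)) out[[rid]] <- nb
      }
      out
    },
    regulatory = {
      net <- problem$network
      reg_idx <- cand$targets %in% net$regulators &
        !cand$targets %in% model$genes
      frozen <- cand$targets[reg_idx]
      frozen_vals <- cand$levels[reg_idx] > 1
      init <- problem$signals
      for (k in seq_along(frozen)) init[frozen[k]] <- frozen_vals[k]
      ss <- regulatory_steady_state(net, regulatory_state(net, init),
                                    frozen = frozen)
      off <- off_metabolic_genes(net, ss$state, model)
      levels <- stats::setNames(rep(0, length(off)), off)
      for (k in which(!reg_idx)) {
        levels[cand$targets[k]] <- cand$levels[k]  # direct gene mods win
      }
      gene_fold_bounds(levels)
    })
}

worst_value <- function(direction) if (direction == "max") -Inf else Inf

#' Evaluate a candidate's fitness
#'
#' Decodes the candidate once, runs each objective's simulation method on
#' the constrained view and assembles the fitness vector. Simulation
#' failures are mapped into `feasible = FALSE` with worst-case sentinel
#' values; no errors escape into optimization loops. Results are cached
#' by decoded constraint map (bounded LRU).
#'
#' @param problem a `cso_problem`
#' @param cand a `candidate`
#' @return a `fitness`: list with `values` (aligned with the objectives)
#'   and `feasible`
#' @export
evaluate_candidate <- function(problem, cand) {
  constraints <- tryCatch(decode_candidate(problem, cand),
                          error = function(e) NULL)
  if (is.null(constraints)) {
    return(structure(list(values = vapply(problem$objectives, function(ob)
      worst_value(ob$direction), 0), feasible = FALSE,
      constraints = NULL), class = "fitness"))
  }
  key <- if (length(constraints)) {
    paste(names(constraints), vapply(constraints, paste, "", collapse = ","),
          sep = "=", collapse = ";")
  } else ""
  hit <- problem$cache[[paste0("f:", key)]]
  if (!is.null(hit)) {
    hit$n_mods <- length(cand$targets)
    hit$values <- fitness_values(problem, hit, cand)
    return(hit)
  }

  view <- apply_conditions(problem_view(problem, with_pool = TRUE),
                           extra = constraints)
  w <- wild_type_reference(problem)

  sims <- list()   # method -> result, shared across objectives
  get_sim <- function(method) {
    m <- toupper(method)
    if (!is.null(sims[[m]])) return(sims[[m]])
    r <- tryCatch(
      simulate_phenotype(view, method, reference = w),
      error = function(e) simulation_result("error", method = method))
    sims[[m]] <<- r
    r
  }

  per_obj <- lapply(problem$objectives, function(ob) {
    biomass <- ob$biomass_id %||% problem$model$objective
    if (ob$kind == "modification_count")
      return(list(ok = TRUE, raw = NA_real_, kind = "count"))
    if (ob$kind == "WYIELD") {
      val <- tryCatch(
        wyield(view, biomass, ob$product_id, ob$alpha,
               ob$objective_fraction),
        error = function(e) NA_real_)
      return(list(ok = !is.na(val), raw = val, kind = "value"))
    }
    r <- get_sim(ob$method)
    if (r$status != "optimal")
      return(list(ok = FALSE, raw = NA_real_, kind = "value"))
    val <- switch(ob$kind,
      BPCY = bpcy(r, biomass, ob$product_id, ob$substrate_id),
      target_flux = r$fluxes[[ob$product_id]],
      growth = r$fluxes[[biomass]])
    list(ok = TRUE, raw = val, kind = "value")
  })

  feasible <- all(vapply(per_obj, `[[`, NA, "ok"))
  fit <- structure(list(per_obj = per_obj, feasible = feasible,
                        constraints = constraints,
                        n_mods = length(cand$targets)),
                   class = "fitness")
  fit$values <- fitness_values(problem, fit, cand)
  cache_put(problem, paste0("f:", key), fit)
  fit
}

fitness_values <- function(problem, fit, cand) {
  vapply(seq_along(problem$objectives), function(k) {
    ob <- problem$objectives[[k]]
    po <- fit$per_obj[[k]]
    if (!fit$feasible || !po$ok) return(worst_value(ob$direction))
    if (identical(po$kind, "count")) return(length(cand$targets))
    po$raw
  }, 0)
}

cache_put <- function(problem, key, value) {
  e <- problem$cache
  cnt <- (e$.n %||% 0L) + 1L
  e$.n <- cnt
  value$.stamp <- cnt
  e[[key]] <- value
  keys <- setdiff(ls(e, all.names = FALSE), character())
  if (length(keys) > problem$cache_max) {
    stamps <- vapply(keys, function(k) {
      s <- e[[k]]$.stamp
      if (is.null(s)) Inf else s
    }, 0)
    drop <- keys[order(stamps)][seq_len(length(keys) - problem$cache_max)]
    rm(list = drop, envir = e)
  }
  invisible(value)
}

#' Enumerate and evaluate every candidate of a small problem
#'
#' Brute-force sweep over all candidates of size 1..max_modifications
#' with all level-grid assignments. Intended for desk-scale problems and
#' as the reference against which evolutionary runs are checked.
#'
#' @param problem a `cso_problem`
#' @param limit guard on the candidate-space size (default 10000)
#' @return data.frame with `modifications`, one column per objective,
#'   and `feasible`
#' @export
enumerate_candidates <- function(problem, limit = 10000) {
  tg <- problem$targets
  lv <- problem$level_grid
  combos <- list()
  for (sz in seq_len(problem$max_modifications)) {
    if (sz > length(tg)) break
    sets <- utils::combn(tg, sz, simplify = FALSE)
    grids <- do.call(expand.grid, rep(list(lv), sz))
    for (s in sets) for (gi in seq_len(nrow(grids)))
      combos[[length(combos) + 1L]] <- candidate(s, as.numeric(grids[gi, ]))
    if (length(combos) > limit)
      stop("candidate space exceeds limit (", limit, ")")
  }
  rows <- lapply(combos, function(cd) {
    fit <- evaluate_candidate(problem, cd)
    c(list(modifications = format(cd)),
      stats::setNames(as.list(fit$values),
                      vapply(problem$objectives, `[[`, "", "kind")),
      list(feasible = fit$feasible))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- make.unique(names(out))
  out
}
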