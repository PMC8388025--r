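# Protein-pool enzymatic constraints: a shared enzyme-mass budget
# sum_j (MW_j / kcat_j) * v_j <= P_pool over enzyme-catalysed fluxes,
# plus per-enzyme expression modifications.

#' Construct enzyme parameters
#'
#' @param table data.frame with columns `reaction_id`, `kcat_per_h`
#'   (turnover number, 1/h, in the flux direction) and `mw_kda` (enzyme
#'   molecular weight, kDa)
#' @param pool total protein budget P_pool (g/gDW)
#' @return an `enzyme_params` object; the per-unit-flux cost of reaction j
#'   is `mw_kda / kcat_per_h`
#' @export
enzyme_params <- function(table, pool) {
  need <- c("reaction_id", "kcat_per_h", "mw_kda")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  if (any(table$kcat_per_h <= 0)) stop("kcat must be > 0")
  if (any(table$mw_kda <= 0)) stop("molecular weight must be > 0")
  if (pool <= 0) stop("protein pool must be > 0")
  structure(list(table = table[need], pool = pool), class = "enzyme_params")
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat("<enzyme_params> ", nrow(x$table), " reactions, pool ",
      x$pool, " g/gDW\n", sep = "")
  invisible(x)
}

enzyme_costs <- function(params) {
  stats::setNames(params$table$mw_kda / params$table$kcat_per_h,
                  params$table$reaction_id)
}

#' Read an enzyme parameter TSV (columns reaction_id, kcat_per_h, mw_kda)
#' @param path file path
#' @param pool protein budget (g/gDW)
#' @return an `enzyme_params` object
#' @export
read_enzyme_tsv <- function(path, pool) {
  enzyme_params(utils::read.delim(path, stringsAsFactors = FALSE), pool)
}

#' Write an enzyme parameter TSV
#' @param params an `enzyme_params` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enzyme_tsv <- function(params, path) {
  utils::write.table(params$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach a shared protein-pool constraint to a model view
#'
#' Adds the linear budget `sum_j (mw_j / kcat_j) v_j <= pool` over the
#' parameterized reactions; every simulator run on the returned view
#' honours it. Parameterized reactions must be irreversible in the view
#' (`lb >= 0`); reversible ones must first be split with
#' [split_reversible()].
#'
#' @param model a `metabolic_model` or view
#' @param params an `enzyme_params` object
#' @return a `model_view` carrying the pool constraint
#' @export
attach_protein_pool <- function(model, params) {
  view <- as_view(model)
  rids <- params$table$reaction_id
  bad <- setdiff(rids, names(view$base$reactions))
  if (length(bad))
    stop("enzyme parameters reference unknown reaction(s): ",
         paste(bad, collapse = ", "))
  no_gpr <- rids[vapply(rids, function(r)
    is.null(view$base$reactions[[r]]$gpr), NA)]
  if (length(no_gpr))
    stop("only reactions with GPRs may carry enzyme parameters: ",
         paste(no_gpr, collapse = ", "))
  rev <- rids[view$bounds[rids, 1] < 0]
  if (length(rev))
    stop("parameterized reaction(s) must be irreversible (lb >= 0): ",
         paste(rev, collapse = ", "), "; split first with split_reversible()")
  view$pool_constraints <- c(view$pool_constraints,
                             list(list(coef = enzyme_costs(params),
                                       sense = "<=", rhs = params$pool)))
  view
}

#' Enzyme-usage accounting of a flux distribution
#' @param fluxes named flux vector
#' @param params an `enzyme_params` object
#' @return total enzyme usage `sum (mw/kcat) v` (g/gDW)
#' @export
enzyme_usage <- function(fluxes, params) {
  costs <- enzyme_costs(params)
  sum(costs * fluxes[names(costs)])
}

#' Decode an enzyme expression modification into a flux cap
#'
#' Scales the reaction's permitted enzyme usage relative to the wild type:
#' with reference usage `u = (mw/kcat) w` the cap becomes
#' `(mw/kcat) v <= fold * u`, i.e. `v <= fold * w`. `fold = 0` shuts the
#' reaction, `fold = 1` is a no-op, `fold > 1` allows usage above wild
#' type (the shared pool still binds globally).
#'
#' @param reaction_id parameterized reaction
#' @param fold non-negative expression fold
#' @param params an `enzyme_params` object
#' @param reference_flux wild-type flux of the reaction
#' @param lb,ub the reaction's current bounds
#' @return numeric `c(lb, ub)` or NULL for a no-op
#' @export
enzyme_modification_bounds <- function(reaction_id, fold, params,
                                       reference_flux, lb, ub) {
  if (fold < 0) stop("enzyme expression fold must be >= 0")
  if (!reaction_id %in% params$table$reaction_id)
    stop("reaction '", reaction_id, "' carries no enzyme parameters")
  if (fold == 1) return(NULL)
  if (fold == 0) return(c(0, 0))
  cap <- fold * reference_flux
  c(max(lb, 0), min(ub, max(cap, 0)))
}

#' Split a reversible reaction into irreversible forward/backward halves
#'
#' Replaces `rid` (lb < 0 < ub) by `rid_fwd` (0, ub) and `rid_bwd`
#' (0, -lb) with negated stoichiometry, both inheriting the GPR. Needed
#' before attaching enzyme parameters to reversible reactions.
#'
#' @param model a `metabolic_model`
#' @param reaction_ids reactions to split
#' @return a new `metabolic_model`
#' @export
split_reversible <- function(model, reaction_ids) {
  model <- base_model(model)
  rxns <- list()
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (rid %in% reaction_ids && r$lb < 0) {
      gpr_str <- if (is.null(r$gpr)) NULL else gpr_unparse(r$gpr)
      rxns[[paste0(rid, "_fwd")]] <- list(stoichiometry = r$stoichiometry,
                                          lb = 0, ub = max(r$ub, 0),
                                          gpr = gpr_str)
      rxns[[paste0(rid, "_bwd")]] <- list(stoichiometry = -r$stoichiometry,
                                          lb = 0, ub = -r$lb,
                                          gpr = gpr_str)
    } else {
      rxns[[rid]] <- list(stoichiometry = r$stoichiometry, lb = r$lb,
                          ub = r$ub,
                          gpr = if (is.null(r$gpr)) NULL else gpr_unparse(r$gpr))
    }
  }
  objective <- model$objective
  if (!is.na(objective) && objective %in% reaction_ids &&
      !(objective %in% names(rxns)))
    objective <- paste0(objective, "_fwd")
  metabolic_model(model$metabolites, rxns, genes = model$genes,
                  objective = objective, annotations = model$annotations)
}
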