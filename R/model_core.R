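# Metabolic model data structures, readers/writers, stoichiometric assembly
# and environmental-condition overlays.

#' Default flux bound used to clamp infinite bounds
#'
#' Constraint-based models conventionally cap unbounded fluxes at
#' 1000 mmol/gDW/h so that every LP stays bounded. SBML infinities are
#' clamped to this magnitude on load.
#' @export
DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' The container every simulation and optimization routine operates on:
#' metabolites, reactions with flux bounds and stoichiometry, genes, GPR
#' (gene-protein-reaction) rules and a designated objective (biomass)
#' reaction.
#'
#' @param metabolites data.frame with columns `id`, `compartment` and
#'   optionally `name`.
#' @param reactions named list; each element a list with fields
#'   `stoichiometry` (named numeric, metabolite id -> signed coefficient,
#'   negative = consumed), `lb`, `ub`, and optionally `gpr` (string or
#'   parsed [gpr] expression).
#' @param genes character vector of gene ids.
#' @param objective id of the objective (biomass) reaction, or `NA`.
#' @param annotations free-form named list.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective = NA_character_,
                            annotations = list()) {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites,
                              compartment = "c",
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (any(!nzchar(metabolites$id))) stop("empty metabolite id")
  if (is.null(names(reactions)) || any(!nzchar(names(reactions))))
    stop("reactions must be a named list")
  if (anyDuplicated(names(reactions)))
    stop("duplicate reaction ids")

  rxns <- lapply(names(reactions), function(rid) {
    r <- reactions[[rid]]
    st <- r$stoichiometry
    if (is.null(st)) st <- numeric()
    st <- unlist(st)
    if (length(st) && is.null(names(st)))
      stop("reaction ", rid, ": stoichiometry must be named by metabolite id")
    if (length(st)) storage.mode(st) <- "double"
    lb <- if (is.null(r$lb)) -DEFAULT_BOUND else as.numeric(r$lb)
    ub <- if (is.null(r$ub)) DEFAULT_BOUND else as.numeric(r$ub)
    if (lb > ub) stop("reaction ", rid, ": lower bound ", lb,
                      " exceeds upper bound ", ub)
    bad <- setdiff(names(st), metabolites$id)
    if (length(bad))
      stop("reaction ", rid, ": unknown metabolite(s) ",
           paste(bad, collapse = ", "))
    gpr <- r$gpr
    if (!is.null(gpr) && is.character(gpr)) {
      gpr <- tryCatch(parse_gpr(gpr), error = function(e)
        stop("reaction ", rid, ": ", conditionMessage(e), call. = FALSE))
    }
    list(id = rid, stoichiometry = st, lb = lb, ub = ub, gpr = gpr)
  })
  names(rxns) <- names(reactions)

  gpr_genes <- unique(unlist(lapply(rxns, function(r)
    if (is.null(r$gpr)) character() else gpr_genes(r$gpr))))
  genes <- union(as.character(genes), gpr_genes)

  if (!is.na(objective) && !objective %in% names(rxns))
    stop("objective reaction '", objective, "' not in model")

  structure(list(metabolites = metabolites,
                 reactions = rxns,
                 genes = genes,
                 objective = objective,
                 annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`
#' @return character vector
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Gene ids of a model
#' @param model a `metabolic_model`
#' @return character vector
#' @export
gene_ids <- function(model) model$genes

#' Stoichiometric matrix
#'
#' Assembles the metabolites-by-reactions matrix S with S\[i, j\] the signed
#' coefficient of metabolite i in reaction j (negative = consumed). Row order
#' follows the model's metabolite order, column order its reaction order.
#'
#' @param model a `metabolic_model` or model view.
#' @return a dense numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  model <- base_model(model)
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (rid in rids) {
    st <- model$reactions[[rid]]$stoichiometry
    if (length(st)) S[names(st), rid] <- st
  }
  S
}

#' Environmental conditions (growth medium) as bound overrides
#'
#' @param bounds named list or data.frame mapping reaction ids to
#'   `c(lb, ub)` pairs.
#' @return an `environmental_conditions` object.
#' @export
environmental_conditions <- function(bounds = list()) {
  if (is.data.frame(bounds)) {
    b <- lapply(seq_len(nrow(bounds)), function(i)
      c(bounds$lb[i], bounds$ub[i]))
    names(b) <- bounds$reaction_id
    bounds <- b
  }
  for (rid in names(bounds)) {
    p <- as.numeric(bounds[[rid]])
    if (length(p) != 2 || p[1] > p[2])
      stop("conditions for ", rid, ": need lb <= ub")
    bounds[[rid]] <- p
  }
  structure(list(bounds = bounds), class = "environmental_conditions")
}

#' Read a growth-medium TSV (columns reaction_id, lb, ub)
#' @param path file path
#' @return an `environmental_conditions` object
#' @export
read_medium_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("medium file must have columns reaction_id, lb, ub")
  environmental_conditions(data.frame(reaction_id = tab$reaction_id,
                                      lb = tab$lb, ub = tab$ub))
}

#' Apply environmental conditions and per-candidate constraints to a model
#'
#' Produces a non-destructive view of the model with merged bounds. The
#' precedence is: `extra` (per-candidate constraints) over `env` (medium)
#' over the model's native bounds. The base model is never mutated; a view
#' is what every simulator consumes.
#'
#' @param model a `metabolic_model` or an existing view (overlays stack).
#' @param env an `environmental_conditions` object or named list of
#'   `c(lb, ub)` pairs.
#' @param extra named list of `c(lb, ub)` pairs taking precedence over `env`.
#' @return a `model_view` object.
#' @export
apply_conditions <- function(model, env = NULL, extra = NULL) {
  base <- base_model(model)
  bounds <- effective_bounds(model)   # inherits overlays if model is a view
  pool <- if (inherits(model, "model_view")) model$pool_constraints else list()
  merge_in <- function(bmap, overrides, label) {
    for (rid in names(overrides)) {
      if (!rid %in% rownames(bmap))
        stop(label, ": unknown reaction '", rid, "'")
      p <- as.numeric(overrides[[rid]])
      bmap[rid, ] <- p
    }
    bmap
  }
  if (inherits(env, "environmental_conditions")) env <- env$bounds
  if (!is.null(env)) bounds <- merge_in(bounds, env, "conditions")
  if (!is.null(extra)) bounds <- merge_in(bounds, extra, "constraints")
  bad <- rownames(bounds)[bounds[, 1] > bounds[, 2]]
  if (length(bad))
    stop("constraint conflict: lb > ub for reaction(s) ",
         paste(bad, collapse = ", "))
  structure(list(base = base, bounds = bounds, pool_constraints = pool),
            class = "model_view")
}

#' @export
print.model_view <- function(x, ...) {
  changed <- sum(x$bounds[, 1] != vapply(x$base$reactions, `[[`, 0, "lb") |
                 x$bounds[, 2] != vapply(x$base$reactions, `[[`, 0, "ub"))
  cat("<model_view> over ", length(x$base$reactions), " reactions (",
      changed, " bound overrides, ", length(x$pool_constraints),
      " pool constraints)\n", sep = "")
  invisible(x)
}

#' Underlying model of a view (identity on plain models)
#' @param model model or view
#' @return the base `metabolic_model`
#' @export
base_model <- function(model) {
  if (inherits(model, "model_view")) model$base else model
}

#' Effective bounds of a model or view
#'
#' @param model model or view
#' @return a reactions-by-2 matrix with columns lb, ub
#' @export
effective_bounds <- function(model) {
  if (inherits(model, "model_view")) return(model$bounds)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  cbind(lb = lb, ub = ub)
}

as_view <- function(model) {
  if (inherits(model, "model_view")) model else apply_conditions(model)
}

clamp_bound <- function(x) {
  x[x > DEFAULT_BOUND] <- DEFAULT_BOUND
  x[x < -DEFAULT_BOUND] <- -DEFAULT_BOUND
  x
}

#' Load a metabolic model from SBML (L3+FBC) or the JSON dialect
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return a `metabolic_model`
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Read the JSON model dialect
#'
#' Dialect: `{"metabolites":[{"id","compartment"}], "reactions":[{"id",
#' "stoichiometry":{met:coef}, "lb","ub","gpr":string-or-null}],
#' "genes":[ids], "objective": reaction-id}`.
#'
#' @param path file path
#' @return a `metabolic_model`
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("JSON model missing 'metabolites' or 'reactions': ", path)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), ""),
    compartment = vapply(doc$metabolites, function(m)
      if (is.null(m$compartment)) "c" else as.character(m$compartment), ""),
    stringsAsFactors = FALSE)
  rxns <- list()
  for (r in doc$reactions) {
    if (is.null(r$id)) stop("JSON reaction without id")
    st <- unlist(r$stoichiometry)
    rxns[[as.character(r$id)]] <- list(
      stoichiometry = st,
      lb = clamp_bound(if (is.null(r$lb)) -DEFAULT_BOUND else as.numeric(r$lb)),
      ub = clamp_bound(if (is.null(r$ub)) DEFAULT_BOUND else as.numeric(r$ub)),
      gpr = if (is.null(r$gpr) || !nzchar(r$gpr)) NULL else as.character(r$gpr))
  }
  objective <- if (is.null(doc$objective)) NA_character_
               else as.character(doc$objective)
  metabolic_model(mets, rxns,
                  genes = as.character(unlist(doc$genes)),
                  objective = objective)
}

#' Write a model in the JSON dialect
#'
#' Round-trips with [read_model_json()]: ids, bounds, GPR strings and the
#' objective are preserved structurally.
#'
#' @param model a `metabolic_model`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  model <- base_model(model)
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(model$reactions, function(r) {
      out <- list(id = r$id, stoichiometry = as.list(r$stoichiometry),
                  lb = r$lb, ub = r$ub)
      out$gpr <- if (is.null(r$gpr)) NULL else gpr_unparse(r$gpr)
      out
    }),
    genes = as.list(model$genes),
    objective = model$objective)
  names(doc$reactions) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

#' Read an SBML Level 3 + FBC v2 model
#'
#' Supports flux bounds through FBC bound parameters, gene associations
#' through `fbc:geneProductAssociation` and the active FBC objective.
#' Infinite bounds are clamped to `DEFAULT_BOUND`.
#'
#' @param path file path
#' @return a `metabolic_model`
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- sbml_ns
  get1 <- function(node, xp) xml2::xml_find_first(node, xp, ns)
  getall <- function(node, xp) xml2::xml_find_all(node, xp, ns)
  attr1 <- function(node, a) xml2::xml_attr(node, a, ns = ns)

  # bound parameters
  params <- getall(doc, ".//s:listOfParameters/s:parameter")
  pval <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(params, "value"))),
    xml2::xml_attr(params, "id"))

  species <- getall(doc, ".//s:listOfSpecies/s:species")
  if (!length(species)) stop("SBML: no species found in ", path)
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(species, "id")[!boundary],
    compartment = xml2::xml_attr(species, "compartment")[!boundary],
    stringsAsFactors = FALSE)

  gps <- getall(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct")
  gp_id <- xml2::xml_attr(gps, "fbc:id", ns = ns)
  gp_lab <- xml2::xml_attr(gps, "fbc:label", ns = ns)
  gp_label <- stats::setNames(ifelse(is.na(gp_lab), gp_id, gp_lab), gp_id)

  gpa_to_string <- function(node) {
    name <- xml2::xml_name(node)
    if (name == "geneProductRef") {
      ref <- attr1(node, "fbc:geneProduct")
      lab <- gp_label[[ref]]
      return(if (is.null(lab) || is.na(lab)) ref else lab)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, "")
    op <- if (name == "and") " and " else if (name == "or") " or " else
      stop("SBML: unsupported GPR node <", name, ">")
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- getall(doc, ".//s:listOfReactions/s:reaction")
  rxns <- list()
  for (rn in rnodes) {
    rid <- attr1(rn, "id")
    # reactants negative, products positive; boundary species skipped
    st <- numeric()
    for (sr in getall(rn, "./s:listOfReactants/s:speciesReference")) {
      sp <- attr1(sr, "species")
      if (!sp %in% mets$id) next
      k <- suppressWarnings(as.numeric(attr1(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      st[sp] <- (if (sp %in% names(st) && !is.na(st[sp])) st[sp] else 0) - k
    }
    for (sr in getall(rn, "./s:listOfProducts/s:speciesReference")) {
      sp <- attr1(sr, "species")
      if (!sp %in% mets$id) next
      k <- suppressWarnings(as.numeric(attr1(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      st[sp] <- (if (sp %in% names(st) && !is.na(st[sp])) st[sp] else 0) + k
    }
    lb_ref <- attr1(rn, "fbc:lowerFluxBound")
    ub_ref <- attr1(rn, "fbc:upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else {
      rev <- attr1(rn, "reversible") %in% "true"
      if (rev) -DEFAULT_BOUND else 0
    }
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]]
          else DEFAULT_BOUND
    if (is.na(lb)) lb <- -DEFAULT_BOUND
    if (is.na(ub)) ub <- DEFAULT_BOUND
    gpa <- get1(rn, "./fbc:geneProductAssociation")
    gpr <- NULL
    if (!inherits(gpa, "xml_missing")) {
      inner <- xml2::xml_children(gpa)
      if (length(inner))
        gpr <- tryCatch(gpa_to_string(inner[[1]]), error = function(e)
          stop("SBML reaction ", rid, ": ", conditionMessage(e)))
    }
    rxns[[rid]] <- list(stoichiometry = st,
                        lb = clamp_bound(lb), ub = clamp_bound(ub),
                        gpr = gpr)
  }

  obj <- NA_character_
  objs <- getall(doc, ".//fbc:listOfObjectives/fbc:objective")
  if (length(objs)) {
    active <- attr1(get1(doc, ".//fbc:listOfObjectives"), "fbc:activeObjective")
    onode <- objs[[1]]
    if (!is.na(active)) {
      hit <- which(xml2::xml_attr(objs, "fbc:id") == active)
      if (length(hit)) onode <- objs[[hit[1]]]
    }
    fo <- get1(onode, ".//fbc:fluxObjective")
    if (!inherits(fo, "xml_missing")) obj <- attr1(fo, "fbc:reaction")
  }
  metabolic_model(mets, rxns, objective = obj)
}
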