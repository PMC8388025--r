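# Boolean transcriptional-regulatory networks and their integration with
# metabolism: synchronous state updates, steady-state computation, rFBA
# (steady state then FBA) and srFBA (one joint MILP).

#' Construct a Boolean regulatory network
#'
#' Each rule maps a target (metabolic gene or transcription factor) to a
#' Boolean expression over regulators, environment signals (ids prefixed
#' `env_`) and the constants `true`/`false`. Operators: `and`, `or`,
#' `not` (case-insensitive), with parentheses; `not` binds tightest.
#'
#' @param rules named character vector: target id -> rule string
#' @param regulators character vector of transcription-factor ids
#' @param signals character vector of environment signal ids
#' @return a `regulatory_network`
#' @export
regulatory_network <- function(rules, regulators = character(),
                               signals = character()) {
  if (anyDuplicated(names(rules))) stop("duplicate rule target")
  exprs <- lapply(rules, parse_bool_rule)
  targets <- names(rules)
  referenced <- unique(unlist(lapply(exprs, bool_rule_vars)))
  signals <- union(signals, grep("^env_", referenced, value = TRUE))
  structure(list(rules = exprs,
                 targets = targets,
                 regulators = unique(regulators),
                 signals = unique(signals)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", length(x$rules), " rules, ",
      length(x$regulators), " regulators, ", length(x$signals),
      " signals\n", sep = "")
  invisible(x)
}

# Boolean rule parser: reuses the GPR tokenizer; adds not and constants.
parse_bool_rule <- function(rule) {
  if (!nzchar(trimws(rule))) stop("empty regulatory rule")
  toks <- gpr_tokenize(gsub("!", " not ", rule, fixed = TRUE))
  i <- 1L; n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(rule) + 1L
  is_kw <- function(t, kw) !is.na(t) && tolower(t) %in% kw
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("rule parse error at position ", pos(),
                       ": unexpected end")
    if (t == "(") {
      at <- pos(); i <<- i + 1L
      node <- parse_or()
      if (!identical(peek(), ")"))
        stop("rule parse error at position ", at, ": unbalanced parenthesis")
      i <<- i + 1L
      return(node)
    }
    if (is_kw(t, "not")) { i <<- i + 1L
      return(list(op = "not", children = list(parse_atom()))) }
    if (is_kw(t, c("true", "false", "1", "0"))) { i <<- i + 1L
      return(list(op = "const", value = tolower(t) %in% c("true", "1"))) }
    if (t == ")" || is_kw(t, c("and", "or", "&", "|", "&&", "||")))
      stop("rule parse error at position ", pos(), ": unexpected '", t, "'")
    i <<- i + 1L
    list(op = "var", id = t)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (is_kw(peek(), c("and", "&", "&&"))) { i <<- i + 1L
      kids <- c(kids, list(parse_atom())) }
    if (length(kids) == 1) kids[[1]] else list(op = "and", children = kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (is_kw(peek(), c("or", "|", "||"))) { i <<- i + 1L
      kids <- c(kids, list(parse_and())) }
    if (length(kids) == 1) kids[[1]] else list(op = "or", children = kids)
  }
  node <- parse_or()
  if (i <= n)
    stop("rule parse error at position ", pos(), ": unexpected '",
         peek(), "'")
  node
}

bool_rule_vars <- function(node) {
  if (node$op == "var") return(node$id)
  if (node$op == "const") return(character())
  unique(unlist(lapply(node$children, bool_rule_vars)))
}

eval_bool_rule <- function(node, state) {
  switch(node$op,
         var = isTRUE(state[[node$id]]),
         const = node$value,
         not = !eval_bool_rule(node$children[[1]], state),
         and = all(vapply(node$children, eval_bool_rule, NA, state = state)),
         or = any(vapply(node$children, eval_bool_rule, NA, state = state)))
}

network_ids <- function(net) {
  unique(c(net$targets, net$regulators, net$signals,
           unlist(lapply(net$rules, bool_rule_vars))))
}

#' Build a complete regulatory state
#'
#' All network ids default to TRUE (genes expressed, signals off must be
#' set explicitly) unless overridden.
#'
#' @param net a `regulatory_network`
#' @param values named logical vector of overrides
#' @param default default value for unlisted ids
#' @return named logical vector over every target, regulator and signal
#' @export
regulatory_state <- function(net, values = logical(), default = TRUE) {
  ids <- network_ids(net)
  st <- stats::setNames(rep(default, length(ids)), ids)
  for (id in names(values)) st[[id]] <- isTRUE(values[[id]])
  st
}

#' One synchronous update of a regulatory network
#'
#' Every non-frozen target is re-evaluated simultaneously from the
#' previous state; regulators without rules and environment signals are
#' never updated. Frozen ids (e.g. deleted TFs pinned FALSE) keep their
#' current value.
#'
#' @param net a `regulatory_network`
#' @param state complete named logical state
#' @param frozen character vector of ids excluded from updating
#' @return the next state
#' @export
synchronous_update <- function(net, state, frozen = character()) {
  nxt <- state
  for (tgt in net$targets) {
    if (tgt %in% frozen) next
    nxt[[tgt]] <- eval_bool_rule(net$rules[[tgt]], as.list(state))
  }
  nxt
}

#' Iterate a regulatory network to steady state
#'
#' Synchronous updates until a fixed point or a revisited state. On a
#' cycle the returned state is the element-wise AND over the cycle's
#' states (conservative: a variable is ON only if ON throughout the
#' cycle) and `converged` is FALSE.
#'
#' @inheritParams synchronous_update
#' @param initial complete initial state (see [regulatory_state()])
#' @param max_iter iteration cap (default `2^n_targets + 1`, capped at 256)
#' @return list with `state` and `converged`
#' @export
regulatory_steady_state <- function(net, initial, frozen = character(),
                                    max_iter = NULL) {
  if (is.null(max_iter))
    max_iter <- min(2L^length(net$targets) + 1L, 256L)
  stopifnot(max_iter >= 1)
  seen <- list(initial)
  state <- initial
  for (it in seq_len(max_iter)) {
    nxt <- synchronous_update(net, state, frozen)
    if (identical(nxt, state))
      return(list(state = state, converged = TRUE))
    hit <- which(vapply(seen, identical, NA, y = nxt))
    if (length(hit)) {
      cyc <- seen[hit[1]:length(seen)]
      collapsed <- Reduce(`&`, cyc)
      collapsed[net$signals[net$signals %in% names(collapsed)]] <-
        state[net$signals[net$signals %in% names(state)]]
      return(list(state = collapsed, converged = FALSE))
    }
    seen <- c(seen, list(nxt))
    state <- nxt
  }
  list(state = state, converged = FALSE)
}

#' Regulatory FBA (rFBA)
#'
#' Computes the regulatory steady state from the initial state, turns off
#' every metabolic gene that is OFF at steady state, disables reactions
#' whose GPR evaluates FALSE under that deletion set, and runs FBA.
#'
#' @param model a `metabolic_model` or view
#' @param net a `regulatory_network` whose metabolic-gene targets are in
#'   the model
#' @param initial initial regulatory state; defaults to all-TRUE with
#'   signals as given in `signals`
#' @param frozen ids pinned at their initial value (TF deletions)
#' @param signals named logical vector of environment signal values
#' @return a `simulation_result` with extra fields `regulatory_state` and
#'   `off_genes`
#' @export
rfba <- function(model, net, initial = NULL, frozen = character(),
                 signals = logical()) {
  view <- as_view(model)
  if (is.null(initial)) {
    init_vals <- signals
    for (f in frozen) if (!f %in% names(init_vals)) init_vals[f] <- FALSE
    initial <- regulatory_state(net, init_vals)
  }
  ss <- regulatory_steady_state(net, initial, frozen)
  off <- off_metabolic_genes(net, ss$state, view$base)
  dis <- disabled_reactions(view$base, off)
  view2 <- if (length(dis)) {
    apply_conditions(view, extra = stats::setNames(
      rep(list(c(0, 0)), length(dis)), dis))
  } else view
  res <- fba(view2)
  res$method <- "rFBA"
  res$regulatory_state <- ss$state
  res$off_genes <- off
  res
}

off_metabolic_genes <- function(net, state, model) {
  cand <- intersect(net$targets, model$genes)
  cand[!vapply(cand, function(g) isTRUE(state[[g]]), NA)]
}

disabled_reactions <- function(model, off_genes) {
  if (!length(off_genes)) return(character())
  rids <- names(model$reactions)
  rids[vapply(rids, function(rid) {
    g <- model$reactions[[rid]]$gpr
    !is.null(g) && !eval_boolean(g, off_genes)
  }, NA)]
}

# ---- srFBA ---------------------------------------------------------------

# Linearize a Boolean expression tree over binary variables; returns rows
# to append and the index of the binary holding the expression's value.
# `var_idx(id)` resolves/creates the binary column for a variable id.
linearize_bool <- function(node, var_idx, new_aux, add_row) {
  lin <- function(nd) {
    if (nd$op == "var") return(var_idx(nd$id))
    if (nd$op == "const") {
      j <- new_aux()
      add_row(stats::setNames(1, j), "=", as.numeric(nd$value))
      return(j)
    }
    kids <- vapply(nd$children, lin, 0L)
    j <- new_aux()
    if (nd$op == "not") {
      add_row(stats::setNames(c(1, 1), c(j, kids[1])), "=", 1)
    } else if (nd$op == "and") {
      for (k in kids)
        add_row(stats::setNames(c(1, -1), c(j, k)), "<=", 0)
      add_row(stats::setNames(c(1, rep(-1, length(kids))), c(j, kids)),
              ">=", -(length(kids) - 1))
    } else { # or
      for (k in kids)
        add_row(stats::setNames(c(1, -1), c(j, k)), ">=", 0)
      add_row(stats::setNames(c(1, rep(-1, length(kids))), c(j, kids)),
              "<=", 0)
    }
    j
  }
  lin(node)
}

#' Steady-state regulatory FBA (srFBA)
#'
#' Single MILP over joint flux and Boolean variables: each regulatory rule
#' is linearized (`b_target = b_expression` via standard AND/OR/NOT
#' indicator rows), gene binaries gate their reactions through the
#' linearized GPR (`lb_i b <= v_i <= ub_i b`), and biomass is maximized
#' over the joint space. Cyclic regulatory binaries are left free, so on
#' networks with cycles srFBA may find states the conservative rFBA
#' collapse discards; on acyclic networks the two coincide.
#'
#' @inheritParams rfba
#' @return a `simulation_result` with extra field `regulatory_state`
#' @export
srfba <- function(model, net, frozen = character(), signals = logical()) {
  view <- as_view(model)
  modelb <- view$base
  rids <- names(modelb$reactions)
  n <- length(rids)
  p0 <- build_fba_problem(view, modelb$objective)

  nv <- n                      # total variable count (grows)
  bin_of <- new.env(parent = emptyenv())   # id -> column
  rows <- list()
  new_col <- function() { nv <<- nv + 1L; nv }
  add_row <- function(coef, sense, rhs)
    rows[[length(rows) + 1L]] <<- list(coef = coef, sense = sense, rhs = rhs)
  var_idx <- function(id) {
    if (!is.null(bin_of[[id]])) return(bin_of[[id]])
    j <- new_col()
    bin_of[[id]] <- j
    j
  }

  # fix signals and frozen ids
  for (s in net$signals) {
    j <- var_idx(s)
    val <- if (s %in% names(signals)) as.numeric(isTRUE(signals[[s]])) else 1
    add_row(stats::setNames(1, j), "=", val)
  }
  for (f in frozen) {
    j <- var_idx(f)
    add_row(stats::setNames(1, j), "=", 0)
  }
  # rule constraints: b_target = b_expr (skip frozen targets)
  for (tgt in net$targets) {
    if (tgt %in% frozen) next
    jt <- var_idx(tgt)
    je <- linearize_bool(net$rules[[tgt]], var_idx, new_col, add_row)
    add_row(stats::setNames(c(1, -1), c(jt, je)), "=", 0)
  }
  # reaction gating: only reactions whose GPR touches regulated/frozen genes
  touched <- union(intersect(net$targets, modelb$genes),
                   intersect(frozen, modelb$genes))
  lb <- view$bounds[, 1]; ub <- view$bounds[, 2]
  for (k in seq_len(n)) {
    g <- modelb$reactions[[k]]$gpr
    if (is.null(g) || !length(intersect(gpr_genes(g), touched))) next
    jr <- linearize_bool(gpr_to_bool_node(g), var_idx, new_col, add_row)
    add_row(stats::setNames(c(1, -ub[k]), c(k, jr)), "<=", 0)
    add_row(stats::setNames(c(1, -lb[k]), c(k, jr)), ">=", 0)
  }

  nb <- nv - n
  A <- cbind(p0$A, matrix(0, nrow(p0$A), nb))
  sense <- p0$sense; rhs <- p0$rhs
  for (r in rows) {
    row <- rep(0, nv)
    row[as.integer(names(r$coef))] <- r$coef
    A <- rbind(A, row)
    sense <- c(sense, r$sense)
    rhs <- c(rhs, r$rhs)
  }
  p <- solver_problem(n = nv,
                      lb = c(lb, rep(0, nb)), ub = c(ub, rep(1, nb)),
                      obj = c(p0$obj, rep(0, nb)), maximize = TRUE,
                      A = A, sense = sense, rhs = rhs,
                      binary = n + seq_len(nb))
  r <- solve_milp(p)
  if (r$status != "optimal")
    return(simulation_result(r$status, method = "srFBA"))
  state <- stats::setNames(logical(0), character(0))
  for (id in ls(bin_of)) state[id] <- r$x[bin_of[[id]]] > 0.5
  simulation_result("optimal", r$objective,
                    flux_distribution(r$x[seq_len(n)], rids), "srFBA",
                    extra = list(regulatory_state = state))
}

# GPR tree -> Boolean-rule node shape (gene leaves become vars)
gpr_to_bool_node <- function(g) {
  if (g$op == "gene") return(list(op = "var", id = g$gene))
  list(op = g$op, children = lapply(g$children, gpr_to_bool_node))
}

#' Read a plain-text regulatory rule file
#'
#' One rule per line, `target = <boolean expr>`; `#` starts a comment.
#' Environment signals are identifiers prefixed `env_`.
#'
#' @param path file path
#' @param regulators optional explicit TF id list; defaults to targets
#'   that are referenced by other rules or are not obvious metabolic genes
#' @return a `regulatory_network`
#' @export
read_regulatory_rules <- function(path, regulators = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rules <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed rule line (expected 'target = expr'): ", ln)
    rules[trimws(parts[1])] <- trimws(parts[2])
  }
  net0 <- regulatory_network(rules)
  if (is.null(regulators)) {
    referenced <- unique(unlist(lapply(net0$rules, bool_rule_vars)))
    regulators <- intersect(names(rules),
                            setdiff(referenced, net0$signals))
  }
  regulatory_network(rules, regulators = regulators)
}

#' Write a regulatory network as a plain-text rule file
#' @param net a `regulatory_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regulatory_rules <- function(net, path) {
  lines <- vapply(names(net$rules), function(tgt)
    paste(tgt, "=", bool_rule_unparse(net$rules[[tgt]])), "")
  writeLines(lines, path)
  invisible(path)
}

bool_rule_unparse <- function(node) {
  switch(node$op,
         var = node$id,
         const = if (node$value) "true" else "false",
         not = paste0("not ", {
           s <- bool_rule_unparse(node$children[[1]])
           if (node$children[[1]]$op %in% c("and", "or"))
             paste0("(", s, ")") else s
         }),
         and = paste(vapply(node$children, function(ch) {
           s <- bool_rule_unparse(ch)
           if (ch$op == "or") paste0("(", s, ")") else s
         }, ""), collapse = " and "),
         or = paste(vapply(node$children, bool_rule_unparse, ""),
                    collapse = " or "))
}
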