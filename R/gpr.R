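# GPR (gene-protein-reaction) rules: parsing, Boolean evaluation for
# knockouts, algebraic evaluation for expression levels, and translation
# of reaction-level expression folds into flux bounds.
#
# Grammar (EBNF):
#   expr    := term { OR term }
#   term    := factor { AND factor }
#   factor  := GENE | "(" expr ")"
#   AND     := "and" | "AND" | "&" | "&&"
#   OR      := "or"  | "OR"  | "|" | "||"
# "and" binds tighter than "or"; operators are case-insensitive.

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|&&|\\|\\||&|\\||[^()&|[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(rule, gregexpr(pat, rule))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_node <- function(op, children) {
  # flatten nested nodes of the same operator: a and b and c -> And(a,b,c)
  flat <- list()
  for (ch in children) {
    if (is.list(ch) && identical(ch$op, op)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  list(op = op, children = flat)
}

#' Parse a GPR rule string into an expression tree
#'
#' Accepts gene identifiers combined with `and`/`AND`/`&` and
#' `or`/`OR`/`|` plus parentheses; `and` binds tighter than `or`.
#'
#' @param rule GPR rule string, e.g. `"g3 or (g1 and g4)"`.
#' @return a `gpr` object: nested list of nodes `list(op, children)` with
#'   leaves `list(op = "gene", gene = id)`; the original string is kept in
#'   attribute `string`.
#' @export
parse_gpr <- function(rule) {
  if (!is.character(rule) || length(rule) != 1 || !nzchar(trimws(rule)))
    stop("empty GPR rule")
  toks <- gpr_tokenize(rule)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(rule) + 1L
  is_and <- function(t) !is.na(t) && tolower(t) %in% c("and", "&", "&&")
  is_or <- function(t) !is.na(t) && tolower(t) %in% c("or", "|", "||")

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error at position ", pos(),
                       ": unexpected end of rule")
    if (t == "(") {
      open_at <- pos()
      i <<- i + 1L
      node <- parse_expr()
      if (!identical(peek(), ")"))
        stop("GPR parse error at position ", open_at,
             ": unbalanced parenthesis")
      i <<- i + 1L
      return(node)
    }
    if (t == ")" || is_and(t) || is_or(t))
      stop("GPR parse error at position ", pos(), ": unexpected '", t, "'")
    i <<- i + 1L
    list(op = "gene", gene = t)
  }
  parse_term <- function() {
    node <- parse_factor()
    kids <- list(node)
    while (is_and(peek())) {
      i <<- i + 1L
      kids <- c(kids, list(parse_factor()))
    }
    if (length(kids) == 1) kids[[1]] else gpr_node("and", kids)
  }
  parse_expr <- function() {
    node <- parse_term()
    kids <- list(node)
    while (is_or(peek())) {
      i <<- i + 1L
      kids <- c(kids, list(parse_term()))
    }
    if (length(kids) == 1) kids[[1]] else gpr_node("or", kids)
  }

  tree <- parse_expr()
  if (i <= n)
    stop("GPR parse error at position ", pos(), ": unexpected '", peek(), "'")
  structure(tree, class = "gpr", string = rule)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_unparse(x), "\n", sep = "")
  invisible(x)
}

#' Render a GPR expression tree back to a canonical rule string
#' @param expr a `gpr` object or node
#' @return character string
#' @export
gpr_unparse <- function(expr) {
  if (expr$op == "gene") return(expr$gene)
  parts <- vapply(expr$children, function(ch) {
    s <- gpr_unparse(ch)
    if (ch$op != "gene" && ch$op != expr$op) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Genes referenced by a GPR expression
#' @param expr a `gpr` object
#' @return character vector of gene ids
#' @export
gpr_genes <- function(expr) {
  if (expr$op == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}

#' Evaluate a GPR rule as a Boolean under a set of gene deletions
#'
#' Deleted genes are FALSE, all others TRUE; `and` is conjunction, `or`
#' disjunction. A FALSE result means the catalysing reaction is disabled.
#'
#' @param expr a `gpr` object
#' @param deleted character vector of deleted gene ids
#' @return logical scalar
#' @export
eval_boolean <- function(expr, deleted = character()) {
  if (expr$op == "gene") return(!(expr$gene %in% deleted))
  vals <- vapply(expr$children, eval_boolean, NA, deleted = deleted)
  if (expr$op == "and") all(vals) else any(vals)
}

#' Evaluate a GPR rule algebraically under gene expression levels
#'
#' Gene identifiers are replaced by their expression folds (1 = wild type,
#' 0 = deleted) and the Boolean operators by associative reductions:
#' `and` -> `min`, `or` -> `max` by default; both are injectable (e.g.
#' `or_op = sum` to model additive isozyme contributions). Genes missing
#' from `levels` default to 1.
#'
#' @param expr a `gpr` object
#' @param levels named numeric vector or list of gene folds (>= 0)
#' @param and_op,or_op associative reduction functions
#' @return non-negative numeric scalar: the reaction-level fold
#' @export
eval_algebraic <- function(expr, levels = numeric(),
                           and_op = min, or_op = max) {
  levels <- unlist(levels)
  if (any(levels < 0)) stop("gene expression levels must be >= 0")
  rec <- function(node) {
    if (node$op == "gene") {
      lv <- levels[node$gene]
      return(if (is.null(lv) || is.na(lv)) 1 else as.numeric(lv))
    }
    vals <- vapply(node$children, rec, 0)
    if (node$op == "and") do.call(and_op, list(vals))
    else do.call(or_op, list(vals))
  }
  rec(expr)
}

#' Translate a reaction-level expression fold into flux bounds
#'
#' Encodes over-/under-expression relative to a wild-type reference flux
#' `w` by altering the reaction's bounds:
#' * fold 1: bounds unchanged;
#' * fold 0 (deletion): (0, 0);
#' * under-expression (fold < 1): flux capped at `fold * w` preserving the
#'   wild-type direction — `(0, fold*w)` for `w > 0`, `(fold*w, 0)` for
#'   `w < 0`, `(0, 0)` for `w = 0`;
#' * over-expression (fold > 1): the bound on the wild-type side is pushed
#'   to `fold * w`, clamped into the original range — `(min(fold*w, ub),
#'   ub)` for `w > 0`, `(lb, max(fold*w, lb))` for `w < 0`; a reaction
#'   unused in the wild type (`w = 0`) is left unchanged, as there is no
#'   direction along which to force flux.
#'
#' @param fold non-negative expression fold (gamma)
#' @param w wild-type reference flux of the reaction
#' @param lb,ub the reaction's current bounds
#' @return numeric `c(lb, ub)`
#' @export
reaction_fold_to_bounds <- function(fold, w, lb, ub) {
  if (fold < 0) stop("expression fold must be >= 0")
  stopifnot(lb <= ub)
  if (fold == 1) return(c(lb, ub))
  if (fold == 0) return(c(0, 0))
  if (fold < 1) {
    if (w > 0) return(c(0, fold * w))
    if (w < 0) return(c(fold * w, 0))
    return(c(0, 0))
  }
  # fold > 1
  if (w > 0) return(c(min(fold * w, ub), ub))
  if (w < 0) return(c(lb, max(fold * w, lb)))
  c(lb, ub)
}
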