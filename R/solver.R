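# Backend-agnostic linear / mixed-integer solver layer.
#
# A solver problem is a plain list:
#   n        number of variables
#   lb, ub   finite variable bounds (length n)
#   obj      linear objective coefficients (length n)
#   maximize logical
#   A        constraint matrix (m x n) or NULL
#   sense    character vector in {"=", "<=", ">="}
#   rhs      right-hand sides
#   binary   integer indices of 0/1 variables (MILP only)
#
# LPs are solved by a dense two-phase tableau simplex with Bland's
# anti-cycling rule after shifting variables to the nonnegative orthant
# (x = v - lb); all bounds are finite by construction (infinities are
# clamped at model load), so no LP here is unbounded. MILPs are solved
# by a deterministic depth-first branch-and-bound over the LP
# relaxation, adequate for the small binary counts that ROOM and srFBA
# generate on curated models.

FEAS_TOL <- 1e-6

solver_problem <- function(n, lb, ub, obj, maximize = TRUE,
                           A = NULL, sense = character(), rhs = numeric(),
                           binary = integer()) {
  stopifnot(length(lb) == n, length(ub) == n, length(obj) == n)
  if (!is.null(A)) stopifnot(ncol(A) == n, nrow(A) == length(rhs),
                             length(sense) == length(rhs))
  list(n = n, lb = lb, ub = ub, obj = obj, maximize = maximize,
       A = A, sense = sense, rhs = rhs, binary = binary)
}

lp_result <- function(status, objective = NA_real_, x = NULL) {
  list(status = status, objective = objective, x = x)
}

#' @keywords internal
solve_lp <- function(p) {
  if (any(p$lb > p$ub + FEAS_TOL)) return(lp_result("infeasible"))
  n <- p$n

  # presolve: variables pinned by equal bounds are substituted out (the
  # two-phase simplex degenerates on zero-width variables), and rows left
  # without free variables become pure feasibility checks
  fixed <- which(p$ub - p$lb <= FEAS_TOL)
  if (length(fixed)) {
    free <- setdiff(seq_len(n), fixed)
    xfix <- (p$lb[fixed] + p$ub[fixed]) / 2
    base_obj <- sum(p$obj[fixed] * xfix)
    A2 <- NULL; sense2 <- character(); rhs2 <- numeric()
    if (!is.null(p$A) && nrow(p$A) > 0) {
      rhs2 <- p$rhs - as.numeric(p$A[, fixed, drop = FALSE] %*% xfix)
      A2 <- p$A[, free, drop = FALSE]
      sense2 <- p$sense
      zero <- apply(abs(A2) <= 1e-12, 1, all)
      if (any(zero)) {
        viol <- (sense2[zero] == "=" & abs(rhs2[zero]) > FEAS_TOL) |
          (sense2[zero] == "<=" & rhs2[zero] < -FEAS_TOL) |
          (sense2[zero] == ">=" & rhs2[zero] > FEAS_TOL)
        if (any(viol)) return(lp_result("infeasible"))
        A2 <- A2[!zero, , drop = FALSE]
        sense2 <- sense2[!zero]
        rhs2 <- rhs2[!zero]
      }
      if (!nrow(A2)) { A2 <- NULL; sense2 <- character(); rhs2 <- numeric() }
    }
    if (!length(free)) {
      x <- numeric(n); x[fixed] <- xfix
      return(lp_result("optimal", base_obj, x))
    }
    sub <- solve_lp(list(n = length(free), lb = p$lb[free], ub = p$ub[free],
                         obj = p$obj[free], maximize = p$maximize,
                         A = A2, sense = sense2, rhs = rhs2))
    if (sub$status != "optimal") return(sub)
    x <- numeric(n)
    x[fixed] <- xfix
    x[free] <- sub$x
    return(lp_result("optimal", sub$objective + base_obj, x))
  }

  shift <- p$lb
  width <- p$ub - p$lb
  # constraints in shifted space: A x {sense} rhs - A %*% shift, x <= width
  A <- diag(n)
  sense <- rep("<=", n)
  rhs <- width
  if (!is.null(p$A) && nrow(p$A) > 0) {
    A <- rbind(A, p$A)
    sense <- c(sense, p$sense)
    rhs <- c(rhs, p$rhs - as.numeric(p$A %*% shift))
  }
  obj <- if (p$maximize) -p$obj else p$obj
  core <- simplex_two_phase(obj, A, sense, rhs)
  if (core$status != "optimal") return(lp_result(core$status))
  x <- core$x + shift
  lp_result("optimal", sum(p$obj * x), x)
}

# Dense two-phase tableau simplex with Bland's rule (minimization,
# x >= 0, mixed-sense rows). All problems fed to it are bounded by
# construction (every variable carries an explicit upper-bound row).
simplex_two_phase <- function(cc, A, sense, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }
  n_le <- sum(sense == "<=")
  n_ge <- sum(sense == ">=")
  n_art <- sum(sense != "<=")
  ncol_tot <- n + n_le + n_ge + n_art
  Tb <- matrix(0, m, ncol_tot + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, ncol_tot + 1L] <- b
  basis <- integer(m)
  js <- n; jg <- n + n_le; ja <- n + n_le + n_ge
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      js <- js + 1L; Tb[i, js] <- 1; basis[i] <- js
    } else {
      if (sense[i] == ">=") { jg <- jg + 1L; Tb[i, jg] <- -1 }
      ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja
      art_cols <- c(art_cols, ja)
    }
  }
  allowed <- rep(TRUE, ncol_tot)

  pivot <- function(zrow, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > 20000L) return(list(status = "error", zrow = zrow))
      enter <- which(allowed & zrow[seq_len(ncol_tot)] < -tol)
      if (!length(enter)) return(list(status = "optimal", zrow = zrow))
      j <- enter[1]                          # Bland: smallest index
      col <- Tb[, j]
      rows <- which(col > tol)
      if (!length(rows)) return(list(status = "unbounded", zrow = zrow))
      ratio <- Tb[rows, ncol_tot + 1L] / col[rows]
      rmin <- min(ratio)
      cand <- rows[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]      # Bland tie-break
      piv <- Tb[i, j]
      Tb[i, ] <<- Tb[i, ] / piv
      for (k in seq_len(m)) {
        if (k != i && abs(Tb[k, j]) > tol)
          Tb[k, ] <<- Tb[k, ] - Tb[k, j] * Tb[i, ]
      }
      zrow <- zrow - zrow[j] * Tb[i, ]
      basis[i] <<- j
    }
  }

  # phase 1: minimize sum of artificials
  if (length(art_cols)) {
    z1 <- numeric(ncol_tot + 1L)
    z1[art_cols] <- 1
    for (i in which(basis %in% art_cols)) z1 <- z1 - Tb[i, ]
    r1 <- pivot(z1, allowed)
    if (r1$status != "optimal") return(list(status = "error"))
    if (-r1$zrow[ncol_tot + 1L] > 1e-7) return(list(status = "infeasible"))
    allowed[art_cols] <- FALSE
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      j <- which(allowed & abs(Tb[i, seq_len(ncol_tot)]) > tol)
      if (length(j)) {
        j <- j[1]
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv
        for (k in seq_len(m)) {
          if (k != i && abs(Tb[k, j]) > tol)
            Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
        }
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)        # redundant row
      }
    }
    if (length(drop_rows)) {
      keep <- setdiff(seq_len(m), drop_rows)
      Tb <- Tb[keep, , drop = FALSE]
      basis <- basis[keep]
      m <- length(keep)
    }
  }

  # phase 2
  z2 <- numeric(ncol_tot + 1L)
  z2[seq_len(n)] <- cc
  for (i in seq_len(m)) {
    j <- basis[i]
    if (abs(z2[j]) > 0) z2 <- z2 - z2[j] * Tb[i, ]
  }
  r2 <- pivot(z2, allowed)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  if (r2$status != "optimal") return(list(status = "error"))
  x <- numeric(ncol_tot)
  x[basis] <- Tb[, ncol_tot + 1L]
  list(status = "optimal", x = x[seq_len(n)])
}

# deterministic DFS branch-and-bound on binary variables
#' @keywords internal
solve_milp <- function(p) {
  if (!length(p$binary)) return(solve_lp(p))
  best <- NULL
  best_obj <- if (p$maximize) -Inf else Inf
  better <- function(a, b) if (p$maximize) a > b + 1e-9 else a < b - 1e-9
  can_beat <- function(bound) {
    if (p$maximize) bound > best_obj + 1e-9 else bound < best_obj - 1e-9
  }
  recurse <- function(lb, ub) {
    rel <- solve_lp(modifyList(p, list(lb = lb, ub = ub)))
    if (rel$status != "optimal") return(invisible())
    if (!can_beat(rel$objective)) return(invisible())
    frac <- abs(rel$x[p$binary] - round(rel$x[p$binary]))
    if (all(frac <= 1e-6)) {
      if (better(rel$objective, best_obj) || is.null(best)) {
        best <<- rel
        best_obj <<- rel$objective
      }
      return(invisible())
    }
    j <- p$binary[which.max(frac)]
    lo <- lb; hi <- ub
    # branch down first for determinism
    hi0 <- hi; hi0[j] <- 0; lo0 <- lo; lo0[j] <- 0
    recurse(lo0, hi0)
    lo1 <- lo; lo1[j] <- 1; hi1 <- hi; hi1[j] <- 1
    recurse(lo1, hi1)
  }
  lb <- p$lb; ub <- p$ub
  lb[p$binary] <- pmax(lb[p$binary], 0)
  ub[p$binary] <- pmin(ub[p$binary], 1)
  recurse(lb, ub)
  if (is.null(best)) return(lp_result("infeasible"))
  best$x[p$binary] <- round(best$x[p$binary])
  best
}

# strictly convex QP: minimize 0.5 x'Dx - d'x under the problem's linear
# constraints and bounds (via quadprog); used by quadratic MOMA
#' @keywords internal
solve_qp <- function(p, D, d) {
  n <- p$n
  Amat <- NULL; bvec <- NULL; meq <- 0L
  if (!is.null(p$A) && nrow(p$A) > 0) {
    eqs <- which(p$sense == "=")
    les <- which(p$sense == "<=")
    ges <- which(p$sense == ">=")
    meq <- length(eqs)
    Amat <- rbind(p$A[eqs, , drop = FALSE],
                  p$A[ges, , drop = FALSE],
                  -p$A[les, , drop = FALSE])
    bvec <- c(p$rhs[eqs], p$rhs[ges], -p$rhs[les])
  }
  Amat <- rbind(Amat, diag(n), -diag(n))
  bvec <- c(bvec, p$lb, -p$ub)
  res <- tryCatch(
    quadprog::solve.QP(Dmat = D, dvec = d, Amat = t(Amat), bvec = bvec,
                       meq = meq),
    error = function(e) NULL)
  if (is.null(res)) return(lp_result("infeasible"))
  lp_result("optimal", res$value, as.numeric(res$solution))
}
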