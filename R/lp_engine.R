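#' Package-wide numerical options
#'
#' One zero tolerance is shared by every module: a quantity is reported
#' "zero" iff its absolute value is at most `zero_tol`.  The default 1e-9
#' is the same threshold used for blocked-reaction detection and for
#' lethality calls; the solver feasibility tolerance is kept an order of
#' magnitude tighter.
#'
#' @param zero_tol tolerance below which an LP optimum counts as zero.
#' @param feas_tol simplex pivot/feasibility tolerance (must be <= zero_tol/10).
#' @param lethal_tol strict threshold under which optimal growth counts as
#'   no growth.
#' @param healthy_fraction minimal fraction of healthy optimal growth a
#'   candidate complex must retain.
#' @param bound_cap finite flux bound substituted for infinite bounds.
#' @return a named list of options.
#' @export
bal_options <- function(zero_tol = 1e-9, feas_tol = 1e-10,
                        lethal_tol = 1e-9, healthy_fraction = 0.9,
                        bound_cap = 1000) {
  stopifnot(zero_tol > 0, feas_tol > 0, lethal_tol > 0,
            healthy_fraction >= 0, healthy_fraction <= 1, bound_cap > 0)
  if (feas_tol > zero_tol / 10)
    stop("feas_tol must be at most zero_tol/10")
  list(zero_tol = zero_tol, feas_tol = feas_tol, lethal_tol = lethal_tol,
       healthy_fraction = healthy_fraction, bound_cap = bound_cap)
}

#' Solve a bounded linear program
#'
#' Minimises or maximises `obj %*% v` subject to equality constraints
#' `eq_mat %*% v = eq_rhs` and box bounds `lb <= v <= ub`.  This is the
#' uniform LP contract used for balanced-complex detection, flux
#' variability analysis, concordance verification and flux balance
#' analysis.  The solver is a dense two-phase primal simplex on the
#' slack-augmented standard form; Dantzig pricing switches to Bland's rule
#' after a fixed number of iterations so termination is guaranteed on the
#' (highly degenerate) flux polytopes that arise here.
#'
#' All bounds must be finite: preprocessing caps them, so an unbounded
#' status is treated as a configuration error rather than a mathematical
#' outcome.
#'
#' @param obj objective coefficient vector (one entry per variable).
#' @param sense `"min"` or `"max"`.
#' @param eq_mat equality constraint matrix (k x n), or NULL.
#' @param eq_rhs right-hand side vector (length k).
#' @param lb,ub finite variable bounds.
#' @param opts options from [bal_options()].
#' @return a list with `status` ("optimal" or "infeasible"),
#'   `objective` (numeric, NA unless optimal) and `solution`
#'   (the optimal variable vector, NULL unless optimal).
#' @examples
#' solve_lp(c(1, 0), "max", matrix(c(1, -1), 1), 0, c(0, 0), c(10, 5))
#' @export
solve_lp <- function(obj, sense = c("min", "max"), eq_mat = NULL,
                     eq_rhs = NULL, lb, ub, opts = bal_options()) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("solve_lp requires finite bounds; cap infinite bounds first ",
         "(see bal_options()$bound_cap)")
  if (is.null(eq_mat)) {
    eq_mat <- matrix(0, 0, n); eq_rhs <- numeric(0)
  }
  eq_mat <- matrix(as.numeric(eq_mat), ncol = n)
  eq_rhs <- as.numeric(eq_rhs)
  stopifnot(nrow(eq_mat) == length(eq_rhs))
  if (any(ub - lb < -opts$feas_tol))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))

  cc <- if (sense == "max") -obj else obj
  res <- simplex_box(cc, eq_mat, eq_rhs, lb, pmax(ub, lb), opts$feas_tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, solution = NULL))
  list(status = "optimal",
       objective = sum(obj * res$x),
       solution = res$x)
}

# min cc'x s.t. E x = f, lb <= x <= ub (finite).  Shifts to y = x - lb,
# adds one slack per variable (y + s = ub - lb) and runs a two-phase
# tableau simplex in which the initial basis (artificials on equality
# rows, slacks on bound rows) is the identity.
simplex_box <- function(cc, E, f, lb, ub, tol) {
  n <- length(cc)
  m_eq <- nrow(E)
  u <- ub - lb
  b0 <- f - if (m_eq) as.vector(E %*% lb) else numeric(0)

  # rows: equalities then bound rows; columns: y (n), s (n)
  m <- m_eq + n
  A <- matrix(0, m, 2L * n)
  if (m_eq) A[seq_len(m_eq), seq_len(n)] <- E
  A[m_eq + seq_len(n), seq_len(n)] <- diag(n)
  A[m_eq + seq_len(n), n + seq_len(n)] <- diag(n)
  b <- c(b0, u)

  # make rhs non-negative so artificials start feasible
  neg <- which(b < 0)
  if (length(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  n_art <- m_eq
  Tb <- cbind(A, if (n_art) diag(m)[, seq_len(m_eq), drop = FALSE], b)
  nc <- 2L * n + n_art
  basis <- c(2L * n + seq_len(n_art), n + seq_len(n))  # artificials, slacks

  if (n_art) {
    cost1 <- c(rep(0, 2L * n), rep(1, n_art))
    ph1 <- simplex_iterate(Tb, basis, cost1, nc, tol)
    if (ph1$failed) stop("simplex: iteration limit reached in phase 1")
    Tb <- ph1$T; basis <- ph1$basis
    obj1 <- sum(cost1[basis] * Tb[, nc + 1L])
    if (obj1 > 1e-7) return(list(status = "infeasible"))
    # drive residual (degenerate) artificials out of the basis
    for (i in which(basis > 2L * n)) {
      piv <- which(abs(Tb[i, seq_len(2L * n)]) > tol)
      if (length(piv)) {
        Tb <- pivot_tableau(Tb, i, piv[1L]); basis[i] <- piv[1L]
      }
    }
    keep_rows <- basis <= 2L * n   # rows still led by an artificial are redundant
    Tb <- Tb[keep_rows, c(seq_len(2L * n), nc + 1L), drop = FALSE]
    basis <- basis[keep_rows]
    nc <- 2L * n
  }

  cost2 <- c(cc, rep(0, nc - n))
  ph2 <- simplex_iterate(Tb, basis, cost2, nc, tol)
  if (ph2$failed) stop("simplex: iteration limit reached in phase 2")
  if (ph2$unbounded) return(list(status = "unbounded"))
  Tb <- ph2$T; basis <- ph2$basis
  x <- numeric(nc)
  x[basis] <- Tb[, nc + 1L]
  y <- x[seq_len(n)]
  list(status = "optimal", x = y + lb)
}

# classic tableau iterations; Dantzig pricing, Bland's rule after
# `bland_after` iterations (anti-cycling), hard iteration cap.
simplex_iterate <- function(Tb, basis, cost, nc, tol) {
  m <- nrow(Tb)
  bland_after <- 4L * (m + nc)
  maxit <- 100L * (m + nc) + 2000L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxit)
      return(list(failed = TRUE))
    cb <- cost[basis]
    red <- cost[seq_len(nc)] -
      as.vector(crossprod(Tb[, seq_len(nc), drop = FALSE], cb))
    red[basis] <- 0
    cand <- which(red < -tol)
    if (!length(cand))
      return(list(T = Tb, basis = basis, failed = FALSE, unbounded = FALSE))
    enter <- if (iter > bland_after) cand[1L] else cand[which.min(red[cand])]
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(failed = FALSE, unbounded = TRUE))
    ratio <- Tb[pos, nc + 1L] / col[pos]
    best <- min(ratio)
    ties <- pos[ratio <= best + tol]
    leave <- ties[which.min(basis[ties])]   # Bland tie-break on leaving var
    Tb <- pivot_tableau(Tb, leave, enter)
    basis[leave] <- enter
  }
}

pivot_tableau <- function(Tb, i, j) {
  Tb[i, ] <- Tb[i, ] / Tb[i, j]
  other <- setdiff(seq_len(nrow(Tb)), i)
  Tb[other, ] <- Tb[other, , drop = FALSE] -
    outer(Tb[other, j], Tb[i, ])
  Tb[, j] <- 0; Tb[i, j] <- 1
  Tb
}

# bounds with infinities capped for LP use
capped_bounds <- function(net, opts) {
  lb <- net$reactions$lb; ub <- net$reactions$ub
  lb[!is.finite(lb)] <- -opts$bound_cap
  ub[!is.finite(ub)] <- opts$bound_cap
  list(lb = lb, ub = ub)
}

# min/max of one linear functional over S (plus optional extra equalities)
optimize_over_S <- function(net, obj, sense, extra_eq = NULL,
                            extra_rhs = NULL, opts = bal_options()) {
  bnd <- capped_bounds(net, opts)
  E <- stoich_matrix(net)
  f <- rep(0, nrow(E))
  if (!is.null(extra_eq)) {
    extra_eq <- matrix(as.numeric(extra_eq), ncol = n_reactions(net))
    if (is.null(extra_rhs)) extra_rhs <- rep(0, nrow(extra_eq))
    E <- rbind(E, extra_eq)
    f <- c(f, extra_rhs)
  }
  solve_lp(obj, sense, E, f, bnd$lb, bnd$ub, opts)
}

#' Flux variability analysis
#'
#' Computes the minimal and maximal steady-state flux of each requested
#' reaction over the flux polytope \eqn{S}, optionally intersected with
#' extra equality constraints (e.g. a forced-balancing constraint
#' \eqn{A^{i:} v = 0}).
#'
#' @param net a `metabolic_network`.
#' @param reactions reaction ids or indices; default all.
#' @param extra_eq optional matrix of extra equality rows (k x n_reactions),
#'   right-hand sides `extra_rhs` (default zero).
#' @param extra_rhs right-hand sides for `extra_eq`.
#' @param opts options from [bal_options()].
#' @return data.frame with columns `id`, `min`, `max`.
#' @export
fva <- function(net, reactions = NULL, extra_eq = NULL, extra_rhs = NULL,
                opts = bal_options()) {
  idx <- if (is.null(reactions)) seq_len(n_reactions(net))
         else if (is.character(reactions)) match(reactions, net$reactions$id)
         else as.integer(reactions)
  if (anyNA(idx)) stop("unknown reaction id in fva()")
  out <- data.frame(id = net$reactions$id[idx],
                    min = rep(NA_real_, length(idx)),
                    max = rep(NA_real_, length(idx)),
                    stringsAsFactors = FALSE)
  if (!length(idx)) return(out)
  nr <- n_reactions(net)
  for (k in seq_along(idx)) {
    obj <- numeric(nr); obj[idx[k]] <- 1
    lo <- optimize_over_S(net, obj, "min", extra_eq, extra_rhs, opts)
    if (lo$status != "optimal")
      stop("fva: flux space infeasible (no steady state satisfies the bounds)")
    hi <- optimize_over_S(net, obj, "max", extra_eq, extra_rhs, opts)
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}
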