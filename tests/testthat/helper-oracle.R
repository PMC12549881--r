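# Brute-force oracle, independent of the LP engine: enumerate all vertices
# of the bounded polytope {v | Nv = 0, lb <= v <= ub} by fixing every
# subset of n - rank(N) coordinates at a bound and solving the remaining
# square system.  A linear functional is zero on the polytope iff it is
# zero at every vertex, so balancedness and concordance can be decided by
# inspection of the vertex set.

enumerate_vertices <- function(net, tol = 1e-7) {
  N <- stoich_matrix(net)
  n <- ncol(N)
  lb <- net$reactions$lb; ub <- net$reactions$ub
  r <- qr(N)$rank
  nf <- n - r
  verts <- list()
  push <- function(v) verts[[length(verts) + 1L]] <<- v
  if (nf == 0L) {
    v <- rep(0, n)
    if (all(v >= lb - tol & v <= ub + tol)) push(v)
  } else {
    combs <- utils::combn(n, nf)
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), nf)))
    for (ci in seq_len(ncol(combs))) {
      F <- combs[, ci]
      M <- N[, -F, drop = FALSE]
      qrM <- qr(M)
      if (qrM$rank < r) next            # fixed set does not define a vertex
      vals <- matrix(lb[F], nf, nrow(grid)) +
        t(grid) * (ub[F] - lb[F])
      rhs <- -N[, F, drop = FALSE] %*% vals
      sol <- qr.coef(qrM, rhs)
      sol[is.na(sol)] <- 0
      resid <- M %*% sol - rhs
      for (g in seq_len(ncol(sol))) {
        if (max(abs(resid[, g])) > tol) next
        v <- numeric(n); v[F] <- vals[, g]; v[-F] <- sol[, g]
        if (all(v >= lb - tol & v <= ub + tol)) push(v)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V / 1e-6)), , drop = FALSE]
}

# balanced iff activity is zero at every vertex
oracle_balanced <- function(net, dec, vertices, tol = 1e-6) {
  acts <- vertices %*% t(dec$A)
  apply(abs(acts) <= tol, 2L, all)
}

# concordant iff the activities are proportional over all vertices with a
# common nonzero ratio
oracle_concordant <- function(dec, i, j, vertices, tol = 1e-6) {
  ai <- as.vector(vertices %*% dec$A[i, ])
  aj <- as.vector(vertices %*% dec$A[j, ])
  k <- which.max(abs(ai))
  if (abs(ai[k]) <= tol) return(list(concordant = FALSE, gamma = NA_real_))
  gamma <- aj[k] / ai[k]
  ok <- abs(gamma) > tol && all(abs(aj - gamma * ai) <= tol * (1 + abs(gamma)))
  list(concordant = ok, gamma = if (ok) gamma else NA_real_)
}

# two-sided Fisher p by direct hypergeometric summation: probability of
# all tables (fixed margins) whose probability does not exceed the
# observed one
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
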