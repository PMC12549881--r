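#' Trivially balanced complexes
#'
#' A complex is trivially balanced if it includes a species that appears
#' in no other complex: the steady-state balance of that species then
#' forces the complex activity to zero.  The zero complex (empty
#' composition) is never trivially balanced.
#'
#' @param dec a `complex_decomposition`.
#' @return integer vector of complex indices.
#' @export
find_trivially_balanced <- function(dec) {
  lone <- which(rowSums(dec$Y > 0) == 1L)       # species in a single complex
  if (!length(lone)) return(integer(0))
  sort(unique(unlist(lapply(lone, function(s) which(dec$Y[s, ] > 0)))))
}

#' Detect balanced complexes by linear programming
#'
#' Complex \eqn{C_j} is balanced iff both the minimum and the maximum of
#' its activity \eqn{A^{j:} v} over the flux polytope \eqn{S} (optionally
#' intersected with extra equality constraints, e.g. a forced-balancing
#' constraint) are zero, decided with the shared zero tolerance.  For each
#' non-balanced complex an LP solution with nonzero activity is retained
#' as a witness; witnesses certify non-balancedness and seed the candidate
#' coupling coefficients of the concordance partition.
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param extra_eq optional extra equality rows over reactions (k x n),
#'   with zero right-hand sides.
#' @param subset optional complex indices to evaluate (default all).
#' @param opts options from [bal_options()].
#' @return data.frame (complex, label, balanced, trivially_balanced,
#'   act_min, act_max) with a `witnesses` attribute: a list holding, for
#'   each evaluated complex, a flux vector of nonzero activity or NULL.
#' @export
find_balanced <- function(net, dec, extra_eq = NULL, subset = NULL,
                          opts = bal_options()) {
  idx <- if (is.null(subset)) seq_len(n_complexes(dec)) else as.integer(subset)
  triv <- find_trivially_balanced(dec)
  out <- data.frame(complex = idx, label = dec$labels[idx],
                    balanced = NA, trivially_balanced = idx %in% triv,
                    act_min = NA_real_, act_max = NA_real_,
                    stringsAsFactors = FALSE)
  witnesses <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    row <- dec$A[idx[k], ]
    lo <- optimize_over_S(net, row, "min", extra_eq, opts = opts)
    if (lo$status != "optimal")
      stop("find_balanced: flux space infeasible")
    hi <- optimize_over_S(net, row, "max", extra_eq, opts = opts)
    out$act_min[k] <- lo$objective
    out$act_max[k] <- hi$objective
    out$balanced[k] <- abs(lo$objective) <= opts$zero_tol &&
      abs(hi$objective) <= opts$zero_tol
    if (!out$balanced[k])
      witnesses[[k]] <- if (abs(hi$objective) >= abs(lo$objective))
        hi$solution else lo$solution
  }
  attr(out, "witnesses") <- witnesses
  out
}

#' Force the balancing of one complex
#'
#' Imposes the equality \eqn{A^{i:} v = 0} on the flux polytope and
#' determines \eqn{Q_i}: the set of previously non-balanced complexes
#' (other than \eqn{C_i}) that become balanced.  Each member is
#' classified: *trivial* if it is concordant with \eqn{C_i} (shares its
#' concordance module — its balancing is implied by the coupling);
#' otherwise *type I* if every reaction incident on it is blocked under
#' the constraint, or *type II* if some incoming and some outgoing
#' reactions still carry flux.  The balancing potential of \eqn{C_i} is
#' \eqn{|Q_i|}.
#'
#' Because concordance is inherited by subsets of \eqn{S}, membership of
#' \eqn{Q_i} is uniform within each concordance module, so only one
#' balance check per module is solved; the type classification is then
#' computed per member.
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param i index (or canonical label) of the complex to force.
#' @param partition a `concordance_partition` from [build_partition()].
#' @param statuses result of [find_balanced()] on the unconstrained
#'   polytope; recomputed when NULL.
#' @param opts options from [bal_options()].
#' @return an object of class `forced_balancing_result`: list with
#'   `source`, `source_label`, `Q` (integer indices), `classification`
#'   (named character vector over `Q`: "trivial", "nontrivial_type_I",
#'   "nontrivial_type_II") and `potential` (= `length(Q)`).
#' @export
force_balance <- function(net, dec, i, partition, statuses = NULL,
                          opts = bal_options()) {
  if (is.character(i)) i <- complex_index(dec, i)
  if (is.na(i)) stop("unknown complex")
  if (is.null(statuses)) statuses <- find_balanced(net, dec, opts = opts)
  non_bal <- statuses$complex[!statuses$balanced]
  res <- structure(list(source = i, source_label = dec$labels[i],
                        Q = integer(0),
                        classification = character(0), potential = 0L),
                   class = "forced_balancing_result")
  if (!i %in% non_bal) return(res)   # already balanced: empty Q

  constraint <- dec$A[i, , drop = FALSE]
  mod_i <- partition$module_of[i]
  Q <- integer(0); cls <- character(0)
  for (m in seq_along(partition$modules)) {
    members <- setdiff(partition$modules[[m]], i)
    if (!length(members)) next
    if (m == mod_i) {
      in_Q <- TRUE     # concordant complexes are balanced by implication
    } else {
      rep_j <- members[1L]
      st <- find_balanced(net, dec, extra_eq = constraint, subset = rep_j,
                          opts = opts)
      in_Q <- st$balanced[1L]
    }
    if (!in_Q) next
    for (j in members) {
      Q <- c(Q, j)
      cls <- c(cls,
               if (m == mod_i) "trivial"
               else classify_member(net, dec, j, constraint, opts))
    }
  }
  ord <- order(Q)
  res$Q <- Q[ord]
  res$classification <- stats::setNames(cls[ord], dec$labels[Q[ord]])
  res$potential <- length(res$Q)
  res
}

# type I iff every reaction incident on complex j is blocked under the
# forcing constraint (FVA restricted to the incident reactions)
classify_member <- function(net, dec, j, constraint, opts) {
  incident <- which(dec$A[j, ] != 0)
  rng <- fva(net, incident, extra_eq = constraint, opts = opts)
  blocked <- pmax(abs(rng$min), abs(rng$max)) <= opts$zero_tol
  if (all(blocked)) "nontrivial_type_I" else "nontrivial_type_II"
}

#' @export
print.forced_balancing_result <- function(x, ...) {
  cat("forced balancing of", x$source_label, "- potential", x$potential, "\n")
  if (x$potential) {
    tab <- table(factor(x$classification,
                        c("trivial", "nontrivial_type_I", "nontrivial_type_II")))
    cat("  trivial:", tab[1], " type I:", tab[2], " type II:", tab[3], "\n")
  }
  invisible(x)
}

#' Balancing potential of every complex
#'
#' All complexes of a concordance module share one balancing potential, so
#' the forced-balancing computation is run once per module (on its
#' representative) and the value copied to the members; balanced complexes
#' have potential zero by definition.
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param partition a `concordance_partition`.
#' @param statuses optional [find_balanced()] result (recomputed if NULL).
#' @param opts options from [bal_options()].
#' @param details if TRUE, also return the per-representative
#'   `forced_balancing_result`s.
#' @return named integer vector of potentials over all complexes, or (with
#'   `details = TRUE`) a list with `potential` and `results`.
#' @export
balancing_potential_all <- function(net, dec, partition, statuses = NULL,
                                    opts = bal_options(), details = FALSE) {
  if (is.null(statuses)) statuses <- find_balanced(net, dec, opts = opts)
  pot <- stats::setNames(rep(0L, n_complexes(dec)), dec$labels)
  results <- vector("list", length(partition$modules))
  for (m in seq_along(partition$modules)) {
    r <- partition$representative[m]
    fb <- force_balance(net, dec, r, partition, statuses, opts)
    results[[m]] <- fb
    pot[partition$modules[[m]]] <- fb$potential
  }
  if (details) list(potential = pot, results = results) else pot
}

#' Summarise forced-balancing outcomes over a network
#'
#' Fractions, over the non-balanced complexes, of complexes that (i) have
#' a nonzero balancing potential, (ii) balance complexes outside their own
#' concordance module, and (iii) induce at least one type-II member.
#'
#' @param results list of `forced_balancing_result`, one per non-balanced
#'   complex (or per module representative — the fractions are identical
#'   because all three properties are module-uniform for (i) and defined
#'   per source for (ii)/(iii)).
#' @return list with `n`, `frac_nonzero_potential`,
#'   `frac_balance_outside_module`, `frac_induce_type_II` (fractions are
#'   `NA` when `results` is empty).
#' @export
classify_forced_summary <- function(results) {
  n <- length(results)
  if (!n)
    return(list(n = 0L, frac_nonzero_potential = NA_real_,
                frac_balance_outside_module = NA_real_,
                frac_induce_type_II = NA_real_))
  nz <- vapply(results, function(r) r$potential > 0, logical(1))
  outside <- vapply(results, function(r)
    any(r$classification != "trivial"), logical(1))
  t2 <- vapply(results, function(r)
    any(r$classification == "nontrivial_type_II"), logical(1))
  list(n = n,
       frac_nonzero_potential = mean(nz),
       frac_balance_outside_module = mean(outside),
       frac_induce_type_II = mean(t2))
}

#' Export balance status / forced-balancing tables as TSV
#'
#' @param x a [find_balanced()] data.frame or `forced_balancing_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_balance_tsv <- function(x, path) {
  if (inherits(x, "forced_balancing_result")) {
    x <- data.frame(source_label = x$source_label,
                    member_label = names(x$classification),
                    class = unname(x$classification),
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
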