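#' Test whether two complexes are concordant
#'
#' Complexes \eqn{C_i} and \eqn{C_j} are concordant when their activities
#' are coupled: there is a \eqn{\gamma \ne 0} with
#' \eqn{A^{j:} v = \gamma\, A^{i:} v} for every \eqn{v} in the flux
#' polytope \eqn{S}.  Because \eqn{S} contains \eqn{v = 0}, the ratio
#' cannot be probed by normalising the activity to 1; instead a candidate
#' \eqn{\gamma} is computed from a witness flux with nonzero activity of
#' \eqn{C_i} (the candidate is unique if coupling holds) and certified by
#' two LPs showing that \eqn{(A^{j:} - \gamma A^{i:}) v} has zero minimum
#' and maximum over \eqn{S}.
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param i,j complex indices (or canonical labels).
#' @param witness_i flux vector with `|complex_activity(dec, i, .)| >`
#'   `zero_tol` (a certificate that \eqn{C_i} is non-balanced).
#' @param opts options from [bal_options()].
#' @return list with `concordant` (logical) and `gamma` (the coupling
#'   coefficient with `A^{j:} v = gamma * A^{i:} v`, or NA).
#' @export
are_concordant <- function(net, dec, i, j, witness_i,
                           opts = bal_options()) {
  if (is.character(i)) i <- complex_index(dec, i)
  if (is.character(j)) j <- complex_index(dec, j)
  act_i <- complex_activity(dec, i, witness_i)
  if (abs(act_i) <= opts$zero_tol)
    stop("are_concordant: witness has zero activity for complex ", i)
  if (i == j) return(list(concordant = TRUE, gamma = 1))
  gamma <- complex_activity(dec, j, witness_i) / act_i
  if (abs(gamma) <= opts$zero_tol)
    return(list(concordant = FALSE, gamma = NA_real_))
  row <- dec$A[j, ] - gamma * dec$A[i, ]
  lo <- optimize_over_S(net, row, "min", opts = opts)
  hi <- optimize_over_S(net, row, "max", opts = opts)
  ok <- lo$status == "optimal" && hi$status == "optimal" &&
    abs(lo$objective) <= opts$zero_tol && abs(hi$objective) <= opts$zero_tol
  list(concordant = ok, gamma = if (ok) gamma else NA_real_)
}

#' Partition non-balanced complexes into concordance modules
#'
#' Concordance is an equivalence relation on the non-balanced complexes,
#' so each complex only needs to be tested against one representative per
#' existing module (transitivity); a module's representative is its
#' lowest complex index and every member stores its coupling coefficient
#' \eqn{\gamma} relative to the representative
#' (\eqn{A^{j:} v = \gamma_j A^{r:} v} on all of \eqn{S},
#' \eqn{\gamma_r = 1}).
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param statuses result of [find_balanced()] (carries the witnesses).
#' @param opts options from [bal_options()].
#' @return an object of class `concordance_partition`: list with
#'   `modules` (list of integer vectors), `representative` (per module),
#'   `module_of` (complex -> module id, NA for balanced complexes),
#'   `gamma` (complex -> coefficient vs its representative, NA for
#'   balanced complexes) and `labels`.
#' @export
build_partition <- function(net, dec, statuses = NULL,
                            opts = bal_options()) {
  if (is.null(statuses)) statuses <- find_balanced(net, dec, opts = opts)
  wit <- attr(statuses, "witnesses")
  non_bal <- statuses$complex[!statuses$balanced]
  witness_of <- function(idx) wit[[match(idx, statuses$complex)]]

  modules <- list(); reps <- integer(0)
  module_of <- rep(NA_integer_, n_complexes(dec))
  gamma <- rep(NA_real_, n_complexes(dec))
  for (j in non_bal) {
    placed <- FALSE
    for (m in seq_along(modules)) {
      r <- reps[m]
      test <- are_concordant(net, dec, r, j, witness_of(r), opts)
      if (test$concordant) {
        modules[[m]] <- c(modules[[m]], j)
        module_of[j] <- m; gamma[j] <- test$gamma
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      modules[[length(modules) + 1L]] <- j
      reps <- c(reps, j)
      module_of[j] <- length(modules); gamma[j] <- 1
    }
  }
  structure(list(modules = modules, representative = reps,
                 module_of = module_of, gamma = gamma,
                 labels = dec$labels),
            class = "concordance_partition")
}

#' @export
print.concordance_partition <- function(x, ...) {
  cat("concordance_partition:", length(x$modules), "modules over",
      sum(!is.na(x$module_of)), "non-balanced complexes\n")
  for (m in seq_along(x$modules))
    cat(sprintf("  [%d] {%s}\n", m,
                paste(x$labels[x$modules[[m]]], collapse = ", ")))
  invisible(x)
}

#' Tabulate a concordance partition
#'
#' @param partition a `concordance_partition`.
#' @return data.frame (complex_label, module_id, gamma_vs_representative).
#' @export
partition_table <- function(partition) {
  keep <- which(!is.na(partition$module_of))
  data.frame(complex_label = partition$labels[keep],
             module_id = partition$module_of[keep],
             gamma_vs_representative = partition$gamma[keep],
             stringsAsFactors = FALSE)
}
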