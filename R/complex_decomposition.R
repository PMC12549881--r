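#' Decompose a network into complexes and the incidence graph
#'
#' The multiset of species on one side of a reaction is a *complex*; the
#' empty side of an exchange reaction is the *zero complex*.  The network
#' is then a directed graph whose nodes are the distinct complexes and
#' whose edges are the reactions, and the stoichiometric matrix factorises
#' as \eqn{N = Y A}: \eqn{Y} (species x complexes, non-negative) holds the
#' species composition of each complex and \eqn{A} (complexes x reactions)
#' is the graph incidence matrix, each column carrying exactly one -1
#' (substrate complex) and one +1 (product complex).
#'
#' Complex identity is decided on the canonical label: coefficients are
#' snapped to a 1e-9 grid (complexes are sensitive to stoichiometric
#' scaling, so upstream normalisation conventions matter), sorted by
#' species id and joined as `"coef*species"`; the zero complex is `"0"`.
#'
#' @param net a preprocessed (irreversible) `metabolic_network`.
#' @return an object of class `complex_decomposition` with fields
#'   `labels`, `compositions` (list of named coefficient vectors), `Y`,
#'   `A`, `substrate_of`, `product_of` (reaction -> complex index).
#' @examples
#' net <- toy_fig1()
#' dec <- build_decomposition(net)
#' length(dec$labels)           # 14 complexes
#' all(dec$Y %*% dec$A == stoich_matrix(net))
#' @export
build_decomposition <- function(net) {
  N <- stoich_matrix(net)
  nr <- ncol(N)
  labels <- character(0)
  compositions <- list()
  substrate_of <- integer(nr)
  product_of <- integer(nr)

  intern <- function(comp) {
    lab <- complex_label(comp)
    k <- match(lab, labels)
    if (is.na(k)) {
      labels[length(labels) + 1L] <<- lab
      compositions[[length(labels)]] <<- comp
      k <- length(labels)
    }
    k
  }

  for (j in seq_len(nr)) {
    col <- stats::setNames(N[, j], rownames(N))  # 1-row matrices drop names
    sub <- -col[col < 0]
    pro <- col[col > 0]
    substrate_of[j] <- intern(sub)
    product_of[j] <- intern(pro)
    if (substrate_of[j] == product_of[j])
      stop("reaction '", colnames(N)[j],
           "' has identical substrate and product complexes")
  }

  ncx <- length(labels)
  Y <- matrix(0, nrow(N), ncx, dimnames = list(rownames(N), labels))
  for (k in seq_len(ncx)) {
    comp <- compositions[[k]]
    if (length(comp)) Y[names(comp), k] <- comp
  }
  A <- matrix(0, ncx, nr, dimnames = list(labels, colnames(N)))
  A[cbind(substrate_of, seq_len(nr))] <- -1
  A[cbind(product_of, seq_len(nr))] <- 1

  structure(
    list(labels = labels, compositions = compositions, Y = Y, A = A,
         substrate_of = substrate_of, product_of = product_of),
    class = "complex_decomposition")
}

#' @export
print.complex_decomposition <- function(x, ...) {
  cat("complex_decomposition:", length(x$labels), "complexes,",
      ncol(x$A), "reactions\n")
  invisible(x)
}

#' Number of complexes in a decomposition
#' @param dec a `complex_decomposition`.
#' @export
n_complexes <- function(dec) length(dec$labels)

# canonical "coef*species + ..." label; "0" for the zero complex
complex_label <- function(comp) {
  if (!length(comp)) return("0")
  comp <- comp[order(names(comp))]
  paste(paste0(format_coef(comp), "*", names(comp)), collapse = " + ")
}

format_coef <- function(x) {
  x <- round(x / 1e-9) * 1e-9
  ifelse(abs(x - round(x)) < 1e-9,
         format(round(x), scientific = FALSE, trim = TRUE),
         format(x, digits = 10, scientific = FALSE, trim = TRUE))
}

#' Look up a complex index by label
#'
#' @param dec a `complex_decomposition`.
#' @param label canonical label(s), e.g. `"1*Oaa"` or `"0"`.
#' @return integer index vector (NA where absent).
#' @export
complex_index <- function(dec, label) match(label, dec$labels)

#' Activity of a complex under a flux distribution
#'
#' The activity of complex \eqn{C_i} is \eqn{A^{i:} v}: the sum of fluxes
#' of its incoming reactions minus the sum of fluxes of its outgoing
#' reactions.  A complex is balanced iff its activity is zero on all of
#' the flux polytope.
#'
#' @param dec a `complex_decomposition`.
#' @param i complex index (or canonical label).
#' @param v flux vector, one entry per reaction.
#' @return numeric activity.
#' @export
complex_activity <- function(dec, i, v) {
  if (is.character(i)) i <- complex_index(dec, i)
  if (is.na(i) || i < 1 || i > n_complexes(dec)) stop("unknown complex")
  if (length(v) != ncol(dec$A))
    stop("flux vector length ", length(v), " != ", ncol(dec$A), " reactions")
  sum(dec$A[i, ] * v)
}

#' Sink and source complexes
#'
#' A sink has only incoming reactions (no -1 in its incidence row), a
#' source only outgoing ones.  In a network without blocked reactions
#' such complexes cannot be balanced.
#'
#' @param dec a `complex_decomposition`.
#' @return list with integer index vectors `sinks` and `sources`.
#' @export
sinks_and_sources <- function(dec) {
  has_out <- apply(dec$A, 1L, function(r) any(r < 0))
  has_in <- apply(dec$A, 1L, function(r) any(r > 0))
  list(sinks = which(!has_out), sources = which(!has_in))
}

#' Tabulate a decomposition
#'
#' @param dec a `complex_decomposition`.
#' @return data.frame (complex_id, label, n_species).
#' @export
decomposition_table <- function(dec) {
  data.frame(complex_id = seq_along(dec$labels),
             label = dec$labels,
             n_species = vapply(dec$compositions, length, integer(1)),
             stringsAsFactors = FALSE)
}

#' Incidence graph edge list
#'
#' @param dec a `complex_decomposition`.
#' @return data.frame (reaction_id, substrate_complex, product_complex).
#' @export
incidence_edges <- function(dec) {
  data.frame(reaction_id = colnames(dec$A),
             substrate_complex = dec$labels[dec$substrate_of],
             product_complex = dec$labels[dec$product_of],
             stringsAsFactors = FALSE)
}
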