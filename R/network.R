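#' Construct a metabolic network
#'
#' A `metabolic_network` holds the stoichiometric model on which all
#' downstream analyses operate: the species, the reactions with their flux
#' bounds and reversibility flags, and the signed stoichiometric matrix
#' \eqn{N} (species x reactions).  The steady-state flux polytope
#' \deqn{S = \{ v \mid N v = 0,\; v_{\min} \le v \le v_{\max} \}}
#' defined by this object is the single source of truth for every linear
#' program solved by the package.
#'
#' Substrate and product coefficients of one reaction are net-cancelled
#' against each other when the matrix column is formed, so a species that
#' appears with equal coefficients on both sides of a reaction drops out of
#' both reaction sides.  Reaction sides (and hence complexes) are recovered
#' from the sign pattern of the matrix columns.
#'
#' @param species character vector of species ids, or a data.frame with
#'   columns `id` and optionally `name`, `compartment`.
#' @param reactions a list; each element a list with fields `id`,
#'   `substrates` (named numeric vector of positive coefficients, possibly
#'   empty), `products` (same), `lb`, `ub`, and optionally `reversible`
#'   (defaults to `lb < 0`).
#' @return an object of class `metabolic_network`.
#' @examples
#' net <- metabolic_network(
#'   species = c("A", "B"),
#'   reactions = list(
#'     list(id = "r1", substrates = c(A = 1), products = c(B = 1),
#'          lb = 0, ub = 10)
#'   )
#' )
#' stoich_matrix(net)
#' @export
metabolic_network <- function(species, reactions) {
  if (is.character(species)) {
    species <- data.frame(id = species, name = NA_character_,
                          compartment = NA_character_,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(species), "id" %in% names(species))
  if (!"name" %in% names(species)) species$name <- NA_character_
  if (!"compartment" %in% names(species)) species$compartment <- NA_character_
  if (anyDuplicated(species$id))
    stop("duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))

  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  n_s <- nrow(species)
  n_r <- length(reactions)
  N <- matrix(0, n_s, n_r, dimnames = list(species$id, rids))
  lb <- numeric(n_r); ub <- numeric(n_r); rev <- logical(n_r)
  for (j in seq_len(n_r)) {
    r <- reactions[[j]]
    for (side in c("substrates", "products")) {
      co <- r[[side]]
      if (length(co)) {
        co <- unlist(co)
        bad <- setdiff(names(co), species$id)
        if (length(bad))
          stop("reaction '", r$id, "' references undeclared species: ",
               paste(bad, collapse = ", "))
        if (any(co <= 0))
          stop("reaction '", r$id, "' has non-positive coefficients")
        sgn <- if (side == "substrates") -1 else 1
        N[names(co), j] <- N[names(co), j] + sgn * co
      }
    }
    if (all(N[, j] == 0))
      stop("reaction '", r$id, "' has empty net stoichiometry")
    lb[j] <- as.numeric(r$lb); ub[j] <- as.numeric(r$ub)
    if (lb[j] > ub[j])
      stop("reaction '", r$id, "': lower bound exceeds upper bound")
    rev[j] <- if (!is.null(r$reversible)) isTRUE(r$reversible) else lb[j] < 0
  }

  structure(
    list(species = species,
         reactions = data.frame(id = rids, lb = lb, ub = ub,
                                reversible = rev, stringsAsFactors = FALSE),
         stoich = N),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$species), "species,",
      nrow(x$reactions), "reactions",
      sprintf("(%d reversible, %d exchange)\n",
              sum(x$reactions$reversible), sum(exchange_reactions(x))))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param net a `metabolic_network`.
#' @return the signed species-by-reactions matrix \eqn{N}.
#' @export
stoich_matrix <- function(net) net$stoich

#' Number of species / reactions
#' @param net a `metabolic_network`.
#' @export
n_species <- function(net) nrow(net$species)

#' @rdname n_species
#' @export
n_reactions <- function(net) nrow(net$reactions)

#' Exchange reactions
#'
#' An exchange reaction has exactly one empty side: its stoichiometric
#' column is one-signed.  The empty side maps to the zero complex in the
#' incidence graph.
#'
#' @param net a `metabolic_network`.
#' @return logical vector over reactions.
#' @export
exchange_reactions <- function(net) {
  apply(net$stoich, 2L, function(col) all(col >= 0) || all(col <= 0))
}

#' Internal species
#'
#' A species is internal iff no exchange reaction touches it; only internal
#' species are eligible for [exchange_balancing()].
#'
#' @param net a `metabolic_network`.
#' @return character vector of internal species ids.
#' @export
internal_species <- function(net) {
  ex <- exchange_reactions(net)
  if (!any(ex)) return(net$species$id)
  touched <- rowSums(abs(net$stoich[, ex, drop = FALSE])) > 0
  net$species$id[!touched]
}

# substrate / product coefficient maps of one reaction (post-cancellation)
reaction_sides <- function(net, j) {
  col <- stats::setNames(net$stoich[, j], rownames(net$stoich))
  list(substrates = -col[col < 0], products = col[col > 0])
}
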