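#' Flux balance analysis
#'
#' Maximises the flux of a named biomass (or other objective) reaction
#' over the steady-state flux polytope, optionally intersected with extra
#' equality constraints such as a forced-balancing constraint
#' \eqn{A^{i:} v = 0}.  An infeasible constrained polytope is reported as
#' zero growth with `status = "infeasible"` rather than as an error.
#'
#' @param net a `metabolic_network`.
#' @param biomass_id objective reaction id.
#' @param extra_eq optional extra equality rows (k x n_reactions, rhs 0).
#' @param opts options from [bal_options()].
#' @return list with `objective` (optimal flux; 0 when infeasible),
#'   `status` and `solution`.
#' @export
fba <- function(net, biomass_id, extra_eq = NULL, opts = bal_options()) {
  j <- match(biomass_id, net$reactions$id)
  if (is.na(j))
    stop("biomass reaction '", biomass_id, "' not in model; valid ids: ",
         paste(utils::head(net$reactions$id, 20), collapse = ", "),
         if (n_reactions(net) > 20) ", ...")
  obj <- numeric(n_reactions(net)); obj[j] <- 1
  res <- optimize_over_S(net, obj, "max", extra_eq, opts = opts)
  if (res$status != "optimal")
    return(list(objective = 0, status = res$status, solution = NULL))
  res
}

#' Forced-balancing lethality screen
#'
#' Computes the optimal growth \eqn{z} of a model and, for every
#' non-balanced complex \eqn{C_i}, the optimal growth \eqn{z_i^*} under
#' the forced-balancing constraint \eqn{A^{i:} v = 0}.  Forcing a
#' balanced complex adds an implied constraint, so \eqn{z_i^* = z} for
#' those without solving.  Balancing is lethal iff
#' \eqn{z_i^* < } `lethal_tol` (strict).
#'
#' @param net a `metabolic_network`.
#' @param dec its `complex_decomposition`.
#' @param biomass_id objective reaction id.
#' @param statuses optional [find_balanced()] result (recomputed if NULL).
#' @param opts options from [bal_options()].
#' @return object of class `growth_result`: list with `biomass_id`, `z`,
#'   `z_star` (named over complex labels) and `lethal` (named logical).
#' @export
lethality_screen <- function(net, dec, biomass_id, statuses = NULL,
                             opts = bal_options()) {
  if (is.null(statuses)) statuses <- find_balanced(net, dec, opts = opts)
  z <- fba(net, biomass_id, opts = opts)$objective
  z_star <- stats::setNames(rep(z, n_complexes(dec)), dec$labels)
  for (i in statuses$complex[!statuses$balanced]) {
    z_star[i] <- fba(net, biomass_id,
                     extra_eq = dec$A[i, , drop = FALSE],
                     opts = opts)$objective
  }
  structure(list(biomass_id = biomass_id, z = z, z_star = z_star,
                 lethal = z_star < opts$lethal_tol),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("growth_result: z = %.6g; %d/%d complexes lethal when forced\n",
              x$z, sum(x$lethal), length(x$lethal)))
  invisible(x)
}

#' Differential candidate complexes between paired models
#'
#' A candidate complex is present (identical canonical composition) in
#' both models, lethal when forcedly balanced in the disease model, and
#' retains at least `healthy_fraction` of the healthy model's own optimal
#' growth when forcedly balanced there.
#'
#' @param disease,healthy `growth_result`s from [lethality_screen()] run
#'   on the two models of a pair (shared species namespace).
#' @param healthy_fraction minimal retained fraction of healthy optimal
#'   growth (default from `opts`).
#' @param opts options from [bal_options()].
#' @return object of class `screen_result`: data.frame with one row per
#'   shared complex (`complex_label`, `z_disease`, `z_star_disease`,
#'   `z_healthy`, `z_star_healthy`, `candidate`) and attribute
#'   `candidates` (labels).
#' @export
candidate_complexes <- function(disease, healthy, healthy_fraction = NULL,
                                opts = bal_options()) {
  if (is.null(healthy_fraction)) healthy_fraction <- opts$healthy_fraction
  stopifnot(healthy_fraction >= 0, healthy_fraction <= 1)
  shared <- intersect(names(disease$z_star), names(healthy$z_star))
  if (!length(shared))
    warning("no complexes shared between the paired models")
  out <- data.frame(
    complex_label = shared,
    z_disease = rep(disease$z, length(shared)),
    z_star_disease = unname(disease$z_star[shared]),
    z_healthy = rep(healthy$z, length(shared)),
    z_star_healthy = unname(healthy$z_star[shared]),
    stringsAsFactors = FALSE)
  out$candidate <- disease$lethal[shared] &
    out$z_star_healthy >= healthy_fraction * healthy$z
  structure(out, candidates = out$complex_label[out$candidate],
            class = c("screen_result", "data.frame"))
}

#' Essential reactions by single knockout
#'
#' A reaction (or forward/backward split pair, knocked out together and
#' counted once under the original id) is essential when constraining its
#' flux to zero drops the optimal growth below `lethal_tol`.
#'
#' @param net a `metabolic_network`.
#' @param biomass_id objective reaction id.
#' @param split_pairs optional map original-id -> c(forward, backward)
#'   from a `preprocessing_report`; members of a pair are knocked out
#'   jointly.
#' @param opts options from [bal_options()].
#' @return character vector of essential reaction ids.
#' @export
essential_reactions <- function(net, biomass_id, split_pairs = NULL,
                                opts = bal_options()) {
  ids <- net$reactions$id
  units <- as.list(ids); names(units) <- ids
  if (length(split_pairs)) {
    paired <- unlist(split_pairs, use.names = FALSE)
    units <- units[!names(units) %in% paired]
    for (orig in names(split_pairs)) units[[orig]] <- split_pairs[[orig]]
  }
  nr <- n_reactions(net)
  essential <- character(0)
  for (u in names(units)) {
    ko <- match(units[[u]], ids)
    ko <- ko[!is.na(ko)]
    if (!length(ko)) next
    eq <- matrix(0, length(ko), nr)
    eq[cbind(seq_along(ko), ko)] <- 1
    z <- fba(net, biomass_id, extra_eq = eq, opts = opts)$objective
    if (z < opts$lethal_tol) essential <- c(essential, u)
  }
  essential
}

#' Enrichment of essential reactions in concordance modules
#'
#' For each requested concordance module, the reactions incident on the
#' module's complexes are cross-tabulated against reaction essentiality
#' and tested with a two-sided Fisher exact test (the exact
#' hypergeometric test, independent of any LP solver).
#'
#' @param dec a `complex_decomposition`.
#' @param partition a `concordance_partition`.
#' @param essential character vector of essential reaction ids.
#' @param modules module ids to test (default all).
#' @return data.frame (`module_id`, `n_incident`,
#'   `n_incident_essential`, `p_value`; `p_value` is NA for an empty
#'   incident set).
#' @export
module_enrichment <- function(dec, partition, essential, modules = NULL) {
  if (is.null(modules)) modules <- seq_along(partition$modules)
  all_rx <- colnames(dec$A)
  ess <- all_rx %in% essential
  out <- data.frame(module_id = modules, n_incident = NA_integer_,
                    n_incident_essential = NA_integer_, p_value = NA_real_)
  for (k in seq_along(modules)) {
    cx <- partition$modules[[modules[k]]]
    inc <- colSums(abs(dec$A[cx, , drop = FALSE])) > 0
    out$n_incident[k] <- sum(inc)
    out$n_incident_essential[k] <- sum(inc & ess)
    if (!any(inc)) next
    tab <- matrix(c(sum(inc & ess), sum(inc & !ess),
                    sum(!inc & ess), sum(!inc & !ess)), 2)
    out$p_value[k] <- stats::fisher.test(tab)$p.value
  }
  out
}

#' Balance a complex by adding an exchange reaction
#'
#' Instead of imposing \eqn{A^{i:} v = 0} directly, a complex containing
#' an internal species can be balanced physiologically by giving that
#' species a (reversible, then split) exchange reaction — experimentally,
#' a transporter.  For sink or source complexes the result can differ
#' from direct forcing, because an exchange flux balances the activity
#' without blocking the reactions around the complex.
#'
#' @param net a `metabolic_network` (preprocessed, irreversible).
#' @param dec its `complex_decomposition`.
#' @param species_id an internal species (no existing exchange touches
#'   it).
#' @param target_complex canonical label of the complex whose balance
#'   status is re-evaluated in the modified model.
#' @param opts options from [bal_options()].
#' @return list with the modified `net`, its new decomposition `dec`,
#'   `balanced` (status of the target in the modified model) and the
#'   target's `status` row from [find_balanced()].
#' @export
exchange_balancing <- function(net, dec, species_id, target_complex,
                               opts = bal_options()) {
  if (!species_id %in% net$species$id)
    stop("unknown species '", species_id, "'")
  if (!species_id %in% internal_species(net))
    stop("species '", species_id, "' already has an exchange reaction")
  cap <- max(net$reactions$ub[is.finite(net$reactions$ub)], opts$bound_cap)
  rxs <- lapply(seq_len(n_reactions(net)), function(j) {
    sides <- reaction_sides(net, j)
    list(id = net$reactions$id[j], substrates = sides$substrates,
         products = sides$products, lb = net$reactions$lb[j],
         ub = net$reactions$ub[j],
         reversible = net$reactions$reversible[j])
  })
  ex_id <- paste0("EX_", species_id)
  rxs[[length(rxs) + 1L]] <- list(id = ex_id, substrates = NULL,
                                  products = stats::setNames(1, species_id),
                                  lb = -cap, ub = cap, reversible = TRUE)
  mod <- split_reversible(metabolic_network(net$species, rxs), opts)$net
  dec2 <- build_decomposition(mod)
  i <- complex_index(dec2, target_complex)
  if (is.na(i))
    stop("target complex '", target_complex, "' absent after modification")
  st <- find_balanced(mod, dec2, subset = i, opts = opts)
  list(net = mod, dec = dec2, balanced = st$balanced[1L], status = st)
}
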