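#' Read a metabolic model
#'
#' Supported dialects:
#' \describe{
#'   \item{`sbml`}{SBML Level 3 (core + FBC flux bounds), read-only.}
#'   \item{`simple-json`}{one JSON document: `species` (list of objects
#'     with `id`, optional `name`/`compartment`) and `reactions` (objects
#'     with `id`, `substrates`/`products` coefficient maps, `lb`, `ub`).
#'     Human-auditable and diff-able; the fixture format.}
#'   \item{`simple-tsv`}{long-format TSV with one stoichiometry row per
#'     (reaction, species): columns `reaction_id`, `species_id`,
#'     `coefficient` (negative = substrate), `lower_bound`,
#'     `upper_bound`.}
#' }
#' With `dialect = "auto"` the extension decides (`.xml`/`.sbml`,
#' `.json`, `.tsv`).
#'
#' Integer stoichiometries of the simple dialects are normalised to
#' smallest integer values (per-reaction division by the gcd) by default,
#' since complexes are sensitive to stoichiometric scaling and
#' cross-model comparisons need one convention; SBML models (float
#' coefficients, scaling fixed by the source reconstruction) are left
#' untouched by default.
#'
#' @param path model file.
#' @param dialect one of `"auto"`, `"sbml"`, `"simple-json"`,
#'   `"simple-tsv"`.
#' @param normalize divide integer reaction stoichiometries by their gcd;
#'   default ON for the simple dialects, OFF for SBML.
#' @return a `metabolic_network`.
#' @export
read_model <- function(path, dialect = c("auto", "sbml", "simple-json",
                                         "simple-tsv"),
                       normalize = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
                      xml = , sbml = "sbml",
                      json = "simple-json",
                      tsv = "simple-tsv",
                      stop("cannot infer dialect from extension '.", ext, "'"))
  }
  net <- switch(dialect,
                "sbml" = read_sbml(path),
                "simple-json" = read_simple_json(path),
                "simple-tsv" = read_simple_tsv(path))
  if (is.null(normalize)) normalize <- dialect != "sbml"
  if (normalize) net <- normalize_stoichiometry(net)
  net
}

read_simple_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("simple-json parse failure in '",
                                           path, "': ", conditionMessage(e)))
  if (is.null(doc$species) || is.null(doc$reactions))
    stop("simple-json model '", path, "' must have 'species' and 'reactions'")
  sp <- data.frame(
    id = vapply(doc$species, function(s) as.character(s$id), character(1)),
    name = vapply(doc$species, function(s)
      if (is.null(s$name)) NA_character_ else as.character(s$name), character(1)),
    compartment = vapply(doc$species, function(s)
      if (is.null(s$compartment)) NA_character_ else as.character(s$compartment),
      character(1)),
    stringsAsFactors = FALSE)
  rxs <- lapply(doc$reactions, function(r) {
    side <- function(x) if (is.null(x) || !length(x)) NULL else
      stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
    list(id = r$id, substrates = side(r$substrates),
         products = side(r$products),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         reversible = if (is.null(r$reversible)) NULL else isTRUE(r$reversible))
  })
  metabolic_network(sp, rxs)
}

read_simple_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("simple-tsv parse failure in '", path, "': ",
                             conditionMessage(e)))
  need <- c("reaction_id", "species_id", "coefficient",
            "lower_bound", "upper_bound")
  if (!all(need %in% names(tab)))
    stop("simple-tsv model '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  sp <- unique(tab$species_id)
  rids <- unique(tab$reaction_id)
  rxs <- lapply(rids, function(rid) {
    rows <- tab[tab$reaction_id == rid, ]
    if (length(unique(rows$lower_bound)) > 1 ||
        length(unique(rows$upper_bound)) > 1)
      stop("simple-tsv: inconsistent bounds for reaction '", rid, "'")
    co <- stats::setNames(rows$coefficient, rows$species_id)
    list(id = rid,
         substrates = -co[co < 0], products = co[co > 0],
         lb = rows$lower_bound[1], ub = rows$upper_bound[1])
  })
  metabolic_network(sp, rxs)
}

# SBML L3 core + fbc bounds; namespace-agnostic via xml2::xml_find_all on
# local-name() so level-2 style files also parse.
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  q <- function(node, xp) xml2::xml_find_all(node, xp)
  sp_nodes <- q(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp_nodes)) stop("SBML '", path, "': no species found")
  sp <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)

  params <- q(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- q(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) stop("SBML '", path, "': no reactions found")
  rxs <- lapply(rx_nodes, function(nd) {
    side <- function(listname) {
      refs <- q(nd, paste0("./*[local-name()='", listname,
                           "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(NULL)
      st <- xml2::xml_attr(refs, "stoichiometry")
      st[is.na(st)] <- "1"
      stats::setNames(as.numeric(st), xml2::xml_attr(refs, "species"))
    }
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    lb_ref <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (rev) -Inf else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else Inf
    list(id = xml2::xml_attr(nd, "id"),
         substrates = side("listOfReactants"),
         products = side("listOfProducts"),
         lb = lb, ub = ub, reversible = rev)
  })
  metabolic_network(sp, rxs)
}

#' Write a metabolic model
#'
#' Round-trips with [read_model()]: read-write-read is the identity on
#' species ids, reaction ids, bounds and the stoichiometric matrix.
#' Only the simple dialects are written.
#'
#' @param net a `metabolic_network`.
#' @param path output file.
#' @param dialect `"simple-json"` or `"simple-tsv"` (`"auto"`: from the
#'   extension).
#' @return the path, invisibly.
#' @export
write_model <- function(net, path,
                        dialect = c("auto", "simple-json", "simple-tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, json = "simple-json", tsv = "simple-tsv",
                      stop("cannot infer write dialect from '.", ext, "'"))
  }
  if (dialect == "simple-json") {
    doc <- list(
      species = lapply(seq_len(n_species(net)), function(i) {
        s <- net$species[i, ]
        out <- list(id = s$id)
        if (!is.na(s$name)) out$name <- s$name
        if (!is.na(s$compartment)) out$compartment <- s$compartment
        out
      }),
      reactions = lapply(seq_len(n_reactions(net)), function(j) {
        sides <- reaction_sides(net, j)
        list(id = net$reactions$id[j],
             substrates = as.list(sides$substrates),
             products = as.list(sides$products),
             lb = net$reactions$lb[j], ub = net$reactions$ub[j],
             reversible = net$reactions$reversible[j])
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(seq_len(n_reactions(net)), function(j) {
      col <- net$stoich[, j]
      nz <- which(col != 0)
      data.frame(reaction_id = net$reactions$id[j],
                 species_id = rownames(net$stoich)[nz],
                 coefficient = col[nz],
                 lower_bound = net$reactions$lb[j],
                 upper_bound = net$reactions$ub[j],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Normalise reaction stoichiometries to smallest integer values
#'
#' Divides each reaction column whose coefficients are all integral by
#' their greatest common divisor.  Complexes are sensitive to
#' stoichiometric scaling, so a consistent convention is required before
#' comparing complexes across models.
#'
#' @param net a `metabolic_network`.
#' @return the rescaled network.
#' @export
normalize_stoichiometry <- function(net) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  for (j in seq_len(n_reactions(net))) {
    co <- net$stoich[, j]
    nz <- abs(co[co != 0])
    if (all(abs(nz - round(nz)) < 1e-9)) {
      g <- Reduce(gcd2, round(nz))
      if (g > 1) net$stoich[, j] <- co / g
    }
  }
  net
}

#' Remove blocked reactions
#'
#' A reaction is blocked when it carries no flux in any steady state: its
#' FVA minimum and maximum are both below `epsilon` in absolute value.
#' Blocked reactions are detected on the model as given (original bounds,
#' capped to `opts$bound_cap` where infinite) and removed; species left
#' orphaned by the removals are dropped as well.
#'
#' @param net a `metabolic_network`.
#' @param epsilon blocked-flux threshold (default the shared 1e-9).
#' @param opts options from [bal_options()].
#' @return list with the pruned `net` and a `report`
#'   (`preprocessing_report`).
#' @export
remove_blocked <- function(net, epsilon = 1e-9, opts = bal_options()) {
  report <- new_report()
  if (epsilon > 0) {
    rng <- fva(net, opts = opts)   # errors if the flux space is infeasible
    blocked <- pmax(abs(rng$min), abs(rng$max)) < epsilon
    report$removed_blocked_reactions <- rng$id[blocked]
    if (any(blocked)) {
      keep <- !blocked
      net$stoich <- net$stoich[, keep, drop = FALSE]
      net$reactions <- net$reactions[keep, , drop = FALSE]
      rownames(net$reactions) <- NULL
      orphan <- rowSums(abs(net$stoich)) == 0
      if (any(orphan)) {
        net$stoich <- net$stoich[!orphan, , drop = FALSE]
        net$species <- net$species[!orphan, , drop = FALSE]
        rownames(net$species) <- NULL
      }
    }
  }
  list(net = net, report = report)
}

#' Split reversible reactions
#'
#' Every reversible reaction is replaced by a forward and a sign-flipped
#' backward irreversible copy.  Afterwards all lower bounds are zero and
#' every upper bound equals the maximum upper bound of the original model,
#' so the flux polytope is a bounded full box-constrained polytope whose
#' steady-state projection onto net fluxes equals that of the original
#' model.
#'
#' @param net a `metabolic_network`.
#' @param opts options from [bal_options()] (`bound_cap` replaces
#'   infinite upper bounds before the maximum is taken).
#' @return list with the split `net` and a `report` whose `split_pairs`
#'   maps original ids to the forward/backward copies and whose
#'   `bound_cap` is the common upper bound applied.
#' @export
split_reversible <- function(net, opts = bal_options()) {
  report <- new_report()
  ub <- net$reactions$ub
  ub[!is.finite(ub)] <- opts$bound_cap
  cap <- max(ub, opts$zero_tol)
  report$bound_cap <- cap

  rev <- which(net$reactions$reversible | net$reactions$lb < 0)
  sp <- net$species
  rxs <- list()
  for (j in seq_len(n_reactions(net))) {
    sides <- reaction_sides(net, j)
    id <- net$reactions$id[j]
    if (j %in% rev) {
      fwd <- paste0(id, "_fwd"); bwd <- paste0(id, "_bwd")
      rxs[[length(rxs) + 1L]] <- list(id = fwd, substrates = sides$substrates,
                                      products = sides$products,
                                      lb = 0, ub = cap, reversible = FALSE)
      rxs[[length(rxs) + 1L]] <- list(id = bwd, substrates = sides$products,
                                      products = sides$substrates,
                                      lb = 0, ub = cap, reversible = FALSE)
      report$split_pairs[[id]] <- c(fwd, bwd)
    } else {
      rxs[[length(rxs) + 1L]] <- list(id = id, substrates = sides$substrates,
                                      products = sides$products,
                                      lb = 0, ub = cap, reversible = FALSE)
    }
  }
  list(net = metabolic_network(sp, rxs), report = report)
}

#' Standard preprocessing pipeline
#'
#' Removes blocked reactions (FVA on the model as given) and then splits
#' reversible reactions, in that order.  The result is the canonical
#' input for the complex decomposition and all downstream LP analyses:
#' all reactions irreversible, all lower bounds zero, all upper bounds
#' equal, no blocked reactions.
#'
#' @param net a `metabolic_network`.
#' @param epsilon blocked threshold.
#' @param opts options from [bal_options()].
#' @return list with `net` and merged `report`.
#' @export
preprocess_model <- function(net, epsilon = 1e-9, opts = bal_options()) {
  s1 <- remove_blocked(net, epsilon, opts)
  s2 <- split_reversible(s1$net, opts)
  rep <- s2$report
  rep$removed_blocked_reactions <- s1$report$removed_blocked_reactions
  list(net = s2$net, report = rep)
}

new_report <- function() {
  structure(list(removed_blocked_reactions = character(0),
                 split_pairs = list(), bound_cap = NA_real_),
            class = "preprocessing_report")
}

#' @export
print.preprocessing_report <- function(x, ...) {
  cat("preprocessing_report:",
      length(x$removed_blocked_reactions), "blocked removed,",
      length(x$split_pairs), "reversible split, bound cap",
      x$bound_cap, "\n")
  invisible(x)
}

#' Write a preprocessing report as TSV
#'
#' @param report a `preprocessing_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  rows <- rbind(
    if (length(report$removed_blocked_reactions))
      data.frame(reaction_id = report$removed_blocked_reactions,
                 action = "removed_blocked", detail = "",
                 stringsAsFactors = FALSE),
    if (length(report$split_pairs))
      data.frame(reaction_id = names(report$split_pairs),
                 action = "split_reversible",
                 detail = vapply(report$split_pairs, paste, character(1),
                                 collapse = ","),
                 stringsAsFactors = FALSE))
  if (is.null(rows))
    rows <- data.frame(reaction_id = character(0), action = character(0),
                       detail = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
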