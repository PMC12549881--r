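#' The 18-reaction TCA/glyoxylate toy network
#'
#' A small carbon-metabolism network of 11 species and 18 irreversible
#' reactions (a TCA cycle with glyoxylate shunt, anaplerotic PEP entry and
#' two exchange reactions) whose complex decomposition has 14 complexes.
#' It is the package's worked example: 7 complexes are (trivially)
#' balanced, the non-balanced complexes fall into 3 concordance modules,
#' and forced balancing of `1*Oaa` has balancing potential 6 with one
#' type-II member.  Reversible steps (aconitase, succinate dehydrogenase,
#' fumarase, malate dehydrogenase) are encoded as explicit
#' forward/backward pairs; all bounds are (0, 1000).
#'
#' @return a `metabolic_network` with 11 species and 18 reactions.
#' @examples
#' net <- toy_fig1()
#' n_complexes(build_decomposition(net))
#' @export
toy_fig1 <- function() {
  sp <- c("AcCoa", "Cit", "Fum", "Gly", "Isocit", "Mal",
          "Oaa", "OG", "Pep", "Pyr", "Succ")
  rx <- function(id, subs, pros)
    list(id = id, substrates = subs, products = pros, lb = 0, ub = 1000)
  metabolic_network(sp, list(
    rx("r01", c(AcCoa = 1, Oaa = 1), c(Cit = 1)),
    rx("r02", c(Cit = 1), c(Isocit = 1)),
    rx("r03", c(Isocit = 1), c(Cit = 1)),
    rx("r04", c(Isocit = 1), c(OG = 1)),
    rx("r05", c(OG = 1), c(Succ = 1)),
    rx("r06", c(Succ = 1), c(Fum = 1)),
    rx("r07", c(Fum = 1), c(Succ = 1)),
    rx("r08", c(Fum = 1), c(Mal = 1)),
    rx("r09", c(Mal = 1), c(Fum = 1)),
    rx("r10", c(Mal = 1), c(Oaa = 1)),
    rx("r11", c(Oaa = 1), c(Mal = 1)),
    rx("r12", c(Isocit = 1), c(Succ = 1, Gly = 1)),
    rx("r13", c(AcCoa = 1, Gly = 1), c(Mal = 1)),
    rx("r14", c(Pep = 1), c(Oaa = 1)),
    rx("r15", c(Pep = 1), c(Pyr = 1)),
    rx("r16", c(Pyr = 1), c(AcCoa = 1)),
    rx("r17", NULL, c(Pep = 1)),
    rx("r18", c(Oaa = 1), NULL)
  ))
}

#' Random mass-balanced test network
#'
#' Generates a random irreversible network for property tests: a backbone
#' chain through the species (entered by one uptake exchange and, when
#' the reaction budget allows, drained by one export exchange) plus
#' random extra reactions whose sides are small random complexes.  With
#' `n_reactions >= n_species + 1` the network is connected through all
#' species.  Deterministic for a fixed seed.
#'
#' @param n_species number of species (>= 1).
#' @param n_reactions total number of reactions (>= 1).
#' @param seed RNG seed.
#' @param exchange_fraction fraction of the extra reactions made exchanges.
#' @param ub upper flux bound used for every reaction.
#' @return a `metabolic_network`.
#' @export
random_network <- function(n_species, n_reactions, seed = 1,
                           exchange_fraction = 0.2, ub = 10) {
  stopifnot(n_species >= 1, n_reactions >= 1)
  sp <- sprintf("M%02d", seq_len(n_species))
  rxs <- vector("list", n_reactions)
  withr_seed <- function(code) { # local RNG so callers' streams are untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    code
  }
  withr_seed({
    k <- 0L
    add <- function(subs, pros) {
      k <<- k + 1L
      rxs[[k]] <<- list(id = sprintf("v%03d", k), substrates = subs,
                        products = pros, lb = 0, ub = ub)
    }
    add(NULL, stats::setNames(1, sp[1]))                   # uptake
    i <- 1L
    while (k < min(n_reactions - 1L, n_species) && i < n_species) {
      add(stats::setNames(1, sp[i]), stats::setNames(1, sp[i + 1L]))
      i <- i + 1L
    }
    if (k < n_reactions) add(stats::setNames(1, sp[i]), NULL)  # export
    while (k < n_reactions) {
      if (stats::runif(1) < exchange_fraction) {
        s <- sample(sp, 1L)
        if (stats::runif(1) < 0.5) add(NULL, stats::setNames(1, s))
        else add(stats::setNames(1, s), NULL)
      } else {
        ns <- sample(1:2, 1L); np <- sample(1:2, 1L)
        subs <- sample(sp, ns); pros <- sample(setdiff(sp, subs),
                                               min(np, n_species - ns))
        if (!length(pros)) pros <- sample(setdiff(sp, subs[1]), 1L)
        add(stats::setNames(rep(1, length(subs)), subs),
            stats::setNames(rep(1, length(pros)), pros))
      }
    }
  })
  metabolic_network(sp, rxs)
}

#' Paired disease/healthy models with a planted differential complex
#'
#' Builds a pair of small growth models sharing a species namespace.  A
#' nutrient S feeds two branches: one produces the planted species P, the
#' other a cofactor Q; biomass precursor B is made by the condensation
#' P + Q -> B and drained by the biomass reaction.  The healthy model
#' additionally carries a bypass S -> B.  Forcing the activity of the
#' planted complex `1*P` (a sink complex fed only by S -> P) to zero
#' blocks the condensation, which severs the only biomass route in the
#' disease model but leaves the bypass route (and hence the full optimum)
#' available in the healthy model.  Chain lengths and reaction order are
#' randomised per seed; the planted invariants are verified by LP before
#' the pair is returned.
#'
#' @param seed RNG seed controlling decoration of the pair.
#' @param n_decoy number of extra decoy chain species appended (>= 0).
#' @param with_bypass whether the healthy model carries the rescuing
#'   bypass; `FALSE` yields an identical pair, whose planted invariants
#'   are unmeetable, and the generator refuses with an error.
#' @param opts options from [bal_options()].
#' @return list with elements `disease`, `healthy` (both
#'   `metabolic_network`), `answer` (planted complex label) and
#'   `biomass_id`.
#' @export
planted_pair <- function(seed = 1, n_decoy = 2, with_bypass = TRUE,
                         opts = bal_options()) {
  stopifnot(n_decoy >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  sp <- c("S", "P", "Q", "B")
  decoys <- if (n_decoy) sprintf("D%02d", seq_len(n_decoy)) else character(0)
  sp <- c(sp, decoys)
  ub <- 1000
  rx <- function(id, subs, pros)
    list(id = id, substrates = subs, products = pros, lb = 0, ub = ub)
  core <- list(
    rx("EX_S", NULL, c(S = 1)),
    rx("SP", c(S = 1), c(P = 1)),
    rx("SQ", c(S = 1), c(Q = 1)),
    rx("PQB", c(P = 1, Q = 1), c(B = 1)),
    rx("BIO", c(B = 1), NULL)
  )
  # decoy chain B -> D1 -> ... -> Dk -> (export); keeps the pair from being
  # a bare textbook diagram and varies with the seed
  extra <- list()
  if (n_decoy) {
    chain <- c("B", decoys)
    for (i in seq_len(n_decoy))
      extra[[i]] <- rx(sprintf("DC%02d", i),
                       stats::setNames(1, chain[i]),
                       stats::setNames(1, chain[i + 1L]))
    extra[[n_decoy + 1L]] <- rx("EX_D", stats::setNames(1, decoys[n_decoy]), NULL)
  }
  dis_rx <- c(core, extra)
  heal_rx <- if (with_bypass) c(dis_rx, list(rx("BYPASS", c(S = 1), c(B = 1))))
             else dis_rx
  perm <- sample(seq_along(dis_rx))
  disease <- metabolic_network(sp, dis_rx[perm])
  healthy <- metabolic_network(sp, heal_rx[sample(seq_along(heal_rx))])
  answer <- "1*P"

  # certify the planted invariants by LP before handing the pair out
  for (m in list(disease, healthy)) {
    dec <- build_decomposition(m)
    i <- complex_index(dec, answer)
    if (is.na(i)) stop("planted_pair: planted complex missing")
    st <- find_balanced(m, dec, opts = opts)
    if (st$balanced[i]) stop("planted_pair: planted complex is balanced")
  }
  z_d <- fba(disease, "BIO", opts = opts)
  z_h <- fba(healthy, "BIO", opts = opts)
  if (z_d$objective <= opts$lethal_tol || z_h$objective <= opts$lethal_tol)
    stop("planted_pair: base models do not grow")
  dec_d <- build_decomposition(disease)
  dec_h <- build_decomposition(healthy)
  zs_d <- fba(disease, "BIO",
              extra_eq = dec_d$A[complex_index(dec_d, answer), , drop = FALSE],
              opts = opts)
  zs_h <- fba(healthy, "BIO",
              extra_eq = dec_h$A[complex_index(dec_h, answer), , drop = FALSE],
              opts = opts)
  if (zs_d$objective >= opts$lethal_tol)
    stop("planted_pair: forcing the planted complex is not lethal in disease")
  if (zs_h$objective < opts$healthy_fraction * z_h$objective)
    stop("planted_pair: healthy model does not tolerate the forcing")

  list(disease = disease, healthy = healthy, answer = answer,
       biomass_id = "BIO")
}
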