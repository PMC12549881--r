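test_that("FBA maximises biomass and reports infeasibility as zero growth", {
  net <- pathway_net()
  expect_equal(fba(net, "bio")$objective, 10)
  # blocking the only precursor path abolishes growth
  blk <- matrix(0, 1, 3); blk[1, 2] <- 1
  expect_equal(fba(net, "bio", extra_eq = blk)$objective, 0)
  # NULL and zero-row constraint sets agree
  expect_equal(fba(net, "bio", extra_eq = matrix(0, 0, 3))$objective,
               fba(net, "bio")$objective)
  expect_error(fba(net, "nope"), "valid ids")
})

test_that("lethality screen forces each non-balanced complex once", {
  net <- pathway_net()
  dec <- build_decomposition(net)
  gr <- lethality_screen(net, dec, "bio")
  expect_equal(gr$z, 10)
  # balanced complexes keep the unconstrained optimum by construction
  st <- find_balanced(net, dec)
  for (lbl in st$label[st$balanced]) expect_equal(unname(gr$z_star[lbl]), 10)
  # z_i* never exceeds z
  expect_true(all(gr$z_star <= gr$z + 1e-7))
})

test_that("candidate calls combine disease lethality with healthy growth", {
  pp <- planted_pair(seed = 8)
  dd <- build_decomposition(pp$disease)
  dh <- build_decomposition(pp$healthy)
  gd <- lethality_screen(pp$disease, dd, pp$biomass_id)
  gh <- lethality_screen(pp$healthy, dh, pp$biomass_id)
  sc <- candidate_complexes(gd, gh)
  expect_true(pp$answer %in% attr(sc, "candidates"))
  # candidates are a subset of shared complexes, all satisfying both rules
  expect_true(all(sc$candidate == (gd$lethal[sc$complex_label] &
    sc$z_star_healthy >= 0.9 * gh$z)))

  # relaxing the healthy bound to zero admits every disease-lethal complex
  sc0 <- candidate_complexes(gd, gh, healthy_fraction = 0)
  expect_setequal(attr(sc0, "candidates"),
                  names(which(gd$lethal[sc0$complex_label])))

  # identical models yield no candidates
  sc_id <- candidate_complexes(gd, gd)
  expect_length(attr(sc_id, "candidates"), 0)
})

test_that("a pair with disjoint namespaces warns about no shared complexes", {
  g1 <- lethality_screen(pathway_net(), build_decomposition(pathway_net()),
                         "bio")
  net2 <- metabolic_network(c("X"), list(
    list(id = "in", substrates = NULL, products = c(X = 1), lb = 0, ub = 1),
    list(id = "bio", substrates = c(X = 1), products = NULL, lb = 0, ub = 1)))
  g2 <- lethality_screen(net2, build_decomposition(net2), "bio")
  # the zero complex is shared by any two models with exchanges, so drop it
  g2$z_star <- g2$z_star[names(g2$z_star) != "0"]
  g2$lethal <- g2$lethal[names(g2$lethal) != "0"]
  g1$z_star <- g1$z_star[names(g1$z_star) != "0"]
  g1$lethal <- g1$lethal[names(g1$lethal) != "0"]
  expect_warning(candidate_complexes(g1, g2), "no complexes shared")
})

test_that("essentiality by knockout marks exactly the load-bearing reactions", {
  expect_setequal(essential_reactions(pathway_net(), "bio"),
                  c("up", "ab", "bio"))
  expect_setequal(essential_reactions(parallel_net(), "bio"),
                  c("up", "bio"))   # neither parallel branch is essential

  # a split reversible pair is knocked out jointly and reported once
  net <- metabolic_network(c("A", "B"), list(
    list(id = "up", substrates = NULL, products = c(A = 1), lb = 0, ub = 10),
    list(id = "conv", substrates = c(A = 1), products = c(B = 1),
         lb = -10, ub = 10),
    list(id = "bio", substrates = c(B = 1), products = NULL, lb = 0, ub = 10)
  ))
  sp <- split_reversible(net)
  ess <- essential_reactions(sp$net, "bio", split_pairs = sp$report$split_pairs)
  expect_true("conv" %in% ess)
  expect_false(any(c("conv_fwd", "conv_bwd") %in% ess))
})

test_that("module enrichment equals the direct hypergeometric computation", {
  # scenario engineered so one module's incident reactions are 12 of 112,
  # 10 of them essential, against 5 essential among the 100 others
  dec <- list(labels = c("cx"), A = matrix(0, 1, 112))
  dec$A[1, 1:12] <- rep(c(-1, 1), 6)
  colnames(dec$A) <- sprintf("r%03d", 1:112)
  class(dec) <- "complex_decomposition"
  part <- structure(list(modules = list(1L)), class = "concordance_partition")
  essential <- c(sprintf("r%03d", 1:10), sprintf("r%03d", 13:17))
  enr <- module_enrichment(dec, part, essential)
  expect_equal(enr$n_incident, 12L)
  expect_equal(enr$n_incident_essential, 10L)
  expect_equal(enr$p_value, fisher_oracle(10, 2, 5, 95), tolerance = 1e-9)

  # no essential reactions anywhere -> p = 1 (zero margin)
  enr0 <- module_enrichment(dec, part, character(0))
  expect_equal(enr0$p_value, 1)
})

test_that("enrichment flags modules dense in essential reactions", {
  pp <- planted_pair(seed = 15, n_decoy = 4)
  dd <- build_decomposition(pp$disease)
  st <- find_balanced(pp$disease, dd)
  part <- build_partition(pp$disease, dd, st)
  ess <- essential_reactions(pp$disease, pp$biomass_id)
  enr <- module_enrichment(dd, part, ess)
  expect_true(all(is.na(enr$p_value) | (enr$p_value >= 0 & enr$p_value <= 1)))
})

test_that("exchange balancing modifies the model and re-evaluates the target", {
  net <- toy_fig1()
  dec <- build_decomposition(net)

  # an exchange for Gly lets the glyoxylate branch decouple; statuses are
  # recomputed on the modified model without error
  xb <- exchange_balancing(net, dec, "Gly", "1*Oaa")
  expect_true(paste0("EX_Gly", "_fwd") %in% xb$net$reactions$id ||
                "EX_Gly_fwd" %in% xb$net$reactions$id)
  expect_type(xb$balanced, "logical")

  # an exchange for a species outside the target's module cannot balance
  # a non-balanced target (adding reactions only enlarges the flux space)
  st <- find_balanced(net, dec)
  expect_false(st$balanced[complex_index(dec, "1*Succ")])
  xb2 <- exchange_balancing(net, dec, "Pyr", "1*Succ")
  expect_false(xb2$balanced)

  # species already exchanged -> precondition error
  expect_error(exchange_balancing(net, dec, "Pep", "1*Succ"),
               "already has an exchange")
  expect_error(exchange_balancing(net, dec, "Ghost", "1*Succ"), "unknown")
})
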