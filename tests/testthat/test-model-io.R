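test_that("simple-json models read, write and round-trip exactly", {
  tf <- tempfile(fileext = ".json")
  writeLines('{
    "species": [{"id": "A"}, {"id": "B"}],
    "reactions": [
      {"id": "r1", "substrates": {"A": 1}, "products": {"B": 1},
       "lb": 0, "ub": 10}
    ]
  }', tf)
  net <- read_model(tf)
  expect_equal(n_species(net), 2L)
  expect_equal(n_reactions(net), 1L)
  expect_equal(unname(stoich_matrix(net)[, 1]), c(-1, 1))

  net2 <- toy_fig1()
  out <- tempfile(fileext = ".json")
  write_model(net2, out)
  back <- read_model(out)
  expect_identical(stoich_matrix(back), stoich_matrix(net2))
  expect_equal(back$reactions$lb, net2$reactions$lb)
  expect_equal(back$reactions$ub, net2$reactions$ub)
})

test_that("the packaged toy fixture file matches the in-code fixture", {
  path <- system.file("extdata", "toy_fig1.json", package = "balcomplex")
  net <- read_model(path)
  expect_equal(n_species(net), 11L)
  expect_equal(n_reactions(net), 18L)
  expect_identical(stoich_matrix(net), stoich_matrix(toy_fig1()))
})

test_that("invalid models are rejected with informative errors", {
  tf <- tempfile(fileext = ".json")
  writeLines('{
    "species": [{"id": "A"}],
    "reactions": [{"id": "r1", "substrates": {"A": 1},
                   "products": {"GHOST": 1}, "lb": 0, "ub": 1}]
  }', tf)
  expect_error(read_model(tf), "undeclared species")

  tf2 <- tempfile(fileext = ".json")
  writeLines('{
    "species": [{"id": "A"}, {"id": "A"}],
    "reactions": [{"id": "r1", "substrates": {"A": 1}, "products": {},
                   "lb": 0, "ub": 1}]
  }', tf2)
  expect_error(read_model(tf2), "duplicate species")

  tf3 <- tempfile(fileext = ".json")
  writeLines("this is not json {", tf3)
  expect_error(read_model(tf3), "parse failure")
})

test_that("simple-tsv round-trips and rejects dialect mismatch", {
  net <- toy_fig1()
  out <- tempfile(fileext = ".tsv")
  write_model(net, out)
  back <- read_model(out)
  N0 <- stoich_matrix(net)
  N1 <- stoich_matrix(back)[rownames(N0), colnames(N0)]
  expect_equal(N1, N0)

  # one stoichiometry row per participating species
  tab <- read.delim(out)
  expect_equal(nrow(tab[tab$reaction_id == "r01", ]), 3L)  # AcCoa, Oaa, Cit

  json_file <- tempfile(fileext = ".json")
  write_model(net, json_file)
  expect_error(read_model(json_file, dialect = "simple-tsv"),
               "simple-tsv")
})

test_that("SBML level-3 FBC models read with bounds and stoichiometry", {
  path <- system.file("extdata", "mini_model.sbml.xml",
                      package = "balcomplex")
  net <- read_model(path)
  expect_equal(net$species$id, c("A", "B", "C"))
  expect_equal(net$reactions$id, c("EX_A", "R1", "R2", "EX_C"))
  # values cross-checked once against an independent SBML reader (cobrapy)
  expect_equal(net$reactions$lb, c(0, 0, -50, 0))
  expect_equal(net$reactions$ub, c(100, 100, 5, 100))
  expect_equal(unname(stoich_matrix(net)["A", ]), c(1, -2, 0, 0))
  expect_true(net$reactions$reversible[3])
  expect_equal(sum(exchange_reactions(net)), 2L)
})

test_that("blocked reactions are detected by FVA and removed", {
  # dead-end: B produced but never consumed and internal -> ab blocked
  net <- metabolic_network(c("A", "B"), list(
    list(id = "in", substrates = NULL, products = c(A = 1), lb = 0, ub = 10),
    list(id = "out", substrates = c(A = 1), products = NULL, lb = 0, ub = 10),
    list(id = "ab", substrates = c(A = 1), products = c(B = 1), lb = 0, ub = 10)
  ))
  res <- remove_blocked(net)
  expect_equal(res$report$removed_blocked_reactions, "ab")
  expect_equal(n_reactions(res$net), 2L)
  expect_false("B" %in% res$net$species$id)  # orphaned species dropped

  # the toy fixture is blocked-free
  res2 <- remove_blocked(toy_fig1())
  expect_length(res2$report$removed_blocked_reactions, 0)

  # epsilon = 0 removes nothing
  res3 <- remove_blocked(net, epsilon = 0)
  expect_equal(n_reactions(res3$net), 3L)
})

test_that("reversible splitting zeroes lower bounds and unifies upper bounds", {
  net <- metabolic_network(c("A", "B"), list(
    list(id = "r", substrates = c(A = 1), products = c(B = 1),
         lb = -10, ub = 10),
    list(id = "ea", substrates = NULL, products = c(A = 1), lb = 0, ub = 5),
    list(id = "eb", substrates = c(B = 1), products = NULL, lb = 0, ub = 1000)
  ))
  res <- split_reversible(net)
  expect_equal(n_reactions(res$net), 4L)
  expect_true(all(res$net$reactions$lb == 0))
  expect_true(all(res$net$reactions$ub == 1000))  # max of original uppers
  expect_equal(res$report$split_pairs$r, c("r_fwd", "r_bwd"))
  # backward copy is the sign flip of the forward copy
  N <- stoich_matrix(res$net)
  expect_equal(N[, "r_bwd"], -N[, "r_fwd"])

  # with already-uniform upper bounds, splitting preserves the optimal
  # steady-state throughput (the bound standardisation is then a no-op)
  net_u <- metabolic_network(c("A", "B"), list(
    list(id = "r", substrates = c(A = 1), products = c(B = 1),
         lb = -10, ub = 10),
    list(id = "ea", substrates = NULL, products = c(A = 1), lb = 0, ub = 10),
    list(id = "eb", substrates = c(B = 1), products = NULL, lb = 0, ub = 10)
  ))
  z0 <- fba(net_u, "eb")$objective
  z1 <- fba(split_reversible(net_u)$net, "eb")$objective
  expect_equal(z1, z0, tolerance = 1e-9)
})

test_that("preprocessing is idempotent", {
  net <- metabolic_network(c("A", "B"), list(
    list(id = "r", substrates = c(A = 1), products = c(B = 1),
         lb = -10, ub = 10),
    list(id = "ea", substrates = NULL, products = c(A = 1), lb = 0, ub = 5),
    list(id = "eb", substrates = c(B = 1), products = NULL, lb = 0, ub = 5),
    list(id = "dead", substrates = c(A = 1), products = NULL, lb = 0, ub = 0)
  ))
  once <- preprocess_model(net)
  twice <- preprocess_model(once$net)
  expect_identical(stoich_matrix(twice$net), stoich_matrix(once$net))
  expect_equal(twice$net$reactions$lb, once$net$reactions$lb)
  expect_length(twice$report$removed_blocked_reactions, 0)
  expect_length(twice$report$split_pairs, 0)
})

test_that("integer stoichiometries are normalised to smallest values", {
  net <- metabolic_network(c("A", "B"), list(
    list(id = "r", substrates = c(A = 4), products = c(B = 2), lb = 0, ub = 1)
  ))
  norm <- normalize_stoichiometry(net)
  expect_equal(unname(stoich_matrix(norm)[, 1]), c(-2, 1))
})

test_that("preprocessing report exports as TSV", {
  res <- preprocess_model(metabolic_network(c("A"), list(
    list(id = "r", substrates = NULL, products = c(A = 1), lb = -1, ub = 1),
    list(id = "e", substrates = c(A = 1), products = NULL, lb = 0, ub = 1)
  )))
  tf <- tempfile(fileext = ".tsv")
  write_report_tsv(res$report, tf)
  tab <- read.delim(tf)
  expect_true("split_reversible" %in% tab$action)
})
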