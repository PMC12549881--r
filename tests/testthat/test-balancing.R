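test_that("trivially balanced complexes are found structurally", {
  tp <- toy_pipeline()
  triv <- tp$dec$labels[find_trivially_balanced(tp$dec)]
  expect_setequal(triv, c("1*Mal", "1*Pyr", "1*Cit", "1*Isocit",
                          "1*OG", "1*Fum", "1*Pep"))

  # a multi-species complex with a lone species is trivially balanced
  net <- metabolic_network(c("A", "B", "C"), list(
    list(id = "r1", substrates = c(A = 1, B = 1), products = c(C = 1),
         lb = 0, ub = 1),
    list(id = "r2", substrates = c(C = 1), products = c(B = 1),
         lb = 0, ub = 1)
  ))
  dec <- build_decomposition(net)
  expect_true(complex_index(dec, "1*A + 1*B") %in%
                find_trivially_balanced(dec))

  # the zero complex has empty composition and is never trivially balanced
  dchain <- build_decomposition(chain_net())
  expect_false(complex_index(dchain, "0") %in%
                 find_trivially_balanced(dchain))
})

test_that("LP detection returns the toy's balanced set with witnesses", {
  tp <- toy_pipeline()
  st <- tp$st
  expect_setequal(st$label[st$balanced],
                  c("1*Mal", "1*Pyr", "1*Cit", "1*Isocit", "1*OG",
                    "1*Fum", "1*Pep"))
  expect_setequal(st$label[!st$balanced],
                  c("1*Oaa", "1*AcCoa + 1*Oaa", "0", "1*Succ",
                    "1*Gly + 1*Succ", "1*AcCoa + 1*Gly", "1*AcCoa"))
  # trivially balanced is a subset of balanced
  expect_true(all(st$balanced[st$trivially_balanced]))
  # witnesses certify non-balancedness
  wit <- attr(st, "witnesses")
  for (k in which(!st$balanced)) {
    expect_gt(abs(complex_activity(tp$dec, st$complex[k], wit[[k]])), 1e-9)
  }
})

test_that("a network whose only steady state is v = 0 is fully balanced", {
  # A -> B with no way to recycle: the only steady state is v = 0
  net <- metabolic_network(c("A", "B"), list(
    list(id = "r", substrates = c(A = 1), products = c(B = 1), lb = 0, ub = 5)))
  dec <- build_decomposition(net)
  st <- find_balanced(net, dec)
  expect_true(all(st$balanced))
})

test_that("forced balancing of 1*Oaa reproduces the worked example", {
  tp <- toy_pipeline()
  fb <- force_balance(tp$net, tp$dec, "1*Oaa", tp$part, tp$st)
  expect_equal(fb$potential, 6L)
  expect_setequal(names(fb$classification),
                  c("1*AcCoa", "1*AcCoa + 1*Oaa", "1*Succ",
                    "1*AcCoa + 1*Gly", "1*Gly + 1*Succ", "0"))
  cls <- fb$classification
  expect_setequal(names(cls)[cls == "trivial"], c("1*AcCoa + 1*Oaa", "0"))
  expect_setequal(names(cls)[cls == "nontrivial_type_I"],
                  c("1*AcCoa", "1*AcCoa + 1*Gly", "1*Gly + 1*Succ"))
  expect_setequal(names(cls)[cls == "nontrivial_type_II"], "1*Succ")

  # forcing the 1*Oaa complex makes 1*Succ balanced (type II: it keeps flux)
  st2 <- find_balanced(tp$net, tp$dec,
                       extra_eq = tp$dec$A[complex_index(tp$dec, "1*Oaa"), ,
                                           drop = FALSE])
  expect_true(st2$balanced[complex_index(tp$dec, "1*Succ")])
})

test_that("forcing an already balanced complex yields an empty Q", {
  tp <- toy_pipeline()
  fb <- force_balance(tp$net, tp$dec, "1*Cit", tp$part, tp$st)
  expect_equal(fb$potential, 0L)
  expect_length(fb$Q, 0)
})

test_that("balancing potentials are module-uniform and bounded below", {
  tp <- toy_pipeline()
  pot <- balancing_potential_all(tp$net, tp$dec, tp$part, tp$st)
  expect_equal(unname(pot[c("1*Oaa", "1*AcCoa + 1*Oaa", "0")]),
               rep(6L, 3))
  succ_mod <- pot[c("1*Succ", "1*Gly + 1*Succ", "1*AcCoa + 1*Gly")]
  expect_equal(length(unique(succ_mod)), 1L)
  # balanced complexes have potential zero
  expect_true(all(pot[tp$st$label[tp$st$balanced]] == 0))
  # potential >= module size - 1
  for (m in seq_along(tp$part$modules)) {
    sz <- length(tp$part$modules[[m]])
    expect_gte(unname(pot[tp$part$representative[m]]), sz - 1L)
  }
})

test_that("module representatives and exhaustive per-complex forcing agree", {
  for (s in c(3, 11, 19)) {
    net <- random_network(5, 10, seed = s)
    dec <- build_decomposition(net)
    st <- find_balanced(net, dec)
    part <- build_partition(net, dec, st)
    pot <- balancing_potential_all(net, dec, part, st)
    for (i in st$complex[!st$balanced]) {
      fb <- force_balance(net, dec, i, part, st)
      expect_equal(unname(pot[i]), fb$potential)
    }
  }
})

test_that("concordant sources induce identical forced-balanced sets", {
  tp <- toy_pipeline()
  mod <- tp$part$modules[[tp$part$module_of[complex_index(tp$dec, "1*Oaa")]]]
  sets <- lapply(mod, function(i) {
    fb <- force_balance(tp$net, tp$dec, i, tp$part, tp$st)
    sort(c(fb$Q, i))
  })
  for (k in seq_along(sets)[-1]) expect_equal(sets[[k]], sets[[1]])
})

test_that("adding the forcing constraint only enlarges the balanced set", {
  for (s in c(5, 9)) {
    net <- random_network(5, 9, seed = s)
    dec <- build_decomposition(net)
    st <- find_balanced(net, dec)
    nb <- st$complex[!st$balanced]
    if (!length(nb)) next
    st2 <- find_balanced(net, dec,
                         extra_eq = dec$A[nb[1], , drop = FALSE])
    expect_true(all(st2$balanced[st$balanced]))
  }
})

test_that("forced-balancing summaries report fractions over sources", {
  tp <- toy_pipeline()
  nb <- tp$st$complex[!tp$st$balanced]
  results <- lapply(nb, function(i)
    force_balance(tp$net, tp$dec, i, tp$part, tp$st))
  s <- classify_forced_summary(results)
  expect_equal(s$n, 7L)
  expect_equal(s$frac_nonzero_potential, 1)
  expect_gt(s$frac_balance_outside_module, 0)
  expect_gt(s$frac_induce_type_II, 0)

  empty <- classify_forced_summary(list())
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$frac_nonzero_potential))
})

test_that("balance and forced-balancing tables export as TSV", {
  tp <- toy_pipeline()
  tf <- tempfile(fileext = ".tsv")
  write_balance_tsv(tp$st, tf)
  expect_equal(nrow(read.delim(tf)), 14L)
  fb <- force_balance(tp$net, tp$dec, "1*Oaa", tp$part, tp$st)
  tf2 <- tempfile(fileext = ".tsv")
  write_balance_tsv(fb, tf2)
  tab <- read.delim(tf2)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$source_label == "1*Oaa"))
})
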