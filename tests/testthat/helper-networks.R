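# small networks used across test files

# 0 -> A -> 0 linear chain, ub 10
chain_net <- function(ub = 10) {
  metabolic_network(c("A"), list(
    list(id = "in", substrates = NULL, products = c(A = 1), lb = 0, ub = ub),
    list(id = "out", substrates = c(A = 1), products = NULL, lb = 0, ub = ub)
  ))
}

# uptake -> A -> B -> biomass linear pathway
pathway_net <- function() {
  metabolic_network(c("A", "B"), list(
    list(id = "up", substrates = NULL, products = c(A = 1), lb = 0, ub = 10),
    list(id = "ab", substrates = c(A = 1), products = c(B = 1), lb = 0, ub = 10),
    list(id = "bio", substrates = c(B = 1), products = NULL, lb = 0, ub = 10)
  ))
}

# uptake -> A -> {two parallel routes} -> B -> biomass
parallel_net <- function() {
  metabolic_network(c("A", "B"), list(
    list(id = "up", substrates = NULL, products = c(A = 1), lb = 0, ub = 10),
    list(id = "p1", substrates = c(A = 1), products = c(B = 1), lb = 0, ub = 10),
    list(id = "p2", substrates = c(A = 1), products = c(B = 1), lb = 0, ub = 10),
    list(id = "bio", substrates = c(B = 1), products = NULL, lb = 0, ub = 10)
  ))
}

toy_pipeline <- function() {
  net <- toy_fig1()
  dec <- build_decomposition(net)
  st <- find_balanced(net, dec)
  part <- build_partition(net, dec, st)
  list(net = net, dec = dec, st = st, part = part)
}
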