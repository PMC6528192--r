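# Shared helpers for the test suite. Network learning on finite samples can
# emit cycle warnings from conflicting orientations; replicate studies
# silence them so the assertions stay about the quantities under test.

quiet_learn <- function(...) suppressWarnings(learn_gdag(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjacency skeleton F1 of a learned network against a simulation truth
study_f1 <- function(net, truth) skeleton_metrics(net, truth)$f1

# single standardized-data study fit used by several tests
fit_study <- function(n, seed, alpha = 0.001, with_instruments = TRUE, ...) {
  st <- simulate_study(n, seed = seed, ...)
  adj <- adjust_covariates(st$metabolites$values, st$covariates)
  inst <- if (with_instruments) genotypes_to_instruments(st$genotypes) else NULL
  net <- quiet_learn(inst, adj, alpha = alpha)
  list(study = st, adjusted = adj, instruments = inst, network = net)
}

# all 64 mixed graphs on 3 nodes (each unordered pair: none/forward/
# backward/undirected), used to test structural Hamming distance properties
all_three_node_amats <- function() {
  states <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 1:4) for (s2 in 1:4) for (s3 in 1:4) {
    a <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    st <- list(states[[s1]], states[[s2]], states[[s3]])
    for (k in 1:3) {
      a[pairs[[k]][1], pairs[[k]][2]] <- st[[k]][1]
      a[pairs[[k]][2], pairs[[k]][1]] <- st[[k]][2]
    }
    out[[length(out) + 1L]] <- a
  }
  out
}
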