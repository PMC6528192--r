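test_that("genotype simulation is deterministic and respects the LD spec", {
  spec <- ld_spec(n_blocks = 4, block_size = 5, within_block_r = 0.9,
                  maf_range = c(0.1, 0.3))
  g1 <- simulate_genotypes(500, spec, seed = 11)
  g2 <- simulate_genotypes(500, spec, seed = 11)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variant_meta, g2$variant_meta)
  expect_true(all(g1$dosages %in% 0:2))
  expect_match(g1$variant_meta$id[1], "^\\d+:\\d+:[ACGT]:[ACGT]$")
  expect_length(unique(g1$variant_meta$gene), 4L)

  # Monte-Carlo check of the allele-copy proxy model: realized mean
  # within-block dosage correlation tracks the target
  gl <- simulate_genotypes(10000, ld_spec(3, 4, 0.9, c(0.2, 0.3)), seed = 1)
  rs <- c()
  for (b in 0:2) {
    idx <- b * 4 + 1:4
    cc <- cor(gl$dosages[, idx])
    rs <- c(rs, cc[upper.tri(cc)])
  }
  expect_gt(mean(rs), 0.85)
  expect_lt(mean(rs), 0.95)
  f <- colMeans(gl$dosages) / 2
  expect_true(all(f > 0.1 & f < 0.4))
})

test_that("forced fixation yields a column of 2s and monomorphism warns", {
  g <- suppressWarnings(
    simulate_genotypes(4, ld_spec(1, 1, 0, c(1, 1)), seed = 1)
  )
  expect_equal(unname(g$dosages[, 1]), rep(2L, 4))
  expect_warning(
    simulate_genotypes(4, ld_spec(1, 1, 0, c(1, 1)), seed = 1),
    "monomorphic"
  )
  expect_error(simulate_genotypes(1, ld_spec()), "n_samples")
  expect_error(ld_spec(within_block_r = 1), "within_block_r")
  expect_error(ld_spec(maf_range = c(0, 0.1)), "maf_range")
})

test_that("random metabolite DAGs are acyclic with the advertised density", {
  # density forcing a single edge on 2 nodes
  tr <- simulate_metabolite_dag(2, edge_density = 1, seed = 7)
  expect_equal(sum(tr$amat), 1L)
  lam <- tr$lambda[tr$lambda != 0]
  expect_true(abs(lam) >= 0.3 && abs(lam) <= 0.8)

  # construction invariant: topological sort never fails
  for (s in 1:5) {
    tr <- simulate_metabolite_dag(50, edge_density = 2, seed = s)
    expect_silent(gdagnet:::topological_order(tr$amat))
  }

  # edge-count expectation: edges ~ Binomial(C(20,2), 2*2/19), so the mean
  # over 100 seeds must fall within 3 standard errors of 20 * 2
  counts <- vapply(1:100, function(s) {
    sum(simulate_metabolite_dag(20, edge_density = 2, seed = s)$amat)
  }, numeric(1))
  p_edge <- 2 * 2 / 19
  se <- sqrt(choose(20, 2) * p_edge * (1 - p_edge) / 100)
  expect_lt(abs(mean(counts) - 40), 3 * se)

  expect_error(simulate_metabolite_dag(20, edge_density = -1), "edge_density")
})

test_that("metabolite generation follows the structural equations", {
  g <- simulate_genotypes(5000, ld_spec(2, 2, 0.9, c(0.2, 0.2)), seed = 2)

  # no effects at all: sample covariance is approximately the identity
  nm <- sprintf("M%02d", 1:6)
  amat <- matrix(0L, 6, 6, dimnames = list(nm, nm))
  truth <- simulation_truth(amat, amat * 0,
                            matrix(numeric(0), 0, 6,
                                   dimnames = list(NULL, nm)),
                            rep(1, 6))
  sim <- simulate_metabolites(g, truth, covariate_effects = 0, noise_seed = 3)
  cc <- cor(sim$metabolites$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(5000))

  # single edge with lambda = 0.5: OLS slope recovers it
  g2 <- simulate_genotypes(10000, ld_spec(2, 2, 0.9, c(0.2, 0.2)), seed = 2)
  nm2 <- c("M01", "M02")
  am2 <- matrix(c(0L, 0L, 1L, 0L), 2, dimnames = list(nm2, nm2))
  lm2 <- matrix(c(0, 0.5, 0, 0), 2, dimnames = list(nm2, nm2))
  tr2 <- simulation_truth(am2, lm2,
                          matrix(numeric(0), 0, 2, dimnames = list(NULL, nm2)),
                          rep(1, 2))
  sim2 <- simulate_metabolites(g2, tr2, covariate_effects = 0, noise_seed = 4)
  slope <- coef(lm(sim2$metabolites$values[, "M02"] ~
                     sim2$metabolites$values[, "M01"]))[2]
  expect_lt(abs(slope - 0.5), 0.02)

  # unknown gene in the effect table errors
  tr3 <- attach_gene_effects(tr2, data.frame(
    gene = "NOPE", metabolite = "M01", gamma = 1, stringsAsFactors = FALSE
  ))
  expect_error(simulate_metabolites(g2, tr3), "absent")
})

test_that("child standardization keeps unit variance and a consistent truth", {
  st <- simulate_study(4000, seed = 9)
  sds <- apply(st$metabolites$values, 2, sd)
  expect_true(all(abs(sds - 1) < 1e-12))
  # recorded lambda is the structural coefficient of the returned data:
  # regressing a child on its parents recovers it
  tr <- st$truth
  child <- names(which(colSums(tr$amat) > 0))[1]
  pa <- colnames(tr$amat)[tr$amat[, child] == 1]
  B <- gene_burden(st$genotypes)$values[, rownames(tr$gamma), drop = FALSE]
  fit <- lm(st$metabolites$values[, child] ~
              st$metabolites$values[, pa, drop = FALSE] + B)
  expect_lt(max(abs(coef(fit)[2:(1 + length(pa))] - tr$lambda[child, pa])),
            0.06)
})

test_that("scenario bundles carry the advertised pleiotropy ground truth", {
  lab_of <- function(sc) {
    lab <- sc$truth$pleiotropy_labels
    setNames(lab$label[lab$gene == sc$gene], lab$metabolite[lab$gene == sc$gene])
  }
  med <- make_scenario("mediated", 200, seed = 1)
  expect_equal(unname(lab_of(med)[c("M01", "M02")]), c("direct", "mediated"))
  ple <- make_scenario("pleiotropic", 200, seed = 1)
  expect_equal(unname(lab_of(ple)[c("M01", "M02")]), c("direct", "direct"))
  nul <- make_scenario("null", 200, seed = 1)
  expect_true(all(nul$truth$pleiotropy_labels$label == "none"))
  gpr <- make_scenario("gpr97_like", 200, seed = 1)
  lg <- lab_of(gpr)
  expect_equal(sum(lg == "direct"), 2L)
  expect_equal(unname(lg["eicoseneate"]), "mediated")
  bn <- make_scenario("bnipl_like", 200, seed = 1)
  expect_setequal(colnames(bn$metabolites$values),
                  c("decanoylcarnitine", "octanoylcarnitine"))
  expect_error(make_scenario("not_a_scenario", 100), "unknown scenario")

  # determinism of the whole bundle
  b1 <- make_scenario("mediated", 300, seed = 5)
  b2 <- make_scenario("mediated", 300, seed = 5)
  expect_identical(b1$metabolites$values, b2$metabolites$values)
  expect_identical(b1$genotypes$dosages, b2$genotypes$dosages)
})

test_that("missingness injection is MCAR at the requested rates", {
  m <- make_scenario("null", 1000, seed = 2)$metabolites
  expect_identical(inject_missingness(m, 0, seed = 1)$values, m$values)
  full <- inject_missingness(m, c(1, 0), seed = 1)
  expect_true(all(is.na(full$values[, 1])))
  expect_false(anyNA(full$values[, 2]))
  half <- inject_missingness(m, 0.5, seed = 3)
  fr <- colMeans(is.na(half$values))
  expect_true(all(fr > 0.45 & fr < 0.55))
  expect_error(inject_missingness(m, 1.2), "rate")
})

test_that("d-separation in the truth implies vanishing partial correlation", {
  # chain M1 -> M2 -> M3: the (M1, M3) partial correlation given M2 must
  # vanish at large n (the oracle underpinning constraint-based learning)
  nm <- c("M01", "M02", "M03")
  am <- matrix(0L, 3, 3, dimnames = list(nm, nm))
  am["M01", "M02"] <- 1L; am["M02", "M03"] <- 1L
  lm_ <- matrix(0, 3, 3, dimnames = list(nm, nm))
  lm_["M02", "M01"] <- 0.8; lm_["M03", "M02"] <- 0.8
  tr <- simulation_truth(am, lm_,
                         matrix(numeric(0), 0, 3, dimnames = list(NULL, nm)),
                         rep(1, 3))
  g <- simulate_genotypes(50000, ld_spec(1, 1, 0, c(0.3, 0.3)), seed = 1)
  sim <- simulate_metabolites(g, tr, covariate_effects = 0, noise_seed = 5)
  Y <- sim$metabolites$values
  pc <- fisher_z_test("M01", "M03", "M02", cor(Y), nrow(Y))
  expect_lt(abs(pc$partial_cor), 3 / sqrt(50000))
})
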