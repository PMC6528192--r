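empty_network <- function(mets) {
  amat <- matrix(0L, length(mets), length(mets), dimnames = list(mets, mets))
  causal_network(amat, rep("metabolite", length(mets)))
}

test_that("with no metabolite edges the SEM collapses to the marginal scan", {
  sc <- make_scenario("pleiotropic", 800, seed = 31)
  adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
  burd <- gene_burden(sc$genotypes)
  net <- empty_network(colnames(adj$residuals))
  fit <- fit_sem(net, adj, burd, genes = sc$gene)
  expect_equal(nrow(fit$lambda), 0L)
  scan <- single_variant_scan(
    burd$values[, sc$gene, drop = FALSE], adj)
  for (r in seq_len(nrow(fit$gamma))) {
    k <- which(scan$metabolite == fit$gamma$metabolite[r])
    expect_equal(fit$gamma$estimate[r], scan$beta[k], tolerance = 1e-12)
    expect_equal(fit$gamma$se[r], scan$se[k], tolerance = 1e-12)
    expect_equal(fit$gamma$p_value[r], scan$p_value[k], tolerance = 1e-12)
  }
})

test_that("SEM recovers mediated and pleiotropic scenario parameters", {
  # mediated: gamma on M1 = 1.5, lambda M1 -> M2 = 0.5; the direct gamma on
  # M2 must vanish
  sc <- make_scenario("mediated", 20000, seed = 32)
  adj <- adjust_covariates(sc$metabolites$values, sc$covariates)
  burd <- gene_burden(sc$genotypes)
  net <- causal_network(sc$truth$amat, rep("metabolite", 2))
  fit <- fit_sem(net, adj, burd, genes = c(sc$gene, sc$null_gene))
  lam <- fit$lambda[fit$lambda$metabolite == "M02", ]
  expect_lt(abs(lam$estimate - 0.5), 0.03)
  g2 <- fit$gamma[fit$gamma$metabolite == "M02" & fit$gamma$gene == sc$gene, ]
  expect_lt(abs(g2$estimate), 0.05)
  g1 <- fit$gamma[fit$gamma$metabolite == "M01" & fit$gamma$gene == sc$gene, ]
  expect_lt(abs(g1$estimate - 1.5), 0.1)

  # pleiotropic: both direct effects recovered
  scp <- make_scenario("pleiotropic", 20000, seed = 33)
  adjp <- adjust_covariates(scp$metabolites$values, scp$covariates)
  fitp <- fit_sem(causal_network(scp$truth$amat, rep("metabolite", 2)),
                  adjp, gene_burden(scp$genotypes), genes = scp$gene)
  expect_lt(max(abs(fitp$gamma$estimate - 1.5)), 0.1)
})

test_that("SEM guards against cycles, undirected edges and collinearity", {
  sc <- make_scenario("mediated", 300, seed = 34)
  adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
  burd <- gene_burden(sc$genotypes)
  und <- matrix(c(0L, 1L, 1L, 0L), 2,
                dimnames = list(c("M01", "M02"), c("M01", "M02")))
  net_und <- causal_network(und, rep("metabolite", 2))
  expect_error(fit_sem(net_und, adj, burd, genes = sc$gene), "undirected")
  expect_no_error(fit_sem(net_und, adj, burd, genes = sc$gene,
                          undirected = "ignore"))
  expect_error(fit_sem(empty_network(c("M01", "M02")), adj, burd,
                       genes = "NOT_A_GENE"), "absent")
  # collinear parents error names the column
  Y <- cbind(adj$residuals, M03 = adj$residuals[, "M01"])
  expect_error(direct_effect_test(sc$gene, "M02", c("M01", "M03"), Y, burd),
               "collinear")
  expect_error(direct_effect_test(sc$gene, "M99", character(0), adj, burd),
               "absent")
})

test_that("direct_effect_test matches the SEM gamma row exactly", {
  sc <- make_scenario("mediated", 2000, seed = 35)
  adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
  burd <- gene_burden(sc$genotypes)
  net <- causal_network(sc$truth$amat, rep("metabolite", 2))
  fit <- fit_sem(net, adj, burd, genes = sc$gene)
  det <- direct_effect_test(sc$gene, "M02", "M01", adj, burd)
  row <- fit$gamma[fit$gamma$metabolite == "M02", ]
  expect_equal(det$beta, row$estimate, tolerance = 1e-12)
  expect_equal(det$se, row$se, tolerance = 1e-12)
  expect_equal(det$p_value, row$p_value, tolerance = 1e-12)
  # empty parents reduce to the marginal test
  det0 <- direct_effect_test(sc$gene, "M01", character(0), adj, burd)
  scan <- single_variant_scan(burd$values[, sc$gene, drop = FALSE],
                              adj$residuals[, "M01", drop = FALSE])
  expect_equal(det0$beta, scan$beta, tolerance = 1e-12)
})

test_that("pleiotropy verdicts follow the direct/mediated logic", {
  run_scenario <- function(name, seed, n = 2000) {
    sc <- make_scenario(name, n, seed = seed)
    adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
    inst <- genotypes_to_instruments(sc$genotypes)
    net <- quiet_learn(inst, adj, alpha = 0.001)
    burd <- gene_burden(sc$genotypes)
    fit <- fit_sem(net, adj, burd, genes = c(sc$gene, sc$null_gene),
                   undirected = "ignore")
    list(sc = sc, net = net, fit = fit, adj = adj, burd = burd)
  }
  x <- run_scenario("bnipl_like", 36)
  call <- assess_pleiotropy(x$sc$gene, colnames(x$sc$metabolites$values),
                            x$net, x$fit, m = x$adj, burdens = x$burd)
  v <- setNames(call$table$verdict, call$table$metabolite)
  expect_equal(unname(v["decanoylcarnitine"]), "direct")
  expect_equal(unname(v["octanoylcarnitine"]), "mediated")
  expect_false(call$is_pleiotropic)
  # the marginal association was there before conditioning
  marg <- call$table[call$table$metabolite == "octanoylcarnitine", ]
  expect_lt(marg$marginal_p, 1e-6)
  expect_gt(marg$conditional_p, 0.025)

  y <- run_scenario("pleiotropic", 37)
  cally <- assess_pleiotropy(y$sc$gene, c("M01", "M02"), y$net, y$fit)
  expect_true(cally$is_pleiotropic)
  expect_equal(sum(cally$table$verdict == "direct"), 2L)

  # a gene with no effect comes out not significant
  callnull <- assess_pleiotropy(y$sc$null_gene, c("M01", "M02"), y$net, y$fit)
  expect_true(all(callnull$table$verdict == "not_significant"))
  expect_false(callnull$is_pleiotropic)

  expect_error(assess_pleiotropy(y$sc$gene, "M99", y$net, y$fit),
               "absent from network")
})

test_that("verdicts are invariant under metabolite relabeling", {
  sc <- make_scenario("bnipl_like", 3000, seed = 38)
  adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
  inst <- genotypes_to_instruments(sc$genotypes)
  burd <- gene_burden(sc$genotypes)
  verdicts <- function(a) {
    net <- quiet_learn(inst, a, alpha = 0.001)
    fit <- fit_sem(net, a, burd, genes = sc$gene, undirected = "ignore")
    call <- assess_pleiotropy(sc$gene, colnames(a$residuals), net, fit)
    sort(paste(call$table$metabolite, call$table$verdict))
  }
  perm <- adj
  perm$residuals <- perm$residuals[, rev(colnames(perm$residuals))]
  expect_equal(verdicts(adj), verdicts(perm))
})
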