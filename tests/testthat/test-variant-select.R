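test_that("gene burdens equal brute-force per-sample sums", {
  g <- simulate_genotypes(10, ld_spec(2, 3, 0.8, c(0.3, 0.4)), seed = 1)
  b <- gene_burden(g)
  # loop oracle
  for (gene in colnames(b$values)) {
    vars <- g$variant_meta$id[g$variant_meta$gene == gene]
    expect_equal(unname(b$values[, gene]),
                 unname(rowSums(g$dosages[, vars, drop = FALSE])))
  }
  # single-variant gene: burden column equals the dosage column
  g1 <- simulate_genotypes(10, ld_spec(2, 1, 0, c(0.3, 0.4)), seed = 2)
  b1 <- gene_burden(g1)
  expect_equal(unname(b1$values[, 1]), unname(g1$dosages[, 1]))
  # unmapped variant errors with the offending id
  gm <- setNames(g$variant_meta$gene, g$variant_meta$id)
  expect_error(gene_burden(g, gm[-1]), g$variant_meta$id[1], fixed = TRUE)
})

test_that("Bonferroni thresholds reproduce the scan-family arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 122, 372), 0.05 / (122 * 372))
  expect_equal(bonferroni_threshold(0.05, 122, 372), 1.1015e-06,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 122, 451), 9.0864e-07,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0, 10), "positive")
  expect_error(bonferroni_threshold(1.5, 10, 10), "alpha")
})

test_that("the association scan matches a per-pair lm oracle to 1e-10", {
  set.seed(5)
  U <- matrix(rbinom(30 * 4, 2, 0.3), 30, 4,
              dimnames = list(NULL, paste0("u", 1:4)))
  Y <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("m", 1:3)))
  Y[, 1] <- Y[, 1] + 0.8 * U[, 2]
  res <- single_variant_scan(U, Y, threshold = 1e-3)
  for (r in seq_len(nrow(res))) {
    sm <- summary(lm(Y[, res$metabolite[r]] ~ U[, res$unit[r]]))$coefficients
    expect_equal(res$beta[r], sm[2, 1], tolerance = 1e-10)
    expect_equal(res$se[r], sm[2, 2], tolerance = 1e-10)
    expect_equal(res$p_value[r], sm[2, 4], tolerance = 1e-10)
  }
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # unit identical to the metabolite: beta -> 1 on standardized scales
  z <- scale(rnorm(100))
  res2 <- single_variant_scan(cbind(u = as.numeric(z)), cbind(m = as.numeric(z)))
  expect_equal(res2$beta, 1, tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-100)

  # monomorphic unit skipped with a warning, not an error
  U2 <- cbind(U, mono = 0L)
  expect_warning(res3 <- single_variant_scan(U2, Y), "monomorphic")
  expect_false("mono" %in% res3$unit)
})

test_that("penalized selection obeys the lasso soft-threshold oracle", {
  set.seed(42)
  n <- 400; p <- 5
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X = n I
  colnames(X) <- paste0("u", 1:p)
  b <- c(2, -1.2, 0.6, 0, 0)
  y <- drop(X %*% b) + rnorm(n)
  # with an orthonormal standardized design, the support at penalty t is
  # exactly {j : |x_j' y / n| > t}
  bo <- drop(crossprod(X, y - mean(y))) / n
  for (t in c(1.5, 0.3, 0.01)) {
    cc_t <- ccrs_select(X, y, tuning_grid = t)
    expect_setequal(cc_t$selected, colnames(X)[abs(bo) > t])
  }
  cc <- ccrs_select(X, y, tuning_grid = c(1.5, 0.3, 0.01))
  expect_setequal(cc$selected, c("u1", "u2", "u3"))
  # refit coefficients equal the OLS oracle on the chosen support
  ols <- coef(lm(y ~ X[, cc$selected]))[-1]
  expect_equal(unname(cc$coefficients), unname(ols), tolerance = 1e-6)
  expect_error(ccrs_select(X, y, tuning_grid = numeric(0)), "empty")

  # null design: support stays (near) empty in most seeds
  sizes <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rbinom(1000 * 20, 2, 0.2), 1000, 20)
    yn <- rnorm(1000)
    length(ccrs_select(Xn, yn)$selected)
  }, numeric(1))
  expect_lt(mean(sizes), 1)
})

test_that("a planted effect is selected through its LD proxy cluster", {
  hits <- vapply(1:20, function(s) {
    g <- simulate_genotypes(800, ld_spec(10, 3, 0.9, c(0.1, 0.3)), seed = s)
    x <- g$dosages[, 1]
    y <- with_seed(s + 500, 2 * (x - mean(x)) / sd(x) + rnorm(800))
    sel <- ccrs_select(g$dosages, y)$selected
    proxies <- g$variant_meta$id[1:3]  # the planted variant's block
    any(sel %in% proxies)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("selection intersection is a subset of both inputs", {
  pa <- data.frame(unit = c("g1", "g2", "g3"),
                   metabolite = c("m1", "m1", "m2"), stringsAsFactors = FALSE)
  pb <- data.frame(unit = c("g2", "g3", "g4"),
                   metabolite = c("m1", "m9", "m2"), stringsAsFactors = FALSE)
  a <- selection_result(pa, "single")
  b <- selection_result(pb, "ccrs")
  ab <- intersect_selections(a, b)
  expect_equal(nrow(ab$pairs), 1L)
  expect_equal(ab$pairs$unit, "g2")
  expect_equal(ab$pairs$provenance, "single+ccrs")
  # disjoint inputs -> empty
  d <- selection_result(data.frame(unit = "gX", metabolite = "mX"), "ccrs")
  expect_equal(nrow(intersect_selections(a, d)$pairs), 0L)
  # a subset of b -> a
  sub <- selection_result(pa[1:2, ], "ccrs")
  expect_equal(nrow(intersect_selections(sub, a)$pairs), 2L)
  expect_lte(nrow(ab$pairs), nrow(a$pairs))
  expect_lte(nrow(ab$pairs), nrow(b$pairs))
})

test_that("replication reuses the scan and handles missing units", {
  sc <- make_scenario("pleiotropic", 600, seed = 8)
  adj <- adjust_covariates(scale(sc$metabolites$values), sc$covariates)
  burd <- gene_burden(sc$genotypes)
  thr <- bonferroni_threshold(0.05, 2, 2)
  scan <- single_variant_scan(burd, adj, threshold = thr)
  sel <- as_selection(scan)
  expect_gt(nrow(sel$pairs), 0)
  # validation = discovery: p-values equal the discovery scan's
  rep1 <- replicate_findings(sel, list(units = burd, m = adj))
  key <- paste(scan$unit, scan$metabolite)
  expect_equal(rep1$p_value,
               scan$p_value[match(paste(rep1$unit, rep1$metabolite), key)],
               tolerance = 1e-12)
  # absent unit -> NA row
  b2 <- burd; b2$values <- b2$values[, 1, drop = FALSE]
  sel2 <- selection_result(data.frame(unit = c(colnames(burd$values)[2]),
                                      metabolite = "M01"), "single")
  rep2 <- replicate_findings(sel2, list(units = b2, m = adj))
  expect_true(is.na(rep2$p_value))
  # independent validation draw replicates a true strong effect
  scv <- make_scenario("pleiotropic", 672, seed = 9)
  adjv <- adjust_covariates(scale(scv$metabolites$values), scv$covariates)
  repv <- replicate_findings(sel, list(units = gene_burden(scv$genotypes),
                                       m = adjv))
  true_rows <- repv$unit == "GENE001"
  expect_true(all(repv$replicated[true_rows]))
})
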