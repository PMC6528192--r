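test_that("Fisher-z test reproduces closed forms and the regression oracle", {
  # closed form: rho = 0.5, n = 100, |S| = 0
  C <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ft <- fisher_z_test("a", "b", character(0), C, 100)
  expect_equal(ft$z, atanh(0.5) * sqrt(97), tolerance = 1e-12)
  expect_equal(ft$p_value, 2 * pnorm(-atanh(0.5) * sqrt(97)),
               tolerance = 1e-12)
  # rho = 0 -> z = 0, p = 1
  C0 <- diag(2); dimnames(C0) <- dimnames(C)
  f0 <- fisher_z_test("a", "b", character(0), C0, 50)
  expect_equal(f0$z, 0)
  expect_equal(f0$p_value, 1)
  expect_error(fisher_z_test("a", "b", character(0), C, 3), "exceed")

  # partial correlation equals brute-force residual correlation
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
    X[, 2] <- X[, 1] + 0.5 * X[, 3] + rnorm(60)
    Cx <- cor(X)
    S <- sample(3:5, sample(1:3, 1))
    r1 <- resid(lm(X[, 1] ~ X[, S, drop = FALSE]))
    r2 <- resid(lm(X[, 2] ~ X[, S, drop = FALSE]))
    ft <- fisher_z_test(1, 2, S, Cx, 60)
    expect_equal(ft$partial_cor, cor(r1, r2), tolerance = 1e-8)
  }
})

test_that("the skeleton search recovers chains and respects alpha bounds", {
  # chain A -> B -> C at large n: skeleton A-B, B-C, no A-C
  set.seed(10)
  n <- 50000
  A <- rnorm(n); B <- 0.8 * A + rnorm(n); C <- 0.8 * B + rnorm(n)
  D <- cbind(A = A, B = B, C = C)
  sk <- learn_skeleton(D, alpha = 0.001)
  expect_true(sk$adj["A", "B"])
  expect_true(sk$adj["B", "C"])
  expect_false(sk$adj["A", "C"])
  expect_equal(sk$sepsets[["A|C"]], "B")

  # perfectly correlated pair: the edge survives any alpha
  z <- rnorm(500)
  Dz <- cbind(a = z, b = z)
  for (a in c(1e-6, 0.001, 0.05)) {
    expect_true(learn_skeleton(Dz, alpha = a)$adj["a", "b"])
  }

  # independent variables: empty skeleton (fixed seed; the per-pair false
  # positive rate is alpha)
  set.seed(11)
  Di <- matrix(rnorm(1000 * 5), 1000, 5)
  expect_equal(sum(learn_skeleton(Di, alpha = 0.001)$adj), 0)

  expect_error(learn_skeleton(D, alpha = 0), "alpha")

  # alpha monotonicity: edge count non-decreasing along the grid
  st <- simulate_study(1500, seed = 12)
  Y <- st$metabolites$values
  counts <- vapply(c(0.0005, 0.001, 0.005, 0.01, 0.05), function(a) {
    sum(learn_skeleton(Y, alpha = a)$adj) / 2
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("orientation anchors instruments and finds chain directions", {
  # P -> M1 -> M2: the M1-M2 edge must orient as M1 -> M2
  set.seed(13)
  n <- 20000
  P <- rbinom(n, 2, 0.3)
  M1 <- 0.8 * P + rnorm(n)
  M2 <- 0.7 * M1 + rnorm(n)
  D <- cbind(P = P, M1 = M1, M2 = M2)
  sk <- learn_skeleton(D, alpha = 0.001,
                       node_types = c("instrument", "metabolite", "metabolite"))
  net <- orient_edges(sk)
  expect_equal(net$amat["P", "M1"], 1L)
  expect_equal(net$amat["M1", "P"], 0L)   # instrument exogeneity
  expect_equal(net$amat["M1", "M2"], 1L)
  expect_equal(net$amat["M2", "M1"], 0L)
  expect_true(net$acyclic)

  # no instruments, two symmetric variables: edge stays undirected
  z <- rnorm(5000); w <- 0.7 * z + rnorm(5000)
  sk2 <- learn_skeleton(cbind(a = z, b = w), alpha = 0.001)
  net2 <- orient_edges(sk2)
  expect_equal(net2$amat["a", "b"], 1L)
  expect_equal(net2$amat["b", "a"], 1L)

  # collider A -> B <- C is detected from data
  set.seed(14)
  A <- rnorm(20000); Cc <- rnorm(20000); B <- 0.7 * A + 0.7 * Cc + rnorm(20000)
  sk3 <- learn_skeleton(cbind(A = A, B = B, C = Cc), alpha = 0.001)
  net3 <- orient_edges(sk3)
  expect_equal(unname(net3$amat[c("A", "B"), "B"]), c(1L, 0L))
  expect_equal(unname(net3$amat["C", "B"]), 1L)
  expect_equal(unname(net3$amat["B", "C"]), 0L)
})

test_that("structural Hamming distance is a metric with unit edge costs", {
  g <- all_three_node_amats()
  # specific costs
  ab <- g[[which(vapply(g, function(a) a["A","B"]==1 && a["B","A"]==0 &&
                          sum(a) == 1, logical(1)))[1]]]
  ab_und <- ab; ab_und["B", "A"] <- 1L
  none <- g[[1]]
  expect_equal(shd(ab, ab), 0)
  expect_equal(shd(ab, ab_und), 1)   # orientation mismatch costs 1
  expect_equal(shd(ab, none), 1)     # missing edge costs 1
  extra <- ab; extra["B", "C"] <- 1L
  expect_equal(shd(extra, none), 2)
  # metric properties by enumeration over all 64 mixed graphs
  Dm <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64) Dm[i, j] <- shd(g[[i]], g[[j]])
  expect_true(all(Dm == t(Dm)))
  expect_true(all(diag(Dm) == 0))
  expect_true(all(Dm[Dm == 0] == 0 | row(Dm) != col(Dm)))
  for (k in sample(1:64, 8)) {
    expect_true(all(Dm <= outer(Dm[, k], Dm[k, ], `+`)))
  }
  expect_error(shd(ab, matrix(0L, 2, 2)), "node sets differ")
})

test_that("alpha tuning prefers stable (small) levels on pure noise", {
  set.seed(15)
  D <- matrix(rnorm(300 * 8), 300, 8)
  tu <- tune_alpha(D, alpha_grid = c(0.001, 0.05), n_replicates = 10,
                   seed = 1)
  expect_equal(tu$chosen_alpha, 0.001)
  expect_lt(tu$stability$mean_shd[tu$stability$alpha == 0.001],
            tu$stability$mean_shd[tu$stability$alpha == 0.05])
  expect_error(tune_alpha(D, n_replicates = 1), "at least 2")
  expect_error(tune_alpha(D, alpha_grid = numeric(0)), "empty")
})

test_that("network learning is deterministic and instruments stay exogenous", {
  fs <- fit_study(1000, seed = 16)
  net_a <- quiet_learn(fs$instruments, fs$adjusted, alpha = 0.001)
  net_b <- quiet_learn(fs$instruments, fs$adjusted, alpha = 0.001)
  expect_identical(net_a$amat, net_b$amat)
  inst_cols <- net_a$nodes$name[net_a$nodes$type == "instrument"]
  expect_true(all(net_a$amat[, inst_cols] == 0L))
  # zero instruments: a CPDAG (undirected edges allowed) is still valid
  net0 <- quiet_learn(NULL, fs$adjusted, alpha = 0.001)
  expect_s3_class(net0, "causal_network")
  expect_true(all(net0$nodes$type == "metabolite"))
  # metabolite-level view
  sub <- metabolite_subgraph(net_a)
  expect_setequal(rownames(sub$metabolite_amat),
                  colnames(fs$adjusted$residuals))
})
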