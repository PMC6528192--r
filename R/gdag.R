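# Constraint-based causal-network learning over instruments + metabolites.
# Instruments are exogenous by design (genotype-derived), so the search
# excludes instrument-instrument edges a priori and anchors every
# instrument-metabolite edge as instrument -> metabolite; v-structures and
# Meek propagation orient the rest.

#' Fisher-z conditional-independence test
#'
#' Partial correlation of nodes `i` and `j` given set `S`, computed by
#' inverting the corresponding submatrix of the correlation matrix, with
#' the Fisher z statistic `atanh(rho) * sqrt(n - |S| - 3)` and a two-sided
#' normal p-value.
#'
#' @param i,j Node names or indices.
#' @param S Conditioning set (names or indices; may be empty).
#' @param corr Correlation matrix of the data.
#' @param n Sample count (must exceed `|S| + 3`).
#' @return List of class `ci_test_result`: `pair`, `S`, `partial_cor`, `z`,
#'   `p_value`, `n_effective`.
#' @export
fisher_z_test <- function(i, j, S = integer(0), corr, n) {
  nm <- colnames(corr)
  ii <- if (is.character(i)) match(i, nm) else as.integer(i)
  jj <- if (is.character(j)) match(j, nm) else as.integer(j)
  ss <- if (is.character(S)) match(S, nm) else as.integer(S)
  if (anyNA(c(ii, jj, ss))) stop_invalid("unknown node in test")
  k <- length(ss)
  if (n <= k + 3) stop_invalid("n must exceed |S| + 3")
  if (k == 0) {
    rho <- corr[ii, jj]
  } else {
    idx <- c(ii, jj, ss)
    sub <- corr[idx, idx, drop = FALSE]
    P <- tryCatch(solve(sub), error = function(e) NULL)
    if (is.null(P) || P[1, 1] * P[2, 2] <= 0) {
      stop_invalid("singular correlation submatrix for set {",
                   paste(nm[idx] %||% idx, collapse = ", "), "}")
    }
    rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  rho_c <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(rho_c) * sqrt(n - k - 3)
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(pair = c(i, j), S = S, partial_cor = rho, z = z,
         p_value = max(p, .Machine$double.xmin), n_effective = n - k - 3),
    class = "ci_test_result"
  )
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("CI test %s _||_ %s | {%s}: pcor = %.4f, z = %.3f, p = %.3g\n",
              x$pair[1], x$pair[2], paste(x$S, collapse = ","),
              x$partial_cor, x$z, x$p_value))
  invisible(x)
}

#' PC-stable skeleton search
#'
#' Order-independent (stable) PC adjacency search: start from the complete
#' graph minus a-priori-excluded pairs, then for growing conditioning-set
#' sizes remove edge (i, j) whenever some subset of the level-fixed
#' adjacencies renders the pair conditionally independent at level `alpha`.
#' Separating sets are recorded. Node order is the (fixed) column order, so
#' the result is deterministic.
#'
#' @param data Numeric matrix (samples x nodes) of instruments + adjusted
#'   metabolites (columns are standardized internally via the correlation).
#' @param alpha CI-test level in (0, 1).
#' @param node_types Character vector per column, `"instrument"` or
#'   `"metabolite"`; instrument-instrument edges are excluded a priori
#'   (principal components are orthogonal by construction). Default: all
#'   metabolites.
#' @param m_max Maximum conditioning-set size (default unrestricted).
#' @return List of class `gdag_skeleton`: `adj` (symmetric logical matrix),
#'   `sepsets` (named list), `node_types`, `n`, `alpha`, `corr`.
#' @export
learn_skeleton <- function(data, alpha = 0.001, node_types = NULL,
                           m_max = Inf) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid("alpha must be in (0, 1)")
  }
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  node_types <- node_types %||% rep("metabolite", ncol(X))
  stopifnot(length(node_types) == ncol(X))
  corr <- stats::cor(X)
  skeleton_from_corr(corr, nrow(X), alpha, node_types, m_max)
}

# skeleton from a precomputed correlation matrix (used by tune_alpha to
# avoid recomputing per alpha)
skeleton_from_corr <- function(corr, n, alpha, node_types, m_max = Inf) {
  p <- ncol(corr)
  nm <- colnames(corr)
  G0 <- matrix(TRUE, p, p)
  diag(G0) <- FALSE
  inst <- node_types == "instrument"
  if (any(inst)) G0[inst, inst] <- FALSE
  mm <- if (is.finite(m_max)) as.integer(m_max) else p
  type_code <- as.integer(node_types != "instrument")
  res <- .skeleton_pc_stable(corr, as.integer(n), alpha, G0, type_code, mm)
  adj <- res$adj
  dimnames(adj) <- list(nm, nm)
  sepsets <- list()
  if (length(res$sep_i)) {
    for (t in seq_along(res$sep_i)) {
      k <- pair_key(nm[res$sep_i[t]], nm[res$sep_j[t]])
      sepsets[[k]] <- nm[res$sep_S[[t]]]
    }
  }
  structure(
    list(adj = adj, sepsets = sepsets, node_types = node_types, n = n,
         alpha = alpha, corr = corr),
    class = "gdag_skeleton"
  )
}

#' @export
print.gdag_skeleton <- function(x, ...) {
  cat(sprintf("<gdag_skeleton> %d nodes, %d edges (alpha = %g)\n",
              ncol(x$adj), sum(x$adj) / 2, x$alpha))
  invisible(x)
}

#' Orient a skeleton into a causal network
#'
#' Three stages: (1) background knowledge — every instrument-metabolite edge
#' is oriented instrument -> metabolite (inherited genetic variation causes
#' metabolite variation, never the reverse); (2) v-structures from the
#' recorded separating sets; (3) Meek propagation rules (R1-R4). Residual
#' ambiguities stay undirected. Orientations that would point into an
#' instrument or reverse an already-directed edge are dropped and logged as
#' conflicts.
#'
#' @param skeleton A `gdag_skeleton` from [learn_skeleton()].
#' @param sepsets,node_types Override the skeleton's own (rarely needed).
#' @return A [causal_network()]; conflicts (if any) in
#'   `attr(net, "conflicts")`.
#' @export
orient_edges <- function(skeleton, sepsets = NULL, node_types = NULL) {
  stopifnot(inherits(skeleton, "gdag_skeleton"))
  sepsets <- sepsets %||% skeleton$sepsets
  node_types <- node_types %||% skeleton$node_types
  A <- skeleton$adj
  res <- orient_amat(A, sepsets, node_types, corr = skeleton$corr,
                     n = skeleton$n, alpha = skeleton$alpha)
  net <- causal_network(res$amat, node_types, sepsets = sepsets,
                        alpha = skeleton$alpha)
  attr(net, "conflicts") <- res$conflicts
  net
}

# core orientation on an adjacency matrix; returns integer amat.
# When corr/n/alpha are supplied, candidate v-structures are screened
# conservatively: i -> j <- k is only oriented if i and k remain dependent
# given sepset(i, k) + {j} (a collider must re-induce the dependence);
# ambiguous triples stay unoriented.
orient_amat <- function(A, sepsets, node_types, corr = NULL, n = NULL,
                        alpha = NULL) {
  p <- ncol(A)
  nm <- colnames(A)
  amat <- matrix(0L, p, p, dimnames = dimnames(A))
  amat[A] <- 1L
  inst <- node_types == "instrument"
  conflicts <- character(0)

  # (1) instruments are exogenous: anchor instrument -> metabolite
  for (i in which(inst)) {
    js <- which(A[i, ])
    amat[js, i] <- 0L
  }

  is_und <- function(a, b) amat[a, b] == 1L && amat[b, a] == 1L
  is_dir <- function(a, b) amat[a, b] == 1L && amat[b, a] == 0L
  orient <- function(a, b, rule) {
    # a -> b; never into an instrument, never reverse an existing arrow
    if (inst[b]) {
      conflicts <<- c(conflicts, sprintf("%s: %s->%s into instrument dropped",
                                         rule, nm[a], nm[b]))
      return(FALSE)
    }
    if (is_dir(b, a)) {
      conflicts <<- c(conflicts, sprintf("%s: %s->%s conflicts with %s->%s",
                                         rule, nm[a], nm[b], nm[b], nm[a]))
      return(FALSE)
    }
    if (amat[a, b] == 1L && amat[b, a] == 0L) return(FALSE)  # already set
    amat[b, a] <<- 0L
    TRUE
  }

  # (2) v-structures: i - j - k with i, k nonadjacent. With data available
  # (corr/n/alpha), the collider status of j is decided by majority vote
  # over all small separating subsets of the adjacencies of i and k; a
  # triple whose separating sets mostly omit j is a collider, one whose
  # sets mostly include j is not, and an exact tie stays unoriented. This
  # is far more robust to near-cancelling pathways than trusting the single
  # separating set recorded first. Without data, the recorded sepset rule
  # is used.
  ambiguous <- character(0)
  triple_key <- function(x, j, y) {
    paste(min(x, y), j, max(x, y), sep = "|")
  }
  # majority votes for metabolite triples draw conditioning candidates from
  # the metabolite layer only (same background knowledge as the skeleton)
  A_vote <- A
  A_vote[, inst] <- FALSE
  for (j in seq_len(p)) {
    nb <- which(A[j, ])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (c_ in seq_len(ncol(cmb))) {
      i <- cmb[1, c_]; k <- cmb[2, c_]
      if (A[i, k]) next
      ss <- sepsets[[pair_key(nm[i], nm[k])]]
      is_collider <- if (is.null(corr)) {
        !(nm[j] %in% (ss %||% character(0)))
      } else {
        # supermajority vote over all small separating subsets of the
        # adjacency sets (candidates from the metabolite layer): j is a
        # collider when fewer than 25% of the separating sets contain it,
        # a non-collider when more than 75% do, ambiguous in between
        cnt <- .classify_triple(corr, as.integer(n), alpha, A_vote,
                                i - 1L, j - 1L, k - 1L, 5L)
        if (cnt[1] == 0) {
          !(nm[j] %in% (ss %||% character(0)))
        } else if (cnt[2] < 0.25 * cnt[1]) {
          TRUE
        } else if (cnt[2] > 0.75 * cnt[1]) {
          FALSE
        } else {
          NA
        }
      }
      if (isTRUE(is_collider)) {
        orient(i, j, "v-structure")
        orient(k, j, "v-structure")
      } else if (is.na(is_collider)) {
        ambiguous <- c(ambiguous, triple_key(i, j, k))
      }
    }
  }

  # (3) Meek rules, iterated to fixpoint
  adj <- function(a, b) amat[a, b] == 1L || amat[b, a] == 1L
  repeat {
    changed <- FALSE
    und <- which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)
    und <- und[und[, 1] < und[, 2], , drop = FALSE]
    if (!nrow(und)) break
    for (r in seq_len(nrow(und))) {
      for (dir in 1:2) {
        a <- und[r, dir]; b <- und[r, 3 - dir]
        if (!is_und(a, b)) next
        fire <- FALSE
        # R1: z -> a, z and b nonadjacent  =>  a -> b, unless the triple
        # (z, a, b) was marked ambiguous during collider classification
        for (z in which(amat[, a] == 1L & amat[a, ] == 0L)) {
          if (z != b && !adj(z, b) &&
              !(triple_key(z, a, b) %in% ambiguous)) { fire <- TRUE; break }
        }
        # R2: a -> z -> b  =>  a -> b
        if (!fire) {
          zs <- which(amat[a, ] == 1L & amat[, a] == 0L &
                        amat[, b] == 1L & amat[b, ] == 0L)
          if (length(zs)) fire <- TRUE
        }
        # R3: a - z -> b, a - w -> b, z and w nonadjacent  =>  a -> b
        if (!fire) {
          zs <- which(amat[a, ] == 1L & amat[, a] == 1L &
                        amat[, b] == 1L & amat[b, ] == 0L)
          if (length(zs) >= 2) {
            for (c1 in seq_len(length(zs) - 1)) {
              for (c2 in (c1 + 1):length(zs)) {
                if (!adj(zs[c1], zs[c2])) { fire <- TRUE; break }
              }
              if (fire) break
            }
          }
        }
        # R4 (background-knowledge rule): a - z, z -> w, w -> b,
        #     z and b nonadjacent, a adjacent to w  =>  a -> b
        if (!fire) {
          ws <- which(amat[, b] == 1L & amat[b, ] == 0L)
          for (w in ws) {
            if (!adj(a, w)) next
            zs <- which(amat[, w] == 1L & amat[w, ] == 0L)
            for (z in zs) {
              if (adj(a, z) && !adj(z, b)) { fire <- TRUE; break }
            }
            if (fire) break
          }
        }
        if (fire && orient(a, b, "meek")) changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(amat = amat, conflicts = conflicts)
}

#' Structural Hamming distance
#'
#' Number of edge discrepancies between two mixed graphs over the same node
#' set: a missing edge, an extra edge, or an orientation mismatch (including
#' directed vs undirected) each cost 1.
#'
#' @param g1,g2 [causal_network()]s or adjacency matrices in the same
#'   encoding (`amat[i, j] = 1` for i -> j; both 1 for undirected).
#' @return Integer distance.
#' @export
shd <- function(g1, g2) {
  a <- if (inherits(g1, "causal_network")) g1$amat else as.matrix(g1)
  b <- if (inherits(g2, "causal_network")) g2$amat else as.matrix(g2)
  if (!identical(dim(a), dim(b))) stop_invalid("node sets differ")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop_invalid("node sets differ")
  }
  shd_amat(a, b)
}

shd_amat <- function(a, b) {
  ca <- a + 2L * t(a)
  cb <- b + 2L * t(b)
  d <- ca != cb
  sum(d[upper.tri(d)])
}

#' Tune the CI-test level by subsample stability (structural Hamming
#' distance)
#'
#' For each candidate alpha, learns the network on `n_replicates` random
#' subsamples (fraction `subsample_frac`, without replacement) and scores the
#' alpha by the mean pairwise structural Hamming distance between the
#' replicate networks: a level whose output barely changes across
#' subsamples fits the data stably. The argmin wins; ties break toward the
#' smaller (more conservative) alpha. The same subsamples are reused for
#' every alpha so the comparison is paired.
#'
#' @param data Numeric matrix (samples x nodes).
#' @param alpha_grid Candidate levels (default
#'   `c(0.0005, 0.001, 0.005, 0.01, 0.05)`).
#' @param n_replicates Number of subsample replicates (default 45; at least
#'   2 are required for a pairwise distance).
#' @param subsample_frac Subsample fraction (default 0.8).
#' @param seed Integer seed for the subsample draws.
#' @param node_types Passed to the skeleton search.
#' @param m_max Maximum conditioning-set size.
#' @return List of class `alpha_tuning`: `chosen_alpha`, `stability`
#'   (`data.frame` with `alpha`, `mean_shd`, `mean_edges`).
#' @export
tune_alpha <- function(data, alpha_grid = c(0.0005, 0.001, 0.005, 0.01, 0.05),
                       n_replicates = 45, subsample_frac = 0.8, seed = 1,
                       node_types = NULL, m_max = Inf) {
  if (!length(alpha_grid)) stop_invalid("empty alpha grid")
  if (!is_count(n_replicates, min = 2)) {
    stop_invalid("stability needs at least 2 replicates")
  }
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  node_types <- node_types %||% rep("metabolite", ncol(X))
  n <- nrow(X)
  m <- max(2L, floor(subsample_frac * n))
  subsets <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) sample.int(n, m))
  })
  grid <- sort(as.numeric(alpha_grid))
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    a <- grid[gi]
    amats <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      corr <- stats::cor(X[subsets[[r]], , drop = FALSE])
      sk <- skeleton_from_corr(corr, m, a, node_types, m_max)
      amats[[r]] <- orient_amat(sk$adj, sk$sepsets, node_types, corr = corr,
                                n = m, alpha = a)$amat
    }
    tot <- 0; cnt <- 0
    for (r1 in seq_len(n_replicates - 1)) {
      for (r2 in (r1 + 1):n_replicates) {
        tot <- tot + shd_amat(amats[[r1]], amats[[r2]])
        cnt <- cnt + 1
      }
    }
    edges <- mean(vapply(amats, function(am) {
      sum((am + t(am)) > 0) / 2
    }, numeric(1)))
    rows[[gi]] <- data.frame(alpha = a, mean_shd = tot / cnt,
                             mean_edges = edges)
  }
  stability <- do.call(rbind, rows)
  best <- which(stability$mean_shd <= min(stability$mean_shd) + 1e-12)
  chosen <- min(stability$alpha[best])
  structure(list(chosen_alpha = chosen, stability = stability),
            class = "alpha_tuning")
}

#' @export
print.alpha_tuning <- function(x, ...) {
  cat("<alpha_tuning> chosen alpha:", format(x$chosen_alpha), "\n")
  print(x$stability, row.names = FALSE)
  invisible(x)
}

#' Learn a genome-anchored causal network
#'
#' Composition of [learn_skeleton()] and [orient_edges()] over the
#' instrument scores and adjusted metabolites. With `instruments = NULL` the
#' search runs on metabolites alone and returns a CPDAG (possibly with
#' undirected edges) — valid but without the genetic anchoring of
#' directions.
#'
#' @param instruments An `instrument_set` (or numeric score matrix), or
#'   `NULL`.
#' @param m An [adjusted_metabolites()] or numeric matrix.
#' @param alpha CI-test level (default 0.001).
#' @param m_max Maximum conditioning-set size.
#' @return A [causal_network()].
#' @export
learn_gdag <- function(instruments, m, alpha = 0.001, m_max = Inf) {
  Y <- scan_values_matrix(m)
  if (is.null(instruments)) {
    data <- Y
    types <- rep("metabolite", ncol(Y))
  } else {
    S <- if (inherits(instruments, "instrument_set")) instruments$scores
         else as.matrix(instruments)
    stopifnot(nrow(S) == nrow(Y))
    data <- cbind(S, Y)
    types <- c(rep("instrument", ncol(S)), rep("metabolite", ncol(Y)))
  }
  sk <- learn_skeleton(data, alpha, node_types = types, m_max = m_max)
  orient_edges(sk)
}

#' Metabolite-level view of a network
#'
#' @param network A [causal_network()].
#' @return List: `metabolite_amat` (adjacency over metabolites only) and
#'   `instrument_parents` (per metabolite, the instruments pointing at it).
#' @export
metabolite_subgraph <- function(network) {
  stopifnot(inherits(network, "causal_network"))
  met <- network$nodes$name[network$nodes$type == "metabolite"]
  inst <- network$nodes$name[network$nodes$type == "instrument"]
  list(
    metabolite_amat = network$amat[met, met, drop = FALSE],
    instrument_parents = lapply(
      setNames(met, met),
      function(m) inst[network$amat[inst, m] == 1L]
    )
  )
}
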