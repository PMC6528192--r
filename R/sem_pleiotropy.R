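# Two-layer structural equation modeling over the learned network:
#   M_i = sum_j lambda_ij M_j + U_i       (metabolite parents)
#   U_i = sum_m gamma_im G_m + e          (gene burdens)
# Estimated equation-by-equation by OLS (path analysis), which is consistent
# for a recursive linear-Gaussian system. A gene is pleiotropic when its
# direct (gamma) effect survives conditioning on the metabolite parents for
# at least two metabolites.

#' Fit the two-layer structural equation model
#'
#' Stage 1: per metabolite, OLS on its directed metabolite parents in the
#' network gives the lambda estimates and residuals U. Stage 2: per
#' metabolite, OLS of U on the tested gene burdens (jointly) gives the gamma
#' estimates. Wald standard errors and p-values per coefficient.
#'
#' @param network A [causal_network()] whose metabolite subgraph is acyclic.
#' @param m An [adjusted_metabolites()] (or matrix) with every metabolite
#'   node of the network as a column.
#' @param burdens A [burden_matrix()] (or matrix).
#' @param genes Genes to test (must be burden columns). Default: all.
#' @param undirected `"error"` (default) aborts when an undirected
#'   metabolite-metabolite edge touches a fitted metabolite — orient or
#'   exclude it first; `"ignore"` treats unresolved edges as absent for
#'   conditioning.
#' @return Object of class `sem_fit`: `lambda` (`data.frame`: metabolite,
#'   parent, estimate, se, p_value), `gamma` (`data.frame`: metabolite, gene,
#'   estimate, se, p_value), `residual_variance`, `residuals` (U matrix), `n`.
#' @export
fit_sem <- function(network, m, burdens, genes = NULL,
                    undirected = c("error", "ignore")) {
  stopifnot(inherits(network, "causal_network"))
  undirected <- match.arg(undirected)
  Y <- scan_values_matrix(m)
  B <- scan_units_matrix(burdens)
  genes <- genes %||% colnames(B)
  if (!all(genes %in% colnames(B))) {
    stop_invalid("gene(s) absent from burdens: ",
                 paste(setdiff(genes, colnames(B)), collapse = ", "))
  }
  sub <- metabolite_subgraph(network)
  am <- sub$metabolite_amat
  mets <- rownames(am)
  if (!all(mets %in% colnames(Y))) {
    stop_invalid("metabolite(s) absent from data: ",
                 paste(setdiff(mets, colnames(Y)), collapse = ", "))
  }
  und <- am == 1L & t(am) == 1L
  if (undirected == "error" && any(und)) {
    idx <- which(und, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop_invalid(
      "undirected metabolite edge(s) incident to fitted metabolites: ",
      paste(sprintf("%s-%s", mets[idx[, 1]], mets[idx[, 2]]), collapse = ", "),
      "; orient them or exclude the metabolites (or use undirected = 'ignore')"
    )
  }
  dir_am <- am == 1L & t(am) == 0L
  if (!directed_part_acyclic(am)) {
    stop_invalid("cyclic metabolite subgraph; cannot fit a recursive SEM")
  }
  n <- nrow(Y)
  lam <- list(); gam <- list()
  U <- matrix(NA_real_, n, length(mets), dimnames = list(rownames(Y), mets))
  rv <- setNames(numeric(length(mets)), mets)
  for (i in mets) {
    parents <- mets[dir_am[, i]]
    st1 <- ols_fit(Y[, i], Y[, parents, drop = FALSE],
                   label = "metabolite parents")
    U[, i] <- st1$residuals
    rv[i] <- st1$sigma2
    if (length(parents)) {
      lam[[i]] <- data.frame(
        metabolite = i, parent = parents, estimate = st1$coef,
        se = st1$se, p_value = st1$p, stringsAsFactors = FALSE
      )
    }
    st2 <- ols_fit(U[, i], B[, genes, drop = FALSE], label = "gene burdens")
    if (length(genes)) {
      gam[[i]] <- data.frame(
        metabolite = i, gene = genes, estimate = st2$coef, se = st2$se,
        p_value = st2$p, stringsAsFactors = FALSE
      )
    }
  }
  bindrows <- function(l, cols) {
    if (length(l)) {
      out <- do.call(rbind, l); rownames(out) <- NULL; out
    } else {
      setNames(
        data.frame(character(0), character(0), numeric(0), numeric(0),
                   numeric(0), stringsAsFactors = FALSE), cols)
    }
  }
  structure(
    list(
      lambda = bindrows(lam, c("metabolite", "parent", "estimate", "se",
                               "p_value")),
      gamma = bindrows(gam, c("metabolite", "gene", "estimate", "se",
                              "p_value")),
      residual_variance = rv, residuals = U, n = n, genes = genes
    ),
    class = "sem_fit"
  )
}

# OLS with intercept; coefficient table for the non-intercept terms
ols_fit <- function(y, X, label = "design") {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    stop_invalid("collinear ", label, ": ", paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(Xi)
  sigma2 <- sum(res^2) / max(df, 1)
  XtXi <- chol2inv(qr.R(qx))
  se_all <- sqrt(sigma2 * diag(XtXi))[order(qx$pivot)]
  keep <- seq_len(ncol(Xi))[-1]
  tval <- cf[keep] / se_all[keep]
  list(
    coef = unname(cf[keep]), se = unname(se_all[keep]),
    p = unname(2 * stats::pt(-abs(tval), df = df)),
    residuals = res, sigma2 = sigma2
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> %d lambda edges, %d genes x %d metabolites, n = %d\n",
              nrow(x$lambda), length(x$genes),
              length(unique(x$gamma$metabolite)), x$n))
  invisible(x)
}

#' Direct-effect test for one gene on one metabolite
#'
#' Single-equation convenience: OLS of the metabolite on the given parents,
#' then OLS of the residual on the gene burden. With `parents` equal to the
#' metabolite's network parents and a single tested gene, this reproduces
#' the corresponding gamma row of [fit_sem()] exactly.
#'
#' @param gene Gene name (burden column).
#' @param metabolite Metabolite name.
#' @param parents Character vector of conditioning metabolites (may be
#'   empty: the test reduces to the marginal scan).
#' @param m Adjusted metabolites (or matrix).
#' @param burdens Burden matrix.
#' @return List: `beta`, `se`, `p_value`.
#' @export
direct_effect_test <- function(gene, metabolite, parents, m, burdens) {
  Y <- scan_values_matrix(m)
  B <- scan_units_matrix(burdens)
  missing_nodes <- setdiff(c(metabolite, parents), colnames(Y))
  if (length(missing_nodes)) {
    stop_invalid("node(s) absent from data: ",
                 paste(missing_nodes, collapse = ", "))
  }
  if (!(gene %in% colnames(B))) stop_invalid("gene absent from burdens: ", gene)
  st1 <- ols_fit(Y[, metabolite], Y[, parents, drop = FALSE],
                 label = "parents")
  st2 <- ols_fit(st1$residuals, B[, gene, drop = FALSE], label = "gene burden")
  list(beta = st2$coef, se = st2$se, p_value = st2$p)
}

#' Classify a gene's metabolite effects as direct or mediated
#'
#' Per candidate metabolite the verdict is `direct` when the gene's gamma
#' coefficient stays significant after conditioning on the metabolite's
#' network parents (Bonferroni over the gene's candidate set), `mediated`
#' when it does not but a directed path from one of the gene's direct-verdict
#' metabolites reaches it, and `not_significant` otherwise. The gene is
#' called pleiotropic when it has at least two direct verdicts.
#'
#' @param gene Gene name.
#' @param candidate_metabolites Metabolites the gene was selected for.
#' @param network The [causal_network()] used in the fit.
#' @param fit The [fit_sem()] result (must include `gene`).
#' @param alpha Per-gene family-wise level (default 0.05, Bonferroni over
#'   the candidates).
#' @param m,burdens Optional data to also report the marginal
#'   (unconditioned) effect per candidate.
#' @return Object of class `pleiotropy_call`: `table` (`data.frame` with
#'   verdicts and before/after statistics), `is_pleiotropic`, `gene`.
#' @export
assess_pleiotropy <- function(gene, candidate_metabolites, network, fit,
                              alpha = 0.05, m = NULL, burdens = NULL) {
  stopifnot(inherits(fit, "sem_fit"), inherits(network, "causal_network"))
  if (!(gene %in% fit$genes)) {
    stop_invalid("gene ", gene, " was not tested in the SEM fit")
  }
  mets_net <- network$nodes$name[network$nodes$type == "metabolite"]
  absent <- setdiff(candidate_metabolites, mets_net)
  if (length(absent)) {
    stop_invalid("metabolite(s) absent from network: ",
                 paste(absent, collapse = ", "))
  }
  thr <- alpha / length(candidate_metabolites)
  g <- fit$gamma[fit$gamma$gene == gene &
                   fit$gamma$metabolite %in% candidate_metabolites, ,
                 drop = FALSE]
  if (nrow(g) < length(candidate_metabolites)) {
    stop_invalid("SEM fit lacks gamma rows for: ",
                 paste(setdiff(candidate_metabolites, g$metabolite),
                       collapse = ", "))
  }
  g <- g[match(candidate_metabolites, g$metabolite), , drop = FALSE]
  verdict <- ifelse(g$p_value <= thr, "direct", "not_significant")
  # mediated: a directed path from a direct-verdict metabolite reaches it
  am <- metabolite_subgraph(network)$metabolite_amat
  dir_am <- (am == 1L & t(am) == 0L) * 1L
  reach <- dag_reachable(dir_am)
  direct_mets <- g$metabolite[verdict == "direct"]
  for (r in which(verdict == "not_significant")) {
    if (length(direct_mets) &&
        any(reach[direct_mets, g$metabolite[r]])) {
      verdict[r] <- "mediated"
    }
  }
  tab <- data.frame(
    gene = gene, metabolite = g$metabolite,
    conditional_beta = g$estimate, conditional_se = g$se,
    conditional_p = g$p_value, verdict = verdict,
    stringsAsFactors = FALSE
  )
  if (!is.null(m) && !is.null(burdens)) {
    marg <- vapply(tab$metabolite, function(met) {
      st <- direct_effect_test(gene, met, character(0), m, burdens)
      c(st$beta, st$p_value)
    }, numeric(2))
    tab$marginal_beta <- marg[1, ]
    tab$marginal_p <- marg[2, ]
  } else {
    tab$marginal_beta <- NA_real_
    tab$marginal_p <- NA_real_
  }
  structure(
    list(gene = gene, table = tab,
         is_pleiotropic = sum(verdict == "direct") >= 2, alpha = alpha),
    class = "pleiotropy_call"
  )
}

#' @export
print.pleiotropy_call <- function(x, ...) {
  cat(sprintf("<pleiotropy_call> %s: %s\n", x$gene,
              if (x$is_pleiotropic) "pleiotropic (>= 2 direct effects)"
              else "not pleiotropic"))
  print(x$table[c("metabolite", "conditional_beta", "conditional_p",
                  "verdict")], row.names = FALSE)
  invisible(x)
}
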