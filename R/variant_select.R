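# LoF-metabolite association: gene burdens, Bonferroni-controlled
# single-variant/burden scans, L1-penalized joint selection with BIC tuning,
# intersection of the two routes, and replication in independent samples.

#' Gene burden matrix
#'
#' Per-sample sum of alternate-allele counts over each gene's variants.
#'
#' @param g A [genotype_matrix()].
#' @param gene_map Optional named character vector variant id -> gene;
#'   defaults to the genotype metadata. Every variant must map to exactly
#'   one gene.
#' @return List of class `burden_matrix`: `values` (samples x genes integer
#'   matrix) and `gene_meta` (list of variant ids per gene).
#' @export
gene_burden <- function(g, gene_map = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(gene_map)) {
    gene_map <- setNames(g$variant_meta$gene, g$variant_meta$id)
  }
  ids <- colnames(g$dosages)
  unmapped <- setdiff(ids, names(gene_map))
  if (length(unmapped)) {
    stop_invalid("variant(s) not mapped to a gene: ",
                 paste(unmapped, collapse = ", "))
  }
  genes <- gene_map[ids]
  b <- t(rowsum(t(g$dosages), group = genes))
  b <- b[, sort(colnames(b)), drop = FALSE]
  structure(
    list(values = b, gene_meta = split(ids, genes)),
    class = "burden_matrix"
  )
}

#' @export
print.burden_matrix <- function(x, ...) {
  cat(sprintf("<burden_matrix> %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' `alpha / (n_metabolites * n_variants)`: the family-wise threshold for a
#' scan of every variant against every metabolite. With 122 metabolites, the
#' AA (372 LoF variants) and EA (451) scans give 1.10e-6 and 9.09e-7.
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param n_metabolites,n_variants Positive test-family dimensions.
#' @return The per-test significance level.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_metabolites, n_variants) {
  if (!is_count(n_metabolites) || !is_count(n_variants)) {
    stop_invalid("n_metabolites and n_variants must be positive integers")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_invalid("alpha must be in (0, 1]")
  }
  alpha / (n_metabolites * n_variants)
}

#' Single-unit association scan
#'
#' Simple linear regression of every metabolite on every unit (variant
#' dosage or gene burden), vectorized over the full units x metabolites
#' grid. Betas are in metabolite-SD units when the metabolites arrive
#' standardized (the usual case: residuals from [adjust_covariates()] of
#' standardized transforms).
#'
#' @param units A [genotype_matrix()], [burden_matrix()] or plain numeric
#'   matrix (samples x units).
#' @param m An [adjusted_metabolites()] or numeric matrix, same samples.
#' @param threshold Per-test significance level used to flag selections
#'   (e.g. [bonferroni_threshold()]).
#' @return `data.frame` of class `association_result` with columns `unit`,
#'   `metabolite`, `beta`, `se`, `p_value`, `n_carriers`, `selected`.
#'   Monomorphic units are skipped with a warning.
#' @export
single_variant_scan <- function(units, m, threshold = 0.05) {
  U <- scan_units_matrix(units)
  Y <- scan_values_matrix(m)
  if (nrow(U) != nrow(Y)) stop_invalid("units and metabolites disagree on samples")
  mono <- apply(U, 2, function(x) stats::var(x) == 0)
  if (any(mono)) {
    warning(sprintf("skipping %d monomorphic unit(s): %s", sum(mono),
                    paste(utils::head(colnames(U)[mono], 5), collapse = ", ")),
            call. = FALSE)
    U <- U[, !mono, drop = FALSE]
  }
  if (!ncol(U)) {
    return(empty_scan_result())
  }
  st <- scan_stats(U, Y)
  out <- data.frame(
    unit = rep(colnames(U), times = ncol(Y)),
    metabolite = rep(colnames(Y), each = ncol(U)),
    beta = as.vector(st$beta),
    se = as.vector(st$se),
    p_value = as.vector(st$p),
    n_carriers = rep(colSums(U > 0), times = ncol(Y)),
    stringsAsFactors = FALSE
  )
  out$selected <- out$p_value <= threshold
  class(out) <- c("association_result", class(out))
  attr(out, "threshold") <- threshold
  out
}

# closed-form simple-regression statistics for all (unit, metabolite) pairs
scan_stats <- function(U, Y) {
  n <- nrow(U)
  R <- suppressWarnings(stats::cor(U, Y))
  R[!is.finite(R)] <- 0
  sdu <- apply(U, 2, stats::sd)
  sdy <- apply(Y, 2, stats::sd)
  beta <- R * (rep(1 / sdu, times = ncol(Y)) *
               matrix(sdy, nrow = ncol(U), ncol = ncol(Y), byrow = TRUE))
  r2 <- pmin(R^2, 1 - 1e-15)
  tstat <- R * sqrt((n - 2) / (1 - r2))
  se <- ifelse(tstat == 0, beta * 0 +
                 sdy[col(R)] / (sdu[row(R)] * sqrt(n - 2)), beta / tstat)
  # se for R == 0: sd_y/(sd_x*sqrt(n-2)) is the correct limit
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(beta = beta, se = se, p = p)
}

scan_units_matrix <- function(units) {
  if (inherits(units, "genotype_matrix")) units$dosages
  else if (inherits(units, "burden_matrix")) units$values
  else as.matrix(units)
}

scan_values_matrix <- function(m) {
  if (inherits(m, "adjusted_metabolites")) m$residuals
  else if (inherits(m, "metabolite_matrix")) m$values
  else as.matrix(m)
}

empty_scan_result <- function() {
  out <- data.frame(
    unit = character(0), metabolite = character(0), beta = numeric(0),
    se = numeric(0), p_value = numeric(0), n_carriers = integer(0),
    selected = logical(0), stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", class(out))
  out
}

#' L1-penalized joint selection over all units (CCRS-style)
#'
#' Fits, for each value of the tuning grid, an L1-penalized linear model of
#' one metabolite on *all* units simultaneously (standardized design), then
#' refits the selected support by OLS and scores it with BIC. The support of
#' the minimum-BIC fit is returned; BIC ties break toward the smaller
#' support (parsimony). This is a lasso-based stand-in for convex-concave
#' penalized selection: joint modelling over all units, a small tuning grid,
#' and min-BIC tuning.
#'
#' @param units A [burden_matrix()], [genotype_matrix()] or numeric matrix.
#' @param metabolite Numeric vector (standardized metabolite).
#' @param tuning_grid Penalty grid (default `c(1.5, 0.3, 0.01)` on the
#'   `glmnet` lambda scale).
#' @return List: `selected` (unit names, possibly empty), `coefficients`
#'   (OLS refit on the support), `chosen_tuning`, `bic` (per grid value).
#' @export
ccrs_select <- function(units, metabolite, tuning_grid = c(1.5, 0.3, 0.01)) {
  if (!length(tuning_grid)) stop_invalid("empty tuning grid")
  X <- scan_units_matrix(units)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- as.numeric(metabolite)
  stopifnot(nrow(X) == length(y))
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  grid <- sort(as.numeric(tuning_grid), decreasing = TRUE)
  if (ncol(X) < 2) {
    # degenerate design: glmnet needs >= 2 columns; fall back to
    # soft-thresholding the single standardized coefficient
    supports <- lapply(grid, function(lam) {
      if (!ncol(X)) return(character(0))
      xs <- as.numeric(scale(X[, 1])) * sqrt(n / (n - 1))
      b <- mean(xs * (y - mean(y)))
      if (abs(b) > lam) colnames(X) else character(0)
    })
  } else {
    fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = grid,
                          standardize = TRUE, thresh = 1e-12)
    cf <- as.matrix(stats::coef(fit))[-1, , drop = FALSE]
    supports <- lapply(seq_along(grid), function(k) {
      rownames(cf)[cf[, k] != 0]
    })
  }
  bic <- vapply(supports, function(s) bic_refit(X, y, s), numeric(1))
  sizes <- lengths(supports)
  best <- which(bic <= min(bic) + 1e-9)
  best <- best[which.min(sizes[best])]
  sel <- supports[[best]]
  coefs <- if (length(sel)) {
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    setNames(fit$coefficients[-1], sel)
  } else {
    setNames(numeric(0), character(0))
  }
  list(selected = sel, coefficients = coefs, chosen_tuning = grid[best],
       bic = setNames(bic, format(grid)))
}

# BIC of the OLS refit on a support (relaxed form; scale-invariant)
bic_refit <- function(X, y, support) {
  n <- length(y)
  Xs <- cbind(1, X[, support, drop = FALSE])
  rss <- sum(stats::lm.fit(Xs, y)$residuals^2)
  n * log(rss / n) + (length(support) + 1) * log(n)
}

#' Selection result from a scan
#'
#' @param scan An `association_result` from [single_variant_scan()].
#' @param method Provenance label.
#' @param gene_map Optional variant -> gene map; when given, pairs are
#'   collapsed to the gene level (taking the most significant variant per
#'   gene-metabolite pair).
#' @return A [selection_result()].
#' @export
as_selection <- function(scan, method = "single", gene_map = NULL) {
  sel <- scan[scan$selected, , drop = FALSE]
  if (!is.null(gene_map) && nrow(sel)) {
    sel$gene <- unname(gene_map[sel$unit])
    sel <- sel[order(sel$p_value), , drop = FALSE]
    sel <- sel[!duplicated(paste(sel$gene, sel$metabolite, sep = "\r")), ,
               drop = FALSE]
    sel$variant <- sel$unit
    sel$unit <- sel$gene
  }
  rownames(sel) <- NULL
  selection_result(as.data.frame(sel), method)
}

#' Intersect two selections
#'
#' Keeps the (unit, metabolite) pairs present in both selections; provenance
#' records both methods. The intersection is a subset of each input (it can
#' only reduce the selection count, which is the point: both routes must
#' agree before a pair is carried forward).
#'
#' @param a,b [selection_result()]s.
#' @return A [selection_result()].
#' @export
intersect_selections <- function(a, b) {
  stopifnot(inherits(a, "selection_result"), inherits(b, "selection_result"))
  ka <- paste(a$pairs$unit, a$pairs$metabolite, sep = "\r")
  kb <- paste(b$pairs$unit, b$pairs$metabolite, sep = "\r")
  keep <- ka %in% kb
  pairs <- a$pairs[keep, , drop = FALSE]
  prov_b <- b$pairs$provenance[match(ka[keep], kb)]
  rownames(pairs) <- NULL
  out <- selection_result(
    pairs[setdiff(names(pairs), "provenance")],
    method = if (nrow(pairs)) paste(pairs$provenance, prov_b, sep = "+")
             else character(0)
  )
  out
}

#' Replication of selected pairs in an independent validation set
#'
#' Re-tests each selected (unit, metabolite) pair by simple linear
#' regression on the validation samples and applies Bonferroni over the
#' number of replication tests. Units absent from the validation data are
#' reported with `NA`.
#'
#' @param selection A [selection_result()].
#' @param validation List with `units` (genotype/burden/matrix) and `m`
#'   (adjusted metabolites or matrix) for the validation samples.
#' @param alpha Family-wise level for the replication family (default 0.05).
#' @return `data.frame`: `unit`, `metabolite`, `beta`, `se`, `p_value`,
#'   `replicated` (`NA` when untestable).
#' @export
replicate_findings <- function(selection, validation, alpha = 0.05) {
  stopifnot(inherits(selection, "selection_result"))
  pairs <- selection$pairs
  if (!nrow(pairs)) {
    return(data.frame(unit = character(0), metabolite = character(0),
                      beta = numeric(0), se = numeric(0),
                      p_value = numeric(0), replicated = logical(0)))
  }
  U <- scan_units_matrix(validation$units)
  Y <- scan_values_matrix(validation$m)
  out <- pairs[c("unit", "metabolite")]
  out$beta <- out$se <- out$p_value <- NA_real_
  testable <- out$unit %in% colnames(U) & out$metabolite %in% colnames(Y)
  thr <- alpha / max(1L, sum(testable))
  for (r in which(testable)) {
    x <- U[, out$unit[r]]
    if (stats::var(x) == 0) next
    st <- scan_stats(cbind(x), cbind(Y[, out$metabolite[r]]))
    out$beta[r] <- st$beta; out$se[r] <- st$se; out$p_value[r] <- st$p
  }
  out$replicated <- out$p_value <= thr
  attr(out, "threshold") <- thr
  out
}

#' Two-route LoF-metabolite selection
#'
#' Convenience wrapper: gene-burden scan at the Bonferroni threshold, plus
#' per-metabolite L1/BIC joint selection over gene burdens, intersected at
#' the gene level.
#'
#' @param burdens A [burden_matrix()].
#' @param m An [adjusted_metabolites()].
#' @param alpha Family-wise level for the scan route.
#' @param tuning_grid Penalty grid for the penalized route.
#' @return List: `selection` (intersection), `scan` (full scan results),
#'   `scan_selection`, `ccrs_selection`, `threshold`.
#' @export
select_lof_associations <- function(burdens, m, alpha = 0.05,
                                    tuning_grid = c(1.5, 0.3, 0.01)) {
  Y <- scan_values_matrix(m)
  thr <- bonferroni_threshold(alpha, ncol(Y), ncol(burdens$values))
  scan <- single_variant_scan(burdens, m, threshold = thr)
  sel_scan <- as_selection(scan, method = "single")
  cc <- lapply(colnames(Y), function(met) {
    ccrs_select(burdens, Y[, met], tuning_grid)$selected
  })
  cc_pairs <- data.frame(
    unit = unlist(cc),
    metabolite = rep(colnames(Y), times = lengths(cc)),
    stringsAsFactors = FALSE
  )
  sel_ccrs <- selection_result(cc_pairs, "ccrs")
  list(
    selection = intersect_selections(sel_scan, sel_ccrs),
    scan = scan, scan_selection = sel_scan, ccrs_selection = sel_ccrs,
    threshold = thr
  )
}
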