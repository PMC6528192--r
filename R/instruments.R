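# Compression of genome variation into strong, mutually independent
# instrumental variables: LD proxy clustering then PCA, keeping the leading
# components that explain more than the variance threshold (default 90%).

#' Linkage-disequilibrium (correlation) matrix
#'
#' Pearson correlation of dosage columns. Monomorphic variants have no
#' defined correlation; their entries are reported as 0 with a warning (the
#' diagonal stays 1).
#'
#' @param g A [genotype_matrix()] or numeric dosage matrix.
#' @return Symmetric variant x variant correlation matrix.
#' @export
ld_matrix <- function(g) {
  X <- scan_units_matrix(g)
  mono <- apply(X, 2, stats::var) == 0
  r <- suppressWarnings(stats::cor(X))
  if (any(mono)) {
    warning(sprintf("%d monomorphic variant(s); correlations reported as 0",
                    sum(mono)), call. = FALSE)
    r[mono, ] <- 0
    r[, mono] <- 0
  }
  diag(r) <- 1
  r
}

#' Cluster near-perfect LD proxies
#'
#' Average-linkage hierarchical clustering on distance `1 - |r|`, cut at
#' height `1 - r_threshold`, so variants whose (average) absolute pairwise
#' correlation exceeds the threshold collapse into one cluster. Unsigned
#' correlation is used because allele coding flips are arbitrary. One
#' representative per cluster: the variant with the highest MAF, ties broken
#' by the lowest genomic position (then lexicographic id).
#'
#' @param ld Correlation matrix from [ld_matrix()].
#' @param r_threshold Proxy threshold in `(0, 1)` (default 0.80).
#' @param maf Named numeric vector of MAFs (names = variant ids); defaults
#'   to 0 for all, making ties position-based.
#' @param pos Named numeric vector of positions for tie-breaking.
#' @return Named list of class `proxy_map`: representative id -> character
#'   vector of all member ids (including itself).
#' @export
cluster_proxies <- function(ld, r_threshold = 0.80, maf = NULL, pos = NULL) {
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold >= 1) {
    stop_invalid("r_threshold must be in (0, 1)")
  }
  ids <- colnames(ld)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(ncol(ld)))
  maf <- maf %||% setNames(rep(0, length(ids)), ids)
  pos <- pos %||% setNames(seq_along(ids), ids)
  if (length(ids) == 1L) {
    out <- setNames(list(ids), ids)
    class(out) <- "proxy_map"
    return(out)
  }
  d <- stats::as.dist(1 - abs(ld))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = 1 - r_threshold)
  groups <- split(ids, cl)
  reps <- vapply(groups, function(g) {
    g[order(-maf[g], pos[g], g)][1]
  }, character(1))
  out <- setNames(groups, reps)
  out <- out[order(match(names(out), ids))]
  class(out) <- "proxy_map"
  out
}

#' Build principal-component instruments
#'
#' PCA of the standardized dosages of the cluster representatives; the
#' smallest set of leading components whose cumulative variance exceeds
#' `var_threshold` is retained. Scores are standardized (instrument columns
#' are exactly orthogonal), loadings orthonormal.
#'
#' @param g_repr A [genotype_matrix()] or dosage matrix restricted to
#'   representatives (run [cluster_proxies()] first), or any numeric matrix.
#' @param var_threshold Cumulative-variance threshold (default 0.90: keep
#'   components responsible for *more than* 90\% of the variation).
#' @param proxy_map Optional [cluster_proxies()] result stored for audit.
#' @return An object of class `instrument_set`: `scores` (samples x PCs,
#'   standardized), `loadings` (variants x PCs), `variance_explained`,
#'   `cum_variance`, `n_retained`, `proxy_map`.
#' @export
build_instruments <- function(g_repr, var_threshold = 0.90, proxy_map = NULL) {
  X <- scan_units_matrix(g_repr)
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold >= 1) {
    stop_invalid("var_threshold must be in (0, 1)")
  }
  zero <- apply(X, 2, stats::var) == 0
  if (any(zero)) {
    stop_invalid("zero-variance column(s): ",
                 paste(colnames(X)[zero], collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) {
    warning("fewer samples than variants; PCA still valid but unstable",
            call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cve <- cumsum(ve)
  k <- which(cve > var_threshold)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- scale(scores)
  # degenerate trailing PCs (zero variance) cannot be retained: cve hits the
  # threshold strictly before them whenever rank < ncol
  colnames(scores) <- sprintf("PC%02d", seq_len(k))
  structure(
    list(
      scores = scores,
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      variance_explained = ve, cum_variance = cve, n_retained = k,
      proxy_map = proxy_map
    ),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> %d PCs retained (cumulative variance %.1f%%) from %d variants\n",
    x$n_retained, 100 * x$cum_variance[x$n_retained], nrow(x$loadings)
  ))
  invisible(x)
}

#' LD-prune genotypes and build instruments in one step
#'
#' @param g A [genotype_matrix()].
#' @param r_threshold Proxy clustering threshold.
#' @param var_threshold PCA cumulative-variance threshold.
#' @return An `instrument_set` (with the proxy map recorded).
#' @export
genotypes_to_instruments <- function(g, r_threshold = 0.80,
                                     var_threshold = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- !g$variant_meta$monomorphic
  X <- g$dosages[, keep, drop = FALSE]
  meta <- g$variant_meta[keep, , drop = FALSE]
  ld <- ld_matrix(X)
  pm <- cluster_proxies(
    ld, r_threshold,
    maf = setNames(meta$maf, meta$id),
    pos = setNames(meta$pos, meta$id)
  )
  build_instruments(X[, names(pm), drop = FALSE], var_threshold,
                    proxy_map = pm)
}
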