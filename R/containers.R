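# S3 containers shared across the pipeline stages.

#' Genotype matrix container
#'
#' Bundles a sample x variant allele-count (dosage) matrix with per-variant
#' metadata. Variant ids follow the `chrom:pos:ref:alt` convention (1-based
#' positions); each variant is assigned to exactly one gene.
#'
#' @param dosages Integer matrix (samples x variants), entries in `{0,1,2}`
#'   or `NA`; rownames are sample ids, colnames variant ids.
#' @param variant_meta `data.frame` with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `maf` and logical `monomorphic`; one row per column of
#'   `dosages`, in the same order.
#' @param ancestry Optional numeric matrix of latent ancestry factor scores
#'   (samples x factors) recorded by the simulator; `NULL` for real data.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_meta, ancestry = NULL) {
  stopifnot(is.matrix(dosages), is.data.frame(variant_meta))
  if (ncol(dosages) != nrow(variant_meta)) {
    stop_invalid("dosages and variant_meta disagree on variant count")
  }
  if (anyDuplicated(rownames(dosages))) stop_invalid("sample ids not unique")
  if (anyDuplicated(variant_meta$id)) stop_invalid("variant ids not unique")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop_invalid("dosages must be allele counts in {0,1,2} or NA")
  colnames(dosages) <- variant_meta$id
  structure(
    list(dosages = dosages, variant_meta = variant_meta, ancestry = ancestry),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants, %d genes, MAF %.3f-%.3f\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variant_meta$gene)),
    min(x$variant_meta$maf), max(x$variant_meta$maf)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Metabolite abundance container
#'
#' @param values Numeric matrix (samples x metabolites), `NA` for missing;
#'   rownames are sample ids, colnames metabolite names.
#' @param meta `data.frame` with columns `metabolite`, `pathway`,
#'   `sub_pathway` (one row per column of `values`).
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, meta = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("M%02d", seq_len(ncol(values)))
  }
  if (is.null(meta)) {
    meta <- data.frame(
      metabolite = colnames(values), pathway = NA_character_,
      sub_pathway = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(colnames(values))) stop_invalid("metabolite names not unique")
  if (anyDuplicated(rownames(values))) stop_invalid("sample ids not unique")
  stopifnot(nrow(meta) == ncol(values))
  structure(list(values = values, meta = meta), class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf(
    "<metabolite_matrix> %d samples x %d metabolites (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)

#' Covariate-adjusted metabolite container
#'
#' Residuals of each (transformed, standardized) metabolite after ordinary
#' least squares on the adjustment covariates; the residual columns are
#' orthogonal to every covariate by construction.
#'
#' @param residuals Numeric matrix (samples x metabolites).
#' @param transform_log Named character vector of per-metabolite transform
#'   labels (`identity`, `log`, `sqrt`, `square`).
#' @param adjustment_covariates Character vector of covariate names used.
#' @param meta Metabolite metadata `data.frame` carried through.
#' @return An object of class `adjusted_metabolites`.
#' @export
adjusted_metabolites <- function(residuals, transform_log,
                                 adjustment_covariates, meta = NULL) {
  stopifnot(is.matrix(residuals))
  structure(
    list(
      residuals = residuals, transform_log = transform_log,
      adjustment_covariates = adjustment_covariates,
      meta = meta
    ),
    class = "adjusted_metabolites"
  )
}

#' @export
print.adjusted_metabolites <- function(x, ...) {
  cat(sprintf(
    "<adjusted_metabolites> %d samples x %d metabolites; adjusted for: %s\n",
    nrow(x$residuals), ncol(x$residuals),
    paste(x$adjustment_covariates, collapse = ", ")
  ))
  invisible(x)
}

#' Causal network over instruments and metabolites
#'
#' Mixed graph produced by the constraint-based search. Internally encoded as
#' an adjacency matrix `amat` where `amat[i, j] == 1` and `amat[j, i] == 0`
#' means a directed edge i -> j, and `amat[i, j] == amat[j, i] == 1` an
#' undirected edge. Instrument nodes never have in-edges.
#'
#' @param amat Square 0/1 integer matrix with dimnames = node names.
#' @param node_types Character vector (`"instrument"` or `"metabolite"`),
#'   one per node.
#' @param sepsets Named list of separating sets recorded during skeleton
#'   search (names are `"i|j"` pair keys of node names).
#' @param alpha Conditional-independence test level used.
#' @return An object of class `causal_network`.
#' @export
causal_network <- function(amat, node_types, sepsets = list(), alpha = NA_real_) {
  stopifnot(is.matrix(amat), nrow(amat) == ncol(amat))
  if (is.null(rownames(amat))) stop_invalid("amat must have node names")
  stopifnot(length(node_types) == nrow(amat))
  storage.mode(amat) <- "integer"
  inst <- node_types == "instrument"
  if (any(amat[, inst, drop = FALSE] != 0L)) {
    stop_invalid("no edge may point into an instrument node")
  }
  net <- structure(
    list(
      amat = amat,
      nodes = data.frame(
        name = rownames(amat), type = node_types, stringsAsFactors = FALSE
      ),
      sepsets = sepsets, alpha_used = alpha, acyclic = NA
    ),
    class = "causal_network"
  )
  net$acyclic <- directed_part_acyclic(amat)
  if (!net$acyclic) {
    warning("directed part of the learned network contains a cycle ",
            "(conflicting finite-sample orientations)", call. = FALSE)
  }
  net
}

# acyclicity of the fully directed subgraph (undirected edges excluded)
directed_part_acyclic <- function(amat) {
  d <- amat == 1L & t(amat) == 0L
  mode(d) <- "integer"
  # peel nodes with no incoming directed edge
  remaining <- rep(TRUE, nrow(d))
  repeat {
    indeg <- colSums(d[remaining, remaining, drop = FALSE])
    if (!length(indeg)) return(TRUE)
    src <- names(indeg)[indeg == 0]
    if (!length(src)) return(FALSE)
    remaining[match(src, rownames(d))] <- FALSE
    if (!any(remaining)) return(TRUE)
  }
}

#' @export
print.causal_network <- function(x, ...) {
  el <- network_edges(x)
  cat(sprintf(
    "<causal_network> %d nodes (%d instruments), %d directed / %d undirected edges, alpha = %s\n",
    nrow(x$nodes), sum(x$nodes$type == "instrument"),
    sum(el$type == "directed"), sum(el$type == "undirected"),
    format(x$alpha_used)
  ))
  invisible(x)
}

#' Edge list of a causal network
#'
#' @param network A `causal_network`.
#' @return `data.frame` with columns `source`, `target`, `type`
#'   (`directed`/`undirected`), `source_type`, `target_type`. Undirected
#'   edges appear once, with the lexicographically smaller node as `source`.
#' @export
network_edges <- function(network) {
  amat <- network$amat
  nm <- rownames(amat)
  ty <- setNames(network$nodes$type, nm)
  out <- list()
  idx <- which(amat == 1L, arr.ind = TRUE)
  seen <- character(0)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (amat[j, i] == 1L) {
        k <- pair_key(nm[i], nm[j])
        if (k %in% seen) next
        seen <- c(seen, k)
        a <- sort(c(nm[i], nm[j]))
        out[[length(out) + 1L]] <- data.frame(
          source = a[1], target = a[2], type = "undirected",
          stringsAsFactors = FALSE
        )
      } else {
        out[[length(out) + 1L]] <- data.frame(
          source = nm[i], target = nm[j], type = "directed",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  el <- if (length(out)) do.call(rbind, out) else {
    data.frame(source = character(0), target = character(0),
               type = character(0), stringsAsFactors = FALSE)
  }
  el$source_type <- unname(ty[el$source])
  el$target_type <- unname(ty[el$target])
  el[order(el$source, el$target), , drop = FALSE]
}

#' Selection result (unit, metabolite) pair set
#'
#' @param pairs `data.frame` with columns `unit`, `metabolite` and optionally
#'   `gene` plus statistics columns.
#' @param method Character label(s) recording which selection method produced
#'   each pair.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(pairs, method) {
  stopifnot(is.data.frame(pairs), all(c("unit", "metabolite") %in% names(pairs)))
  if (length(method) == 1L) method <- rep(method, nrow(pairs))
  stopifnot(length(method) == nrow(pairs))
  pairs$provenance <- method
  key <- paste(pairs$unit, pairs$metabolite, sep = "\r")
  if (anyDuplicated(key)) stop_invalid("duplicate (unit, metabolite) pairs")
  structure(list(pairs = pairs), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d (unit, metabolite) pairs [%s]\n",
              nrow(x$pairs),
              paste(unique(x$pairs$provenance), collapse = "; ")))
  invisible(x)
}
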