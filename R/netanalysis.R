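# Module (community) detection on the metabolite network, module
# neighbourhoods, and overlay of the LoF selection results.

#' Detect densely connected metabolite modules
#'
#' Community detection on the undirected skeleton of the metabolite
#' subgraph. The default greedy modularity optimization is deterministic;
#' isolated metabolites become singleton modules.
#'
#' @param network A [causal_network()] with at least one metabolite edge.
#' @param method `"greedy_modularity"` (the only method).
#' @param resolution Resolution parameter; 1 (default) uses fast-greedy
#'   modularity, other values switch to Leiden optimization of modularity at
#'   that resolution (run under a fixed internal seed for determinism).
#' @return Object of class `module_partition`: `assignment` (named integer
#'   vector metabolite -> module id), `neighbors` (list per module),
#'   `quality` (modularity score).
#' @export
detect_modules <- function(network, method = "greedy_modularity",
                           resolution = 1) {
  stopifnot(inherits(network, "causal_network"))
  method <- match.arg(method, "greedy_modularity")
  am <- metabolite_subgraph(network)$metabolite_amat
  sym <- (am + t(am)) > 0
  if (!any(sym)) stop_invalid("no metabolite edges; nothing to cluster")
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
  cl <- if (resolution == 1) {
    igraph::cluster_fast_greedy(g)
  } else {
    with_seed(20240101, {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution, n_iterations = 10)
    })
  }
  assignment <- stats::setNames(igraph::membership(cl), rownames(sym))
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  # deterministic coarsening: merge community pairs while modularity does
  # not decrease (breaks numerical ties toward the coarsest partition,
  # e.g. a single clique stays one module)
  repeat {
    q0 <- igraph::modularity(g, assignment)
    ids <- sort(unique(assignment))
    merged <- FALSE
    if (length(ids) > 1) {
      for (a in seq_len(length(ids) - 1)) {
        for (b in (a + 1):length(ids)) {
          cand <- assignment
          cand[cand == ids[b]] <- ids[a]
          if (igraph::modularity(g, cand) >= q0 - 1e-12) {
            assignment <- cand
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  assignment <- stats::setNames(match(assignment, sort(unique(assignment))),
                                names(assignment))
  part <- structure(
    list(assignment = assignment, neighbors = NULL,
         quality = igraph::modularity(g, assignment)),
    class = "module_partition"
  )
  part$neighbors <- lapply(
    stats::setNames(nm = sort(unique(assignment))),
    function(mid) module_neighbors(part, network, mid)
  )
  part
}

#' @export
print.module_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("<module_partition> %d modules over %d metabolites, modularity %.3f\n",
              k, length(x$assignment), x$quality))
  invisible(x)
}

#' Metabolites adjacent to (but outside) a module
#'
#' @param partition A `module_partition`.
#' @param network The [causal_network()] it was computed on.
#' @param module_id Module id.
#' @return Character vector of neighbour metabolites (edges in either
#'   direction count).
#' @export
module_neighbors <- function(partition, network, module_id) {
  stopifnot(inherits(partition, "module_partition"))
  if (!(module_id %in% partition$assignment)) {
    stop_invalid("unknown module id: ", module_id)
  }
  am <- metabolite_subgraph(network)$metabolite_amat
  sym <- (am + t(am)) > 0
  members <- names(partition$assignment)[partition$assignment == module_id]
  outside <- setdiff(rownames(sym), members)
  touching <- rowSums(sym[outside, members, drop = FALSE]) > 0
  sort(outside[touching])
}

#' Overlay LoF selection results on the module partition
#'
#' @param partition A `module_partition`.
#' @param selections A [selection_result()] of (gene, metabolite) pairs.
#' @param pleiotropy Optional list of [assess_pleiotropy()] calls; verdicts
#'   are joined in when given.
#' @param metabolite_meta Metabolite metadata `data.frame` (`metabolite`,
#'   `pathway`) for the pathway count table.
#' @return List of class `module_overlay`: `report` (`data.frame`:
#'   metabolite, module, genes, verdicts) and `pathway_counts`
#'   (`data.frame`: pathway, n_metabolites — distinct influenced metabolites
#'   per pathway; the counts sum to the number of distinct influenced
#'   metabolites).
#' @export
lof_module_overlay <- function(partition, selections, pleiotropy = NULL,
                               metabolite_meta = NULL) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(selections, "selection_result"))
  mets <- names(partition$assignment)
  pairs <- selections$pairs
  verdict_of <- function(gene, met) {
    if (is.null(pleiotropy)) return(NA_character_)
    for (pc in pleiotropy) {
      if (pc$gene == gene && met %in% pc$table$metabolite) {
        return(pc$table$verdict[pc$table$metabolite == met])
      }
    }
    NA_character_
  }
  report <- data.frame(
    metabolite = mets,
    module = unname(partition$assignment[mets]),
    genes = vapply(mets, function(m) {
      paste(sort(pairs$unit[pairs$metabolite == m]), collapse = ";")
    }, character(1)),
    verdicts = vapply(mets, function(m) {
      gs <- sort(pairs$unit[pairs$metabolite == m])
      paste(vapply(gs, verdict_of, character(1), met = m), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  influenced <- unique(pairs$metabolite)
  if (is.null(metabolite_meta)) {
    metabolite_meta <- data.frame(metabolite = influenced,
                                  pathway = NA_character_,
                                  stringsAsFactors = FALSE)
  }
  pw <- metabolite_meta$pathway[match(influenced, metabolite_meta$metabolite)]
  pw[is.na(pw)] <- "Unannotated"
  counts <- if (length(influenced)) {
    as.data.frame(table(pathway = pw), stringsAsFactors = FALSE)
  } else {
    data.frame(pathway = character(0), Freq = integer(0))
  }
  names(counts) <- c("pathway", "n_metabolites")
  structure(list(report = report, pathway_counts = counts),
            class = "module_overlay")
}

#' @export
print.module_overlay <- function(x, ...) {
  cat("<module_overlay>\n")
  print(x$pathway_counts, row.names = FALSE)
  invisible(x)
}
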