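# Structure-recovery metrics against a known simulation truth: skeleton
# precision/recall/F1 over metabolite-metabolite edges and orientation
# accuracy among the recovered true edges.

#' Skeleton recovery metrics against a simulation truth
#'
#' Compares the learned undirected skeleton, restricted to metabolite
#' nodes, with the true DAG's skeleton.
#'
#' @param network A [causal_network()] (instrument nodes are ignored).
#' @param truth A [simulation_truth()].
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
skeleton_metrics <- function(network, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  mets <- colnames(truth$amat)
  am <- metabolite_subgraph(network)$metabolite_amat[mets, mets]
  sk_l <- (am + t(am)) > 0
  sk_t <- (truth$amat + t(truth$amat)) > 0
  up <- upper.tri(sk_t)
  tp <- sum(sk_l[up] & sk_t[up])
  fp <- sum(sk_l[up] & !sk_t[up])
  fn <- sum(!sk_l[up] & sk_t[up])
  precision <- if (tp + fp > 0) tp / (tp + fp) else 1
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Orientation accuracy among recovered true edges
#'
#' Of the true metabolite edges present in the learned skeleton, the
#' fraction oriented in the true direction (an undirected or reversed edge
#' counts as not correctly oriented).
#'
#' @inheritParams skeleton_metrics
#' @return List: `n_recovered`, `n_correct`, `accuracy` (`NA` when no true
#'   edge was recovered).
#' @export
orientation_accuracy <- function(network, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  mets <- colnames(truth$amat)
  am <- metabolite_subgraph(network)$metabolite_amat[mets, mets]
  idx <- which(truth$amat == 1L, arr.ind = TRUE)
  if (!nrow(idx)) return(list(n_recovered = 0L, n_correct = 0L,
                              accuracy = NA_real_))
  recovered <- correct <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]  # true edge i -> j
    if (am[i, j] == 1L || am[j, i] == 1L) {
      recovered <- recovered + 1L
      if (am[i, j] == 1L && am[j, i] == 0L) correct <- correct + 1L
    }
  }
  list(n_recovered = recovered, n_correct = correct,
       accuracy = if (recovered > 0) correct / recovered else NA_real_)
}
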