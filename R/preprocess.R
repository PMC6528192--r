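# Metabolite preprocessing: filtering, imputation, transformation to
# normality, covariate adjustment. Pipeline order: filter (missingness +
# normality on observed values) -> impute -> transform -> adjust.

#' Impute missing metabolite values
#'
#' @param m A [metabolite_matrix()] with no fully-missing column.
#' @param method `"knn"` (default): each missing entry is the mean of the
#'   value in the `k` nearest samples (Euclidean distance over metabolites
#'   complete in the whole matrix; falls back to pairwise-complete distances
#'   when no column is complete). `"half_min"`: half the observed column
#'   minimum (limit-of-detection convention). `"column_median"`: observed
#'   column median.
#' @param k Neighbours for `"knn"`.
#' @return A [metabolite_matrix()] with no missing values; observed entries
#'   are unchanged.
#' @export
impute_missing <- function(m, method = c("knn", "half_min", "column_median"),
                           k = 10) {
  stopifnot(inherits(m, "metabolite_matrix"))
  method <- match.arg(method)
  v <- m$values
  all_miss <- colSums(!is.na(v)) == 0
  if (any(all_miss)) {
    stop_invalid("fully missing metabolite(s) must be filtered first: ",
                 paste(colnames(v)[all_miss], collapse = ", "))
  }
  if (!anyNA(v)) return(m)
  out <- v
  if (method == "column_median") {
    for (j in which(colSums(is.na(v)) > 0)) {
      out[is.na(v[, j]), j] <- stats::median(v[, j], na.rm = TRUE)
    }
  } else if (method == "half_min") {
    for (j in which(colSums(is.na(v)) > 0)) {
      out[is.na(v[, j]), j] <- min(v[, j], na.rm = TRUE) / 2
    }
  } else {
    if (!is_count(k)) stop_invalid("k must be a positive integer")
    complete_cols <- which(colSums(is.na(v)) == 0)
    if (length(complete_cols)) {
      d <- as.matrix(stats::dist(scale(v[, complete_cols, drop = FALSE])))
    } else {
      # pairwise-available scaled Euclidean distance
      sv <- scale(v)
      n <- nrow(v)
      d <- matrix(0, n, n)
      for (a in seq_len(n - 1)) {
        diffs <- sweep(sv[(a + 1):n, , drop = FALSE], 2, sv[a, ])
        msd <- rowMeans(diffs^2, na.rm = TRUE)
        d[a, (a + 1):n] <- d[(a + 1):n, a] <- sqrt(msd)
      }
    }
    diag(d) <- Inf
    for (j in which(colSums(is.na(v)) > 0)) {
      obs <- which(!is.na(v[, j]))
      for (s in which(is.na(v[, j]))) {
        dist_s <- d[s, obs]
        nb <- obs[order(dist_s)][seq_len(min(k, length(obs)))]
        out[s, j] <- mean(v[nb, j])
      }
    }
  }
  metabolite_matrix(out, m$meta)
}

#' Choose the transform that best normalizes a metabolite
#'
#' Candidates are identity, log, square root and square (log and square root
#' are skipped, not shifted, when the data contain non-positive /negative
#' values). The candidate maximizing the Shapiro-Wilk W statistic wins; the
#' returned vector is the winning transform standardized to mean 0, SD 1.
#' Shapiro-Wilk is computed on at most 5000 values (deterministic evenly
#' spaced subsample above that).
#'
#' @param x Numeric vector (no `NA`s; drop them first).
#' @return List with `label`, `y` (standardized transformed vector) and
#'   `normality_stat` (the Shapiro-Wilk W).
#' @export
select_transform <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[!is.na(x)]
  if (length(x) < 3) stop_invalid("need at least 3 observed values")
  if (stats::sd(x) == 0) stop_invalid("constant vector: no valid transform")
  cand <- list(identity = x, square = x^2)
  if (all(x > 0)) cand$log <- log(x)
  if (all(x >= 0)) cand$sqrt <- sqrt(x)
  w <- vapply(cand, function(y) {
    if (stats::sd(y) == 0) return(-Inf)
    shapiro_w(y)
  }, numeric(1))
  lab <- names(which.max(w))
  y <- cand[[lab]]
  list(label = lab, y = as.numeric(scale(y)), normality_stat = unname(w[lab]))
}

shapiro_w <- function(y) {
  n <- length(y)
  if (n > 5000) {
    y <- sort(y)[round(seq(1, n, length.out = 5000))]
  }
  unname(stats::shapiro.test(y)$statistic)
}

#' Filter metabolites on missingness and achievable normality
#'
#' Drops metabolites with a missing fraction of at least `max_missing_frac`
#' (the rule is "at least", so exactly 50\% missing is dropped at the
#' default) and metabolites whose best transform still has a Shapiro-Wilk W
#' below `min_normality_stat` (computed on the observed values). Constant
#' columns are dropped with reason `constant`.
#'
#' @param m A [metabolite_matrix()] (may contain `NA`s).
#' @param max_missing_frac Missingness cutoff (default 0.5).
#' @param min_normality_stat Shapiro-Wilk W threshold (default 0.90).
#' @return List with `metabolites` (the retained [metabolite_matrix()], raw
#'   values) and `dropped` (`data.frame` of `metabolite`, `reason`).
#' @export
filter_metabolites <- function(m, max_missing_frac = 0.5,
                               min_normality_stat = 0.90) {
  stopifnot(inherits(m, "metabolite_matrix"))
  v <- m$values
  reasons <- character(0); dropped <- character(0)
  keep <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    miss <- mean(is.na(x))
    if (miss >= max_missing_frac) {
      dropped <- c(dropped, colnames(v)[j]); reasons <- c(reasons, "missing")
      next
    }
    obs <- x[!is.na(x)]
    if (length(obs) < 3 || stats::sd(obs) == 0) {
      dropped <- c(dropped, colnames(v)[j]); reasons <- c(reasons, "constant")
      next
    }
    st <- select_transform(obs)
    if (st$normality_stat < min_normality_stat) {
      dropped <- c(dropped, colnames(v)[j]); reasons <- c(reasons, "non_normal")
      next
    }
    keep[j] <- TRUE
  }
  if (!any(keep)) stop_invalid("all metabolites filtered")
  list(
    metabolites = metabolite_matrix(v[, keep, drop = FALSE],
                                    m$meta[keep, , drop = FALSE]),
    dropped = data.frame(metabolite = dropped, reason = reasons,
                         stringsAsFactors = FALSE)
  )
}

#' Apply the best normalizing transform to every metabolite
#'
#' @param m A complete (post-imputation) [metabolite_matrix()].
#' @return List with `metabolites` (transformed, each column standardized)
#'   and `transform_log` (named character vector of labels).
#' @export
transform_metabolites <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (anyNA(m$values)) stop_invalid("impute before transforming")
  v <- m$values
  labs <- character(ncol(v))
  for (j in seq_len(ncol(v))) {
    st <- select_transform(v[, j])
    v[, j] <- st$y
    labs[j] <- st$label
  }
  names(labs) <- colnames(v)
  list(metabolites = metabolite_matrix(v, m$meta), transform_log = labs)
}

#' Residualize metabolites on covariates
#'
#' Per metabolite, ordinary least squares on all covariates plus an
#' intercept; the residual columns are exactly orthogonal to every covariate
#' (and the operation is idempotent).
#'
#' @param m A complete [metabolite_matrix()] (or plain matrix).
#' @param covariates `data.frame` or matrix of covariates, rows aligned with
#'   samples. Factor-like columns must already be coded numerically
#'   (e.g. sex/phase as 0/1).
#' @param transform_log Optional transform labels carried into the result.
#' @return An [adjusted_metabolites()].
#' @export
adjust_covariates <- function(m, covariates, transform_log = NULL) {
  v <- if (inherits(m, "metabolite_matrix")) m$values else as.matrix(m)
  meta <- if (inherits(m, "metabolite_matrix")) m$meta else NULL
  if (anyNA(v)) stop_invalid("adjust_covariates requires complete data (impute first)")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (anyNA(X)) stop_invalid("covariates contain missing values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_invalid("rank-deficient covariate matrix; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, v)
  dimnames(res) <- dimnames(v)
  adjusted_metabolites(
    residuals = res,
    transform_log = transform_log %||%
      setNames(rep(NA_character_, ncol(v)), colnames(v)),
    adjustment_covariates = colnames(as.matrix(covariates)),
    meta = meta
  )
}

#' Full metabolite preprocessing
#'
#' Filter (missingness and normality) -> impute -> transform -> adjust.
#'
#' @inheritParams filter_metabolites
#' @inheritParams impute_missing
#' @param covariates Covariate table for [adjust_covariates()].
#' @return List: `adjusted` ([adjusted_metabolites()]), `dropped`
#'   (`data.frame`), `transform_log`.
#' @export
preprocess_metabolites <- function(m, covariates, max_missing_frac = 0.5,
                                   min_normality_stat = 0.90,
                                   method = "knn", k = 10) {
  flt <- filter_metabolites(m, max_missing_frac, min_normality_stat)
  imp <- impute_missing(flt$metabolites, method = method, k = k)
  tr <- transform_metabolites(imp)
  adj <- adjust_covariates(tr$metabolites, covariates,
                           transform_log = tr$transform_log)
  list(adjusted = adj, dropped = flt$dropped,
       transform_log = tr$transform_log)
}
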