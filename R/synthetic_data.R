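# Synthetic genotype / metabolite generator with known causal ground truth.
#
# The generator emulates the structure of a cohort-scale exome + serum
# metabolomics study: rare-ish LoF variants arranged in LD blocks with
# near-perfect proxies, gene burden scores, metabolites produced by a
# linear-Gaussian structural equation system, covariates (age, sex, BMI,
# measurement phase, ancestry factors), and MCAR missingness.

#' LD block specification
#'
#' Describes how simulated variants are arranged into linkage-disequilibrium
#' blocks: within a block all variants share a minor-allele frequency and a
#' target pairwise dosage correlation.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size Variants per block.
#' @param within_block_r Target pairwise dosage correlation inside a block,
#'   in `[0, 1)`. Values above 0.80 give "proxy" variants that a single
#'   representative can stand in for.
#' @param maf_range Length-2 numeric, range the per-block alternate-allele
#'   frequency is drawn from. Must lie in `(0, 1]`; values above 0.5 are
#'   allowed for edge cases such as fixation.
#' @return An object of class `ld_spec`.
#' @export
ld_spec <- function(n_blocks = 10, block_size = 4, within_block_r = 0.9,
                    maf_range = c(0.05, 0.30)) {
  if (!is_count(n_blocks) || !is_count(block_size)) {
    stop_invalid("n_blocks and block_size must be positive integers")
  }
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1) {
    stop_invalid("within_block_r must be in [0, 1)")
  }
  maf_range <- as.numeric(maf_range)
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2)
  if (any(maf_range <= 0) || any(maf_range > 1) || maf_range[1] > maf_range[2]) {
    stop_invalid("maf_range must satisfy 0 < low <= high <= 1")
  }
  structure(
    list(n_blocks = n_blocks, block_size = block_size,
         within_block_r = within_block_r, maf_range = maf_range),
    class = "ld_spec"
  )
}

#' Simulate genotypes in LD blocks
#'
#' Generates allele counts (0/1/2) for variants arranged in LD blocks. Each
#' block has a "source" variant; proxy variants copy each source haplotype
#' allele with probability `within_block_r` and otherwise redraw it from the
#' block allele frequency, which makes the expected pairwise dosage
#' correlation equal to `within_block_r` while preserving the marginal MAF.
#' Optional latent ancestry factors shift the per-sample allele frequency on
#' the logit scale (and are returned so metabolite means can load on them),
#' so downstream covariate adjustment has real confounding to remove.
#'
#' @param n_samples Number of samples (>= 2).
#' @param spec An [ld_spec()].
#' @param genes_per_block Genes per block; variants are assigned round-robin
#'   within their block.
#' @param n_ancestry Number of latent ancestry factors.
#' @param ancestry_strength SD of the per-block logit-frequency loadings on
#'   the ancestry factors (0 disables confounding).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, spec = ld_spec(),
                               genes_per_block = 1, n_ancestry = 2,
                               ancestry_strength = 0, seed = 1) {
  if (!is_count(n_samples, min = 2)) {
    stop_invalid("n_samples must be an integer >= 2")
  }
  stopifnot(inherits(spec, "ld_spec"))
  if (!is_count(genes_per_block)) stop_invalid("genes_per_block must be >= 1")
  with_seed(seed, {
    p <- spec$n_blocks * spec$block_size
    dos <- matrix(0L, n_samples, p)
    anc <- matrix(stats::rnorm(n_samples * n_ancestry), n_samples, n_ancestry,
                  dimnames = list(NULL, sprintf("ANC%d", seq_len(n_ancestry))))
    meta <- vector("list", spec$n_blocks)
    gene_counter <- 0L
    for (b in seq_len(spec$n_blocks)) {
      maf_b <- stats::runif(1, spec$maf_range[1], spec$maf_range[2])
      load_b <- stats::rnorm(n_ancestry, 0, ancestry_strength)
      # per-sample allele frequency, shifted by ancestry on the logit scale
      pf <- if (maf_b >= 1) rep(1, n_samples) else {
        stats::plogis(stats::qlogis(maf_b) + drop(anc %*% load_b))
      }
      h1 <- stats::rbinom(n_samples, 1L, pf)
      h2 <- stats::rbinom(n_samples, 1L, pf)
      cols <- matrix(0L, n_samples, spec$block_size)
      cols[, 1] <- h1 + h2
      if (spec$block_size > 1) {
        for (v in 2:spec$block_size) {
          keep1 <- stats::rbinom(n_samples, 1L, spec$within_block_r)
          keep2 <- stats::rbinom(n_samples, 1L, spec$within_block_r)
          g1 <- ifelse(keep1 == 1L, h1, stats::rbinom(n_samples, 1L, pf))
          g2 <- ifelse(keep2 == 1L, h2, stats::rbinom(n_samples, 1L, pf))
          cols[, v] <- g1 + g2
        }
      }
      idx <- (b - 1L) * spec$block_size + seq_len(spec$block_size)
      dos[, idx] <- cols
      chrom <- ((b - 1L) %% 22L) + 1L
      pos <- 1000000L * b + 137L * seq_len(spec$block_size)
      ref <- sample(c("A", "C", "G", "T"), spec$block_size, replace = TRUE)
      alt <- vapply(ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1))
      gene <- sprintf(
        "GENE%03d",
        gene_counter + ((seq_len(spec$block_size) - 1L) %% genes_per_block) + 1L
      )
      gene_counter <- gene_counter + genes_per_block
      meta[[b]] <- data.frame(
        id = sprintf("%d:%d:%s:%s", chrom, pos, ref, alt),
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, meta)
    rownames(meta) <- NULL
    f <- colMeans(dos) / 2
    meta$maf <- pmin(f, 1 - f)
    meta$alt_freq <- f
    meta$monomorphic <- apply(dos, 2, function(x) length(unique(x)) == 1L)
    if (any(meta$monomorphic)) {
      warning(sprintf(
        "%d variant(s) monomorphic at n = %d (flagged, retained): %s",
        sum(meta$monomorphic), n_samples,
        paste(utils::head(meta$id[meta$monomorphic], 5), collapse = ", ")
      ), call. = FALSE)
    }
    rownames(dos) <- sprintf("S%04d", seq_len(n_samples))
    rownames(anc) <- rownames(dos)
    genotype_matrix(dos, meta, ancestry = anc)
  })
}

#' Simulation ground truth
#'
#' Constructor for the object holding the true metabolite DAG, its edge
#' coefficients, the true gene -> metabolite direct effects, per-metabolite
#' residual SDs, and per (gene, metabolite) pleiotropy labels.
#'
#' @param amat p x p 0/1 matrix; `amat[j, i] == 1` means edge j -> i.
#' @param lambda p x p numeric; `lambda[i, j]` is the coefficient of parent
#'   metabolite j in the structural equation of metabolite i (non-zero
#'   exactly where `t(amat)` is 1).
#' @param gamma genes x metabolites numeric matrix of direct effects in
#'   metabolite-SD units per burden allele (may have zero rows).
#' @param noise_sd Per-metabolite residual SD.
#' @return An object of class `simulation_truth` with a `pleiotropy_labels`
#'   data frame (`direct`, `mediated`, `none`) derived from `gamma` and
#'   reachability in the DAG.
#' @export
simulation_truth <- function(amat, lambda, gamma, noise_sd) {
  stopifnot(is.matrix(amat), is.matrix(lambda), is.matrix(gamma))
  p <- nrow(amat)
  stopifnot(ncol(amat) == p, all(dim(lambda) == p), ncol(gamma) == p,
            length(noise_sd) == p)
  if (!all((lambda != 0) == t(amat == 1))) {
    stop_invalid("lambda must be non-zero exactly on DAG edges")
  }
  if (!directed_part_acyclic(amat)) stop_invalid("truth DAG contains a cycle")
  obj <- structure(
    list(amat = amat, lambda = lambda, gamma = gamma, noise_sd = noise_sd),
    class = "simulation_truth"
  )
  obj$pleiotropy_labels <- truth_labels(obj)
  obj
}

# reachability closure of the truth DAG
dag_reachable <- function(amat) {
  r <- amat > 0
  p <- nrow(amat)
  for (k in seq_len(p)) r <- r | (r %*% r > 0)  # doubling; p steps overkill but cheap
  r
}

truth_labels <- function(truth) {
  genes <- rownames(truth$gamma)
  mets <- colnames(truth$gamma)
  if (!length(genes)) {
    return(data.frame(gene = character(0), metabolite = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  reach <- dag_reachable(truth$amat)
  out <- expand.grid(gene = genes, metabolite = mets,
                     stringsAsFactors = FALSE)
  out$label <- "none"
  for (r in seq_len(nrow(out))) {
    g <- out$gene[r]; m <- out$metabolite[r]
    if (truth$gamma[g, m] != 0) {
      out$label[r] <- "direct"
    } else {
      direct_targets <- mets[truth$gamma[g, ] != 0]
      if (length(direct_targets) &&
          any(reach[direct_targets, m])) {
        out$label[r] <- "mediated"
      }
    }
  }
  out
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth> %d metabolites, %d edges, %d genes with effects\n",
    nrow(x$amat), sum(x$amat), sum(rowSums(x$gamma != 0) > 0)
  ))
  invisible(x)
}

#' Simulate a random metabolite DAG
#'
#' Draws a random topological order over the metabolites and includes each
#' forward edge independently with probability `2 * edge_density /
#' (n_metabolites - 1)` (capped at 1), so the expected number of edges is
#' `n_metabolites * edge_density` and the expected number of parents per node
#' is `edge_density`. Edge coefficients are uniform on `effect_range` with
#' random sign. Acyclicity is guaranteed by construction.
#'
#' @param n_metabolites Number of metabolites (>= 2).
#' @param edge_density Expected parents per node (>= 0).
#' @param effect_range Length-2 numeric `(lo, hi)`, `0 < lo <= hi`.
#' @param noise_sd Residual SD for every metabolite.
#' @param seed Integer seed.
#' @return A [simulation_truth()] with an empty gene-effect table; attach
#'   gene effects with [attach_gene_effects()].
#' @export
simulate_metabolite_dag <- function(n_metabolites, edge_density = 2,
                                    effect_range = c(0.3, 0.8),
                                    noise_sd = 1, seed = 1) {
  if (!is_count(n_metabolites, min = 2)) {
    stop_invalid("n_metabolites must be an integer >= 2")
  }
  if (!is.numeric(edge_density) || edge_density < 0) {
    stop_invalid("edge_density must be >= 0")
  }
  stopifnot(length(effect_range) == 2, effect_range[1] <= effect_range[2])
  with_seed(seed, {
    p <- n_metabolites
    nm <- sprintf("M%02d", seq_len(p))
    ord <- sample(p)
    p_edge <- min(1, 2 * edge_density / (p - 1))
    amat <- matrix(0L, p, p, dimnames = list(nm, nm))
    lambda <- matrix(0, p, p, dimnames = list(nm, nm))
    for (a in seq_len(p - 1)) {
      for (b in (a + 1):p) {
        if (stats::runif(1) < p_edge) {
          from <- ord[a]; to <- ord[b]
          amat[from, to] <- 1L
          lambda[to, from] <- sample(c(-1, 1), 1) *
            stats::runif(1, effect_range[1], effect_range[2])
        }
      }
    }
    gamma <- matrix(numeric(0), 0, p, dimnames = list(NULL, nm))
    simulation_truth(amat, lambda, gamma, rep(noise_sd, p))
  })
}

#' Attach gene -> metabolite direct effects to a simulation truth
#'
#' @param truth A [simulation_truth()].
#' @param effects `data.frame` with columns `gene`, `metabolite`, `gamma`
#'   (SD units per burden allele).
#' @param null_genes Character vector of additional genes carried with all
#'   zero effects (useful as negative controls).
#' @return The updated `simulation_truth` (pleiotropy labels recomputed).
#' @export
attach_gene_effects <- function(truth, effects, null_genes = character(0)) {
  stopifnot(inherits(truth, "simulation_truth"),
            all(c("gene", "metabolite", "gamma") %in% names(effects)))
  mets <- colnames(truth$amat)
  if (!all(effects$metabolite %in% mets)) {
    stop_invalid("unknown metabolite in gene effect table")
  }
  genes <- unique(c(effects$gene, null_genes))
  gamma <- matrix(0, length(genes), length(mets),
                  dimnames = list(genes, mets))
  for (r in seq_len(nrow(effects))) {
    gamma[effects$gene[r], effects$metabolite[r]] <- effects$gamma[r]
  }
  simulation_truth(truth$amat, truth$lambda, gamma, truth$noise_sd)
}

#' Simulate covariates
#'
#' Age, sex (0/1), BMI, measurement phase (0/1) and ancestry-factor
#' surrogates (`PC1..PCk`, taken from the genotype simulation when available
#' so that genotype frequencies and metabolite means share confounding).
#'
#' @param n Number of samples.
#' @param ancestry Optional matrix of ancestry factor scores (samples x k).
#' @param sample_ids Row names to use.
#' @return `data.frame` of covariates.
#' @export
simulate_covariates <- function(n, ancestry = NULL, sample_ids = NULL) {
  cov <- data.frame(
    age = stats::rnorm(n, 54, 6),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, 28, 5),
    phase = stats::rbinom(n, 1, 0.5)
  )
  if (!is.null(ancestry)) {
    anc <- as.data.frame(ancestry)
    names(anc) <- sprintf("PC%d", seq_len(ncol(anc)))
    cov <- cbind(cov, anc)
  }
  rownames(cov) <- sample_ids %||% sprintf("S%04d", seq_len(n))
  cov
}

#' Simulate metabolites from a structural equation system
#'
#' Generates each metabolite in topological order as the sum of its parent
#' metabolites (weighted by the true edge coefficients), the gene burden
#' terms, covariate terms, and Gaussian noise:
#' `M_i = sum_j lambda_ij M_j + sum_m gamma_im B_m + X beta_i + eps_i`.
#'
#' @param genotypes A [genotype_matrix()]; burdens for the genes named in
#'   `truth$gamma` are computed from it (error if a gene is absent).
#' @param truth A [simulation_truth()].
#' @param covariates Optional covariate `data.frame`; simulated via
#'   [simulate_covariates()] when `NULL`.
#' @param covariate_effects Either `NULL`/0 (no covariate effects), the
#'   string `"default"` (random N(0, 0.2) effects of each standardized
#'   covariate on each metabolite), or a numeric matrix (covariates x
#'   metabolites).
#' @param noise_seed Integer seed for all randomness in this step.
#' @param pathways Optional character vector of pathway labels recycled over
#'   metabolites (defaults to a metabolomics-style mix).
#' @param standardize `"none"` (default) evaluates the equations exactly as
#'   written, so each coefficient is recovered by OLS on the raw columns but
#'   metabolite variance compounds along the topological order. `"children"`
#'   rescales every metabolite to unit sample SD as it is generated (parents
#'   therefore enter each child equation on the SD scale) and rescales the
#'   recorded truth coefficients accordingly, so the returned truth still
#'   contains the exact structural coefficients of the returned data while
#'   variance stays flat across the network — the convention used for
#'   larger study simulations.
#' @return List with elements `metabolites` ([metabolite_matrix()]),
#'   `covariates` (`data.frame`) and `truth` (the [simulation_truth()],
#'   rescaled when `standardize = "children"`).
#' @export
simulate_metabolites <- function(genotypes, truth, covariates = NULL,
                                 covariate_effects = "default",
                                 noise_seed = 1, pathways = NULL,
                                 standardize = c("none", "children")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "simulation_truth"))
  genes <- rownames(truth$gamma)
  known <- unique(genotypes$variant_meta$gene)
  if (length(genes) && !all(genes %in% known)) {
    stop_invalid("truth references gene(s) absent from genotypes: ",
                 paste(setdiff(genes, known), collapse = ", "))
  }
  n <- nrow(genotypes$dosages)
  p <- ncol(truth$amat)
  mets <- colnames(truth$amat)
  with_seed(noise_seed, {
    if (is.null(covariates)) {
      covariates <- simulate_covariates(n, ancestry = genotypes$ancestry,
                                        sample_ids = rownames(genotypes$dosages))
    }
    X <- scale(as.matrix(covariates))
    X[!is.finite(X)] <- 0  # zero-variance covariate (e.g. tiny n) contributes nothing
    if (is.character(covariate_effects) &&
        identical(covariate_effects, "default")) {
      beta <- matrix(stats::rnorm(ncol(X) * p, 0, 0.2), ncol(X), p)
    } else if (is.null(covariate_effects) ||
               (is.numeric(covariate_effects) &&
                length(covariate_effects) == 1 && covariate_effects == 0)) {
      beta <- matrix(0, ncol(X), p)
    } else {
      beta <- covariate_effects
      stopifnot(is.matrix(beta), nrow(beta) == ncol(X), ncol(beta) == p)
    }
    B <- if (length(genes)) {
      gene_burden(genotypes)$values[, genes, drop = FALSE]
    } else {
      matrix(0, n, 0)
    }
    M <- matrix(0, n, p, dimnames = list(rownames(genotypes$dosages), mets))
    covterm <- X %*% beta
    lambda_out <- truth$lambda
    gamma_out <- truth$gamma
    noise_out <- truth$noise_sd
    ord <- topological_order(truth$amat)
    for (i in ord) {
      parents <- which(truth$amat[, i] == 1L)
      mu <- covterm[, i]
      if (length(parents)) {
        mu <- mu + M[, parents, drop = FALSE] %*% truth$lambda[i, parents]
      }
      if (length(genes)) {
        mu <- mu + B %*% truth$gamma[, i]
      }
      M[, i] <- mu + stats::rnorm(n, 0, truth$noise_sd[i])
      if (standardize == "children") {
        c_i <- stats::sd(M[, i])
        M[, i] <- (M[, i] - mean(M[, i])) / c_i
        lambda_out[i, ] <- lambda_out[i, ] / c_i
        gamma_out[, i] <- gamma_out[, i] / c_i
        noise_out[i] <- noise_out[i] / c_i
      }
    }
    truth_out <- if (standardize == "children") {
      simulation_truth(truth$amat, lambda_out, gamma_out, noise_out)
    } else {
      truth
    }
    if (is.null(pathways)) {
      pathways <- c("Lipid", "Amino Acid", "Peptide", "Nucleotide",
                    "Xenobiotics")
    }
    meta <- data.frame(
      metabolite = mets,
      pathway = rep_len(pathways, p),
      sub_pathway = NA_character_,
      stringsAsFactors = FALSE
    )
    list(metabolites = metabolite_matrix(M, meta), covariates = covariates,
         truth = truth_out)
  })
}

topological_order <- function(amat) {
  p <- nrow(amat)
  remaining <- seq_len(p)
  ord <- integer(0)
  a <- amat
  while (length(remaining)) {
    indeg <- colSums(a[remaining, remaining, drop = FALSE])
    src <- remaining[indeg == 0]
    if (!length(src)) stop_invalid("cycle in DAG")
    ord <- c(ord, src)
    remaining <- setdiff(remaining, src)
  }
  ord
}

#' Build a named analysis scenario with known pleiotropy ground truth
#'
#' The scenarios mirror the canonical configurations used to reason about
#' pleiotropy versus mediation:
#' * `mediated`: gene -> M1 -> M2 (direct effect on M1 only; M2 mediated).
#' * `pleiotropic`: gene -> M1 and gene -> M2 with no M1-M2 edge (two direct
#'   effects; true pleiotropy).
#' * `null`: no gene effect at all.
#' * `bnipl_like`: the `mediated` wiring with carnitine metabolite names
#'   (decanoylcarnitine -> octanoylcarnitine), gamma = 1.5 SD, lambda = 0.5,
#'   MAF 8%.
#' * `gpr97_like`: three lipid metabolites; direct effects on oleate and
#'   glycocholenate_sulfate, oleate -> eicoseneate so the eicoseneate signal
#'   is mediated (direct on 2 metabolites, mediated on 1).
#'
#' Every scenario also carries a second, effect-free gene as a negative
#' control. Effects are in metabolite-SD units per burden allele.
#'
#' @param name One of `"pleiotropic"`, `"mediated"`, `"null"`,
#'   `"gpr97_like"`, `"bnipl_like"`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param gamma,lambda Effect sizes (defaults 1.5 and 0.5).
#' @param maf Alternate-allele frequency of the causal gene's variants
#'   (default 0.08).
#' @param covariate_effects Passed to [simulate_metabolites()].
#' @return An object of class `scenario_bundle`: list with `genotypes`,
#'   `metabolites`, `covariates`, `truth`, `gene`, `null_gene`, `name`.
#' @export
make_scenario <- function(name, n_samples, seed = 1, gamma = 1.5,
                          lambda = 0.5, maf = 0.08,
                          covariate_effects = "default") {
  choices <- c("pleiotropic", "mediated", "null", "gpr97_like", "bnipl_like")
  if (!is.character(name) || length(name) != 1L || !(name %in% choices)) {
    stop_invalid("unknown scenario name; must be one of: ",
                 paste(choices, collapse = ", "))
  }
  spec <- ld_spec(n_blocks = 2, block_size = 3, within_block_r = 0.95,
                  maf_range = c(maf, maf))
  genotypes <- simulate_genotypes(n_samples, spec, seed = seed)
  gene <- "GENE001"; null_gene <- "GENE002"
  mets <- switch(name,
    bnipl_like = c("decanoylcarnitine", "octanoylcarnitine"),
    gpr97_like = c("oleate", "eicoseneate", "glycocholenate_sulfate"),
    c("M01", "M02")
  )
  p <- length(mets)
  amat <- matrix(0L, p, p, dimnames = list(mets, mets))
  lmat <- matrix(0, p, p, dimnames = list(mets, mets))
  eff <- switch(name,
    mediated = , bnipl_like = {
      amat[1, 2] <- 1L; lmat[2, 1] <- lambda
      data.frame(gene = gene, metabolite = mets[1], gamma = gamma,
                 stringsAsFactors = FALSE)
    },
    pleiotropic = data.frame(gene = gene, metabolite = mets[1:2],
                             gamma = gamma, stringsAsFactors = FALSE),
    null = NULL,
    gpr97_like = {
      amat[1, 2] <- 1L; lmat[2, 1] <- lambda
      data.frame(gene = gene, metabolite = mets[c(1, 3)], gamma = gamma,
                 stringsAsFactors = FALSE)
    }
  )
  gamma_mat <- matrix(0, 2, p, dimnames = list(c(gene, null_gene), mets))
  truth <- simulation_truth(amat, lmat, gamma_mat, rep(1, p))
  if (!is.null(eff)) {
    truth <- attach_gene_effects(truth, eff, null_genes = null_gene)
  }
  sim <- simulate_metabolites(genotypes, truth,
                              covariate_effects = covariate_effects,
                              noise_seed = seed + 1000L,
                              pathways = "Lipid")
  structure(
    list(genotypes = genotypes, metabolites = sim$metabolites,
         covariates = sim$covariates, truth = truth, gene = gene,
         null_gene = null_gene, name = name),
    class = "scenario_bundle"
  )
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("<scenario_bundle> '%s': %d samples, %d metabolites\n",
              x$name, nrow(x$genotypes$dosages), ncol(x$metabolites$values)))
  invisible(x)
}

#' Simulate a full genome-to-metabolome study
#'
#' Convenience wrapper wiring the generator pieces together: a random
#' metabolite DAG, one causal gene (own LD block) per instrumented
#' metabolite, optional null genes, and metabolites generated from the
#' structural equations. This is the workhorse for structure-recovery
#' experiments.
#'
#' @param n_samples Samples.
#' @param n_metabolites Metabolites in the DAG.
#' @param edge_density Expected parents per metabolite.
#' @param effect_range Metabolite -> metabolite coefficient magnitude range.
#' @param n_instrumented How many metabolites receive a direct genetic
#'   effect (each from its own gene).
#' @param gamma_gene Genetic effect size (SD per burden allele).
#' @param n_null_genes Extra genes with no effect.
#' @param maf_range,block_size,within_block_r LD block settings.
#' @param covariate_effects Passed to [simulate_metabolites()].
#' @param seed Integer seed.
#' @return List: `genotypes`, `metabolites`, `covariates`, `truth`,
#'   `instrumented` (metabolite names), `genes` (causal gene names).
#' @export
simulate_study <- function(n_samples, n_metabolites = 20, edge_density = 2,
                           effect_range = c(0.3, 0.8), n_instrumented = 10,
                           gamma_gene = 0.5, n_null_genes = 2,
                           maf_range = c(0.15, 0.30), block_size = 3,
                           within_block_r = 0.9,
                           covariate_effects = 0, seed = 1) {
  stopifnot(n_instrumented <= n_metabolites)
  truth <- simulate_metabolite_dag(n_metabolites, edge_density, effect_range,
                                   seed = seed)
  n_genes <- n_instrumented + n_null_genes
  spec <- ld_spec(n_blocks = n_genes, block_size = block_size,
                  within_block_r = within_block_r, maf_range = maf_range)
  genotypes <- simulate_genotypes(n_samples, spec, seed = seed + 1L)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  instrumented <- with_seed(seed + 2L, {
    sample(colnames(truth$amat), n_instrumented)
  })
  eff <- data.frame(gene = genes[seq_len(n_instrumented)],
                    metabolite = instrumented, gamma = gamma_gene,
                    stringsAsFactors = FALSE)
  truth <- attach_gene_effects(truth, eff,
                               null_genes = genes[-seq_len(n_instrumented)])
  sim <- simulate_metabolites(genotypes, truth,
                              covariate_effects = covariate_effects,
                              noise_seed = seed + 3L,
                              standardize = "children")
  list(genotypes = genotypes, metabolites = sim$metabolites,
       covariates = sim$covariates, truth = sim$truth,
       instrumented = instrumented, genes = eff$gene)
}

#' Inject missing-completely-at-random values
#'
#' @param m A [metabolite_matrix()].
#' @param rate Missingness fraction in `[0, 1]`; scalar or one value per
#'   metabolite.
#' @param seed Integer seed.
#' @return The matrix with entries masked to `NA` at the requested rates.
#' @export
inject_missingness <- function(m, rate, seed = 1) {
  stopifnot(inherits(m, "metabolite_matrix"))
  p <- ncol(m$values)
  if (length(rate) == 1L) rate <- rep(rate, p)
  if (length(rate) != p || any(rate < 0) || any(rate > 1) || any(!is.finite(rate))) {
    stop_invalid("rate must be in [0, 1], scalar or one per metabolite")
  }
  with_seed(seed, {
    v <- m$values
    n <- nrow(v)
    for (j in seq_len(p)) {
      if (rate[j] == 0) next
      mask <- stats::runif(n) < rate[j]
      v[mask, j] <- NA_real_
    }
    metabolite_matrix(v, m$meta)
  })
}
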