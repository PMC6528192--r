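# Readers/writers for the standard table formats, variant QC on the printed
# call-level filters, run configuration, and the end-to-end pipeline.
# All tables are sample-major TSV with a header row and ids in column 1;
# genotypes can round-trip through a minimal VCFv4.2 with a GT field.

# ---- writers ---------------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

matrix_to_df <- function(mat, id_col = "sample_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write genotypes as TSV (and optionally a minimal VCFv4.2)
#'
#' @param g A [genotype_matrix()].
#' @param path Dosage TSV path (samples x variants, ids in column 1).
#' @param meta_path Variant metadata TSV path.
#' @param vcf_path Optional path for a minimal VCFv4.2 file with a GT field
#'   and the gene assignment in `INFO/GENE`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, meta_path = NULL, vcf_path = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  write_tsv(matrix_to_df(g$dosages), path)
  if (!is.null(meta_path)) {
    write_tsv(g$variant_meta, meta_path)
  }
  if (!is.null(vcf_path)) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Assigned gene\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", rownames(g$dosages)), collapse = "\t")
    )
    vm <- g$variant_meta
    body <- vapply(seq_len(nrow(vm)), function(v) {
      gts <- gt_code[as.character(g$dosages[, v])]
      gts[is.na(gts)] <- "./."
      paste(c(vm$chrom[v], vm$pos[v], vm$id[v], vm$ref[v], vm$alt[v], ".",
              "PASS", paste0("GENE=", vm$gene[v]), "GT", gts),
            collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), vcf_path)
  }
  invisible(path)
}

#' Read genotypes from TSV or VCF
#'
#' TSV: a dosage table written by [write_genotypes()] plus its metadata
#' table. VCF: parsed with `vcfR`; dosages are alternate-allele counts from
#' the GT field, multi-allelic records are split into one variant per
#' alternate allele, and half-calls (one missing allele) become missing.
#'
#' @param path Dosage TSV or VCF path.
#' @param format `"tsv"` or `"vcf"`.
#' @param meta_path Variant metadata TSV (required for `"tsv"`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), meta_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(meta_path)) stop_invalid("meta_path required for TSV genotypes")
    dos <- df_to_matrix(utils::read.delim(path, check.names = FALSE))
    storage.mode(dos) <- "integer"
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    return(genotype_matrix(dos, meta))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_invalid("VCF has no GT field")
  info_gene <- vcfR::extract.info(v, element = "GENE")
  rows <- list()
  dos_cols <- list()
  for (r in seq_len(nrow(fx))) {
    alts <- strsplit(fx$ALT[r], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\|", "/", gt[r, ]), "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      d <- vapply(alleles, function(a) {
        if (length(a) != 2 || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      f <- mean(d, na.rm = TRUE) / 2
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s:%s:%s:%s", fx$CHROM[r], fx$POS[r], fx$REF[r],
                     alts[k]),
        chrom = fx$CHROM[r], pos = as.integer(fx$POS[r]), ref = fx$REF[r],
        alt = alts[k],
        gene = if (!is.null(info_gene)) info_gene[r] else NA_character_,
        maf = min(f, 1 - f), alt_freq = f,
        monomorphic = length(unique(d[!is.na(d)])) <= 1L,
        stringsAsFactors = FALSE
      )
      dos_cols[[length(dos_cols) + 1L]] <- d
    }
  }
  dos <- do.call(cbind, dos_cols)
  rownames(dos) <- colnames(gt)
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  genotype_matrix(dos, meta)
}

#' Write / read a metabolite matrix
#'
#' @param m A [metabolite_matrix()].
#' @param path Values TSV path.
#' @param meta_path Metabolite metadata TSV path.
#' @return `path` invisibly (writer); a [metabolite_matrix()] (reader).
#' @export
write_metabolites <- function(m, path, meta_path = NULL) {
  stopifnot(inherits(m, "metabolite_matrix"))
  write_tsv(matrix_to_df(m$values), path)
  if (!is.null(meta_path)) write_tsv(m$meta, meta_path)
  invisible(path)
}

#' @rdname write_metabolites
#' @export
read_metabolites <- function(path, meta_path = NULL) {
  vals <- df_to_matrix(utils::read.delim(path, check.names = FALSE))
  meta <- if (!is.null(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  metabolite_matrix(vals, meta)
}

#' Write / read a covariate table
#'
#' @param cov Covariate `data.frame` (numeric columns; sex/phase as 0/1).
#' @param path TSV path.
#' @return `path` invisibly (writer); `data.frame` (reader).
#' @export
write_covariates <- function(cov, path) {
  df <- data.frame(sample_id = rownames(cov), cov, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  df
}

#' Write a causal network as an edge-list TSV (and optionally GraphML)
#'
#' @param network A [causal_network()].
#' @param path Edge-list TSV path (`source`, `target`, `type`,
#'   `source_type`, `target_type`).
#' @param graphml_path Optional GraphML path.
#' @param sepset_path Optional JSON path for the recorded separating sets.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml_path = NULL,
                          sepset_path = NULL) {
  stopifnot(inherits(network, "causal_network"))
  write_tsv(network_edges(network), path)
  if (!is.null(graphml_path)) {
    el <- network_edges(network)
    g <- igraph::graph_from_data_frame(
      el[c("source", "target", "type")],
      directed = TRUE,
      vertices = network$nodes
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(sepset_path)) {
    jsonlite::write_json(network$sepsets, sepset_path, auto_unbox = FALSE)
  }
  invisible(path)
}

#' Persist an instrument set
#'
#' Scores and loadings as TSV plus a JSON with variance fractions and the
#' proxy map.
#'
#' @param instruments An `instrument_set`.
#' @param scores_path,loadings_path,meta_path Output paths.
#' @return `scores_path`, invisibly.
#' @export
write_instruments <- function(instruments, scores_path, loadings_path = NULL,
                              meta_path = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  write_tsv(matrix_to_df(instruments$scores), scores_path)
  if (!is.null(loadings_path)) {
    write_tsv(matrix_to_df(instruments$loadings, id_col = "variant"),
              loadings_path)
  }
  if (!is.null(meta_path)) {
    pm <- instruments$proxy_map
    jsonlite::write_json(
      list(
        variance_explained = instruments$variance_explained,
        cum_variance = instruments$cum_variance,
        n_retained = instruments$n_retained,
        proxy_map = if (is.null(pm)) list() else unclass(pm)
      ),
      meta_path, auto_unbox = FALSE, digits = NA
    )
  }
  invisible(scores_path)
}

#' Write a simulation truth as JSON
#'
#' @param truth A [simulation_truth()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(
    list(
      metabolites = colnames(truth$amat),
      edges = {
        idx <- which(truth$amat == 1L, arr.ind = TRUE)
        data.frame(
          from = colnames(truth$amat)[idx[, 1]],
          to = colnames(truth$amat)[idx[, 2]],
          lambda = truth$lambda[cbind(idx[, 2], idx[, 1])],
          stringsAsFactors = FALSE
        )
      },
      gamma = {
        idx <- which(truth$gamma != 0, arr.ind = TRUE)
        data.frame(
          gene = rownames(truth$gamma)[idx[, 1]],
          metabolite = colnames(truth$gamma)[idx[, 2]],
          gamma = truth$gamma[idx],
          stringsAsFactors = FALSE
        )
      },
      genes = rownames(truth$gamma),
      noise_sd = truth$noise_sd,
      pleiotropy_labels = truth$pleiotropy_labels
    ),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

# ---- variant QC ------------------------------------------------------------

#' Variant-call quality filters
#'
#' Applies the call-level removal rules for exome variant calls. SNVs pass
#' when posterior >= 0.95, total depth >= 6, allelic fraction >= 0.1, at
#' least 3 variant reads, and fewer than 99\% of reads in a single
#' direction. Indels pass when the allelic fraction is >= 0.2 for
#' heterozygous (>= 0.8 for homozygous) calls, total depth >= 60 and at
#' least 30 variant reads. Removals are phrased as strict inequalities
#' ("less than 6x"), so passes are inclusive at each boundary. A record
#' missing a required field fails with reason `missing_field`.
#'
#' @param records `data.frame` with columns `id`, `type` (`"snv"`/`"indel"`),
#'   `posterior`, `depth`, `allelic_fraction`, `variant_reads`,
#'   `strand_fraction` (largest fraction of reads in one direction),
#'   `zygosity` (`"het"`/`"hom"`; indels only).
#' @return `data.frame`: `id`, `pass`, `reasons` (comma-joined rule ids,
#'   empty string for passes).
#' @export
variant_qc <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- function(type) {
    if (type == "snv") {
      c("posterior", "depth", "allelic_fraction", "variant_reads",
        "strand_fraction")
    } else {
      c("allelic_fraction", "depth", "variant_reads", "zygosity")
    }
  }
  out <- data.frame(id = records$id, pass = FALSE, reasons = "",
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (is.na(rec$type) || !(rec$type %in% c("snv", "indel"))) {
      out$reasons[r] <- "missing_field"
      next
    }
    fields <- needed(rec$type)
    vals <- lapply(fields, function(f) {
      if (!f %in% names(rec)) NA else rec[[f]]
    })
    names(vals) <- fields
    if (any(vapply(vals, function(x) is.null(x) || is.na(x), logical(1)))) {
      out$reasons[r] <- "missing_field"
      next
    }
    reasons <- character(0)
    if (rec$type == "snv") {
      if (vals$posterior < 0.95) reasons <- c(reasons, "posterior_lt_0.95")
      if (vals$depth < 6) reasons <- c(reasons, "depth_lt_6")
      if (vals$allelic_fraction < 0.1) reasons <- c(reasons, "af_lt_0.1")
      if (vals$variant_reads < 3) reasons <- c(reasons, "variant_reads_lt_3")
      if (vals$strand_fraction >= 0.99) reasons <- c(reasons, "strand_ge_0.99")
    } else {
      af_min <- if (vals$zygosity == "hom") 0.8 else 0.2
      if (vals$allelic_fraction < af_min) {
        reasons <- c(reasons, sprintf("af_lt_%.1f_%s", af_min, vals$zygosity))
      }
      if (vals$depth < 60) reasons <- c(reasons, "depth_lt_60")
      if (vals$variant_reads < 30) reasons <- c(reasons, "variant_reads_lt_30")
    }
    out$pass[r] <- length(reasons) == 0
    out$reasons[r] <- paste(reasons, collapse = ",")
  }
  out
}

# ---- configuration ---------------------------------------------------------

#' Pipeline run configuration
#'
#' All thresholds and grids of the pipeline with their standard defaults:
#' CI-level grid `{0.0005, 0.001, 0.005, 0.01, 0.05}` tuned on 45 subsample
#' replicates (or a fixed `alpha = 0.001`), penalized-selection grid
#' `{1.5, 0.3, 0.01}`, Bonferroni base level 0.05, proxy threshold r > 0.80,
#' PCA variance threshold 0.90, missingness cutoff 0.50.
#'
#' @param scenario Scenario name for simulated input (see [make_scenario()]),
#'   or `"study"` for [simulate_study()], or `NULL` when reading files.
#' @param n_samples Samples to simulate.
#' @param seed Integer seed.
#' @param alpha Fixed CI-test level used when `tune = FALSE`.
#' @param tune Whether to tune alpha by subsample stability.
#' @param alpha_grid,n_replicates,subsample_frac Tuning settings.
#' @param ccrs_grid Penalized-selection tuning grid.
#' @param bonferroni_alpha Family-wise level for the scan.
#' @param r_threshold LD proxy threshold.
#' @param var_threshold PCA cumulative-variance threshold.
#' @param max_missing Metabolite missingness cutoff.
#' @param min_normality Shapiro-Wilk W threshold.
#' @param impute_method,knn_k Imputation settings.
#' @param sem_alpha Per-gene family-wise level for pleiotropy verdicts.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = "mediated", n_samples = 1000, seed = 1,
                       alpha = 0.001, tune = FALSE,
                       alpha_grid = c(0.0005, 0.001, 0.005, 0.01, 0.05),
                       n_replicates = 45, subsample_frac = 0.8,
                       ccrs_grid = c(1.5, 0.3, 0.01),
                       bonferroni_alpha = 0.05, r_threshold = 0.80,
                       var_threshold = 0.90, max_missing = 0.50,
                       min_normality = 0.90, impute_method = "knn",
                       knn_k = 10, sem_alpha = 0.05) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (lossless round trip)
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

# ---- pipeline --------------------------------------------------------------

#' Run the full genome-to-metabolome analysis
#'
#' Executes preprocess -> two-route variant selection -> instruments ->
#' network learning (optionally alpha tuning) -> SEM pleiotropy assessment
#' -> module detection, and (optionally) writes every artifact plus a
#' provenance JSON. Re-running with an identical configuration produces a
#' byte-identical output bundle.
#'
#' @param config A [run_config()].
#' @param data Optional list with `genotypes`, `metabolites`, `covariates`
#'   (and optionally `truth`); when `NULL`, simulated from
#'   `config$scenario`.
#' @param output_dir Optional directory for the artifact bundle.
#' @return List of class `pipeline_result` with each stage's output.
#' @export
run_pipeline <- function(config = run_config(), data = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  res <- tryCatch({
    if (is.null(data)) {
      data <- if (identical(config$scenario, "study")) {
        simulate_study(config$n_samples, seed = config$seed)
      } else {
        make_scenario(config$scenario, config$n_samples, seed = config$seed)
      }
    }
    stage <- "preprocess"
    prep <- preprocess_metabolites(
      data$metabolites, data$covariates,
      max_missing_frac = config$max_missing,
      min_normality_stat = config$min_normality,
      method = config$impute_method, k = config$knn_k
    )
    stage <- "variant_select"
    burdens <- gene_burden(data$genotypes)
    sel <- select_lof_associations(
      burdens, prep$adjusted, alpha = config$bonferroni_alpha,
      tuning_grid = config$ccrs_grid
    )
    stage <- "instruments"
    instruments <- genotypes_to_instruments(
      data$genotypes, r_threshold = config$r_threshold,
      var_threshold = config$var_threshold
    )
    stage <- "gdag"
    tuning <- NULL
    alpha <- config$alpha
    net_data <- cbind(instruments$scores, prep$adjusted$residuals)
    types <- c(rep("instrument", ncol(instruments$scores)),
               rep("metabolite", ncol(prep$adjusted$residuals)))
    if (isTRUE(config$tune)) {
      tuning <- tune_alpha(net_data, config$alpha_grid,
                           n_replicates = config$n_replicates,
                           subsample_frac = config$subsample_frac,
                           seed = config$seed, node_types = types)
      alpha <- tuning$chosen_alpha
    }
    network <- learn_gdag(instruments, prep$adjusted, alpha = alpha)
    stage <- "sem_pleiotropy"
    genes_selected <- unique(sel$selection$pairs$unit)
    sem <- NULL; pleiotropy <- list()
    if (length(genes_selected)) {
      sem <- fit_sem(network, prep$adjusted, burdens, genes = genes_selected,
                     undirected = "ignore")
      pleiotropy <- lapply(genes_selected, function(g) {
        cand <- sel$selection$pairs$metabolite[sel$selection$pairs$unit == g]
        assess_pleiotropy(g, cand, network, sem, alpha = config$sem_alpha,
                          m = prep$adjusted, burdens = burdens)
      })
      names(pleiotropy) <- genes_selected
    }
    stage <- "netanalysis"
    msub <- metabolite_subgraph(network)$metabolite_amat
    modules <- NULL; overlay <- NULL
    if (any((msub + t(msub)) > 0)) {
      modules <- detect_modules(network)
      overlay <- lof_module_overlay(modules, sel$selection, pleiotropy,
                                    metabolite_meta = data$metabolites$meta)
    }
    list(
      config = config, data = data, preprocessed = prep, burdens = burdens,
      selection = sel, instruments = instruments, tuning = tuning,
      alpha_used = alpha, network = network, sem = sem,
      pleiotropy = pleiotropy, modules = modules, overlay = overlay
    )
  }, error = function(e) {
    stop_invalid(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)))
  })
  class(res) <- "pipeline_result"
  if (!is.null(output_dir)) write_bundle(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> scenario '%s': %d selected pairs, alpha = %g, %d pleiotropy calls\n",
    x$config$scenario %||% "(files)", nrow(x$selection$selection$pairs),
    x$alpha_used, length(x$pleiotropy)
  ))
  invisible(x)
}

# write every artifact of a pipeline run; deterministic content only (no
# timestamps), so identical runs give byte-identical bundles
write_bundle <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, ...)
  write_config(res$config, fp("config.yaml"))
  write_genotypes(res$data$genotypes, fp("genotypes.tsv"),
                  meta_path = fp("variants.tsv"),
                  vcf_path = fp("genotypes.vcf"))
  write_metabolites(res$data$metabolites, fp("metabolites.tsv"),
                    meta_path = fp("metabolite_meta.tsv"))
  write_covariates(res$data$covariates, fp("covariates.tsv"))
  if (!is.null(res$data$truth)) write_truth(res$data$truth, fp("truth.json"))
  write_tsv(matrix_to_df(res$preprocessed$adjusted$residuals),
            fp("adjusted_metabolites.tsv"))
  write_tsv(res$preprocessed$dropped, fp("dropped_metabolites.tsv"))
  write_tsv(res$selection$scan, fp("scan_results.tsv"))
  write_tsv(res$selection$selection$pairs, fp("selected_pairs.tsv"))
  write_instruments(res$instruments, fp("instrument_scores.tsv"),
                    loadings_path = fp("instrument_loadings.tsv"),
                    meta_path = fp("instruments.json"))
  if (!is.null(res$tuning)) {
    write_tsv(res$tuning$stability, fp("alpha_tuning.tsv"))
  }
  write_network(res$network, fp("network_edges.tsv"),
                graphml_path = fp("network.graphml"),
                sepset_path = fp("sepsets.json"))
  if (!is.null(res$sem)) {
    write_tsv(res$sem$lambda, fp("sem_lambda.tsv"))
    write_tsv(res$sem$gamma, fp("sem_gamma.tsv"))
  }
  if (length(res$pleiotropy)) {
    rep_tab <- do.call(rbind, lapply(res$pleiotropy, function(pc) {
      tab <- pc$table
      tab$is_pleiotropic <- pc$is_pleiotropic
      tab
    }))
    rownames(rep_tab) <- NULL
    write_tsv(rep_tab, fp("pleiotropy_report.tsv"))
  }
  if (!is.null(res$modules)) {
    write_tsv(res$overlay$report, fp("module_report.tsv"))
    write_tsv(res$overlay$pathway_counts, fp("pathway_counts.tsv"))
  }
  jsonlite::write_json(
    list(
      package = "gdagnet",
      version = as.character(utils::packageVersion("gdagnet")),
      seed = res$config$seed,
      alpha_used = res$alpha_used,
      config = unclass(res$config)
    ),
    fp("provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(output_dir)
}
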