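test_that("genotypes round-trip through TSV and minimal VCF", {
  g <- make_scenario("mediated", 30, seed = 51)$genotypes
  tsv <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
  vcf <- tempfile(fileext = ".vcf")
  write_genotypes(g, tsv, meta_path = meta, vcf_path = vcf)
  g_tsv <- read_genotypes(tsv, "tsv", meta_path = meta)
  expect_identical(g_tsv$dosages, g$dosages)
  expect_equal(g_tsv$variant_meta$id, g$variant_meta$id)
  g_vcf <- read_genotypes(vcf, "vcf")
  expect_identical(unname(g_vcf$dosages[rownames(g$dosages), g$variant_meta$id]),
                   unname(g$dosages))
  expect_equal(g_vcf$variant_meta$gene,
               g$variant_meta$gene[match(g_vcf$variant_meta$id,
                                         g$variant_meta$id)])
})

test_that("VCF parsing handles GT conventions, half-calls and multi-allelics", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Assigned gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "1:100:A:G", "A", "G", ".", "PASS", "GENE=G1", "GT",
          "0/1", "1|1", "./.", sep = "\t"),
    paste("2", "200", "2:200:C:T,A", "C", "T,A", ".", "PASS", "GENE=G2", "GT",
          "1/2", "0/2", "./1", sep = "\t")
  ), vcf)
  g <- read_genotypes(vcf, "vcf")
  expect_equal(ncol(g$dosages), 3L)  # multi-allelic split into two variants
  expect_equal(unname(g$dosages[, "1:100:A:G"]), c(1L, 2L, NA))
  expect_equal(unname(g$dosages[, "2:200:C:T"]), c(1L, 0L, NA))  # half-call -> NA
  expect_equal(unname(g$dosages[, "2:200:C:A"]), c(1L, 1L, NA))
  expect_equal(g$variant_meta$gene, c("G1", "G2", "G2"))
})

test_that("metabolites and covariates round-trip losslessly enough", {
  # tiny n: rare variants may be monomorphic, which warns by design
  sc <- suppressWarnings(make_scenario("pleiotropic", 25, seed = 52))
  mp <- tempfile(fileext = ".tsv"); mm <- tempfile(fileext = ".tsv")
  write_metabolites(sc$metabolites, mp, meta_path = mm)
  back <- read_metabolites(mp, meta_path = mm)
  expect_equal(back$values, sc$metabolites$values, tolerance = 1e-12)
  expect_equal(back$meta$pathway, sc$metabolites$meta$pathway)
  cp <- tempfile(fileext = ".tsv")
  write_covariates(sc$covariates, cp)
  cov <- read_covariates(cp)
  expect_equal(as.matrix(cov), as.matrix(sc$covariates), tolerance = 1e-12)
})

test_that("variant QC applies the printed call-level rules at the boundaries", {
  rec <- data.frame(
    id = sprintf("v%d", 1:9),
    type = c(rep("snv", 5), rep("indel", 3), "snv"),
    posterior = c(0.95, 0.94, 0.95, 0.95, 0.95, NA, NA, NA, 0.99),
    depth = c(6, 10, 5, 6, 6, 60, 59, 60, NA),
    allelic_fraction = c(0.1, 0.5, 0.3, 0.09, 0.1, 0.2, 0.5, 0.15, 0.5),
    variant_reads = c(3, 10, 5, 5, 2, 30, 35, 30, 10),
    strand_fraction = c(0.5, 0.99, 0.6, 0.5, 0.5, NA, NA, NA, 0.5),
    zygosity = c(rep(NA, 5), "het", "het", "het", NA),
    stringsAsFactors = FALSE
  )
  qc <- variant_qc(rec)
  expect_true(qc$pass[1])                       # all boundaries inclusive
  expect_false(qc$pass[2])                      # 99% single direction
  expect_match(qc$reasons[2], "strand")
  expect_false(qc$pass[3]); expect_match(qc$reasons[3], "depth_lt_6")
  expect_false(qc$pass[4]); expect_match(qc$reasons[4], "af_lt_0.1")
  expect_false(qc$pass[5]); expect_match(qc$reasons[5], "variant_reads_lt_3")
  expect_true(qc$pass[6])                       # het indel at all boundaries
  expect_false(qc$pass[7]); expect_match(qc$reasons[7], "depth_lt_60")
  expect_false(qc$pass[8]); expect_match(qc$reasons[8], "af_lt_0.2_het")
  expect_false(qc$pass[9]); expect_equal(qc$reasons[9], "missing_field")
})

test_that("run configurations serialize losslessly", {
  cfg <- run_config(scenario = "pleiotropic", n_samples = 321, seed = 9,
                    alpha = 0.005, tune = TRUE, knn_k = 7)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_identical(unclass(back), unclass(cfg))
})

test_that("the pipeline runs end to end and reports stage failures", {
  out <- tempfile()
  res <- suppressWarnings(run_pipeline(
    run_config(scenario = "mediated", n_samples = 500, seed = 3),
    output_dir = out
  ))
  expect_s3_class(res, "pipeline_result")
  expect_true(file.exists(file.path(out, "provenance.json")))
  expect_true(file.exists(file.path(out, "network_edges.tsv")))
  expect_true(file.exists(file.path(out, "genotypes.vcf")))
  # the mediated scenario ends in a mediated verdict for M02
  call <- res$pleiotropy[["GENE001"]]
  expect_false(is.null(call))
  expect_error(
    run_pipeline(run_config(scenario = "nope", n_samples = 100)),
    "stage 'input'"
  )
})
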