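#' Build or load a pipeline configuration
#'
#' The configuration is a flat named list (YAML on disk) of input paths and
#' thresholds: `counts`, `genes_bed`, `loci_bed`, `fasta`, `crystal`,
#' `positives`, `pirsf_gmt`, `go_gmt`, `kegg_gmt`, plus the tunables
#' `min_maf`, `min_call`, `max_hwe_p`, `max_distance`, `svm_cost`,
#' `svm_gamma`, `n_randomizations`, `keep_fraction`, `n_folds`, `alpha`,
#' `min_overlap`, `gwas_alpha`, `gwas_threshold`, `seed`. Every paper-gap
#' default is surfaced here so a stricter or looser reading is one edit
#' away.
#'
#' @param x a named list, or the path to a YAML file.
#' @return a `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  defaults <- list(
    counts = NULL, genes_bed = NULL, loci_bed = NULL, fasta = NULL,
    crystal = NULL, positives = NULL, pirsf_gmt = NULL, go_gmt = NULL,
    kegg_gmt = NULL,
    min_maf = 0.01, min_call = 0.95, max_hwe_p = 1e-6,
    max_distance = 500000, svm_cost = 1, svm_gamma = NA,
    n_randomizations = 200, keep_fraction = 1.0, n_folds = 5,
    alpha = 0.05, min_overlap = 2, p_adjust = "none",
    gwas_alpha = 0.05, gwas_threshold = NA, seed = 1)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns the list of problems found (missing files, out-of-range
#' thresholds, missing annotation namespaces); an empty character vector
#' means the configuration is runnable.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems (possibly empty).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  files <- c("counts", "genes_bed", "loci_bed", "fasta", "crystal",
             "positives", "pirsf_gmt", "go_gmt", "kegg_gmt")
  for (f in files) {
    if (is.null(config[[f]]))
      problems <- c(problems, paste0("missing input path: ", f))
    else if (!file.exists(config[[f]]))
      problems <- c(problems, paste0(f, " does not exist: ", config[[f]]))
  }
  rng <- function(field, lo, hi) {
    v <- config[[field]]
    if (!is.numeric(v) || is.na(v) || v < lo || v > hi)
      problems <<- c(problems, sprintf("%s out of range [%g, %g]", field, lo, hi))
  }
  rng("min_maf", 0, 0.5); rng("min_call", 0, 1); rng("max_hwe_p", 0, 1)
  rng("alpha", 0, 1); rng("gwas_alpha", 0, 1); rng("keep_fraction", 0, 1)
  if (!is.numeric(config$max_distance) || config$max_distance < 0)
    problems <- c(problems, "max_distance must be non-negative")
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    problems <- c(problems, "seed must be an integer")
  problems
}

#' Run the full multidimensional screen
#'
#' Executes the three screening dimensions in order — Bayes-factor SNP
#' screen (after QC), genetic screen against disease loci, SVM structural
#' screen against known disease genes, functional annotation screen — then
#' the Fisher/Bonferroni GWAS baseline and the overlap comparison. All
#' intermediate tables and a JSON report are written under `outdir`; the
#' report is byte-reproducible for a fixed config and seed (timings go to
#' the log file only).
#'
#' @param config a [pipeline_config()] (or something coercible by it).
#' @param outdir output directory (created if needed).
#' @return the screen report, invisibly a list: per-stage id sets and
#'   counts, the config echo, and the file manifest.
#' @export
run_pipeline <- function(config, outdir) {
  config <- pipeline_config(unclass(config))
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "pipeline.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg); cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("reading inputs")
  counts <- stage("read", read_counts(config$counts))
  genes <- stage("read", read_bed(config$genes_bed))
  loci <- stage("read", read_bed(config$loci_bed))
  positives <- stage("read", readLines(config$positives))
  positives <- positives[nzchar(positives)]

  say("stage 1a: QC (", nrow(counts), " SNPs)")
  qc <- stage("qc", qc_filter(counts, config$min_maf, config$min_call,
                              config$max_hwe_p))
  utils::write.table(qc$rejected, file.path(outdir, "qc_rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage 1b: Bayes-factor screen (", nrow(qc$pass), " SNPs)")
  bf <- stage("bayes", screen_snps(qc$pass))
  write_bfln(bf$scores, file.path(outdir, "bfln.tsv"))

  say("stage 1c: genetic screen -> test set")
  snp_pos <- counts[c("snp_id", "chrom", "pos")]
  test_set <- stage("map", genetic_screen(bf$significant, snp_pos, genes,
                                          loci, config$max_distance))
  test_set <- setdiff(test_set, positives)
  writeLines(test_set, file.path(outdir, "test_set.txt"))

  say("stage 2a: protein features")
  records <- stage("features",
                   read_protein_records(config$fasta, config$crystal))
  fm <- stage("features", build_feature_matrix(records))
  write_features(fm$features, file.path(outdir, "features.tsv"))

  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  gr_l <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start, loci$end))
  in_loci <- genes$id[unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr_g, gr_l)))]
  negative_pool <- setdiff(genes$id, c(in_loci, positives, test_set))
  negative_pool <- intersect(negative_pool, rownames(fm$features))
  pos_pool <- intersect(positives, rownames(fm$features))
  test_feat <- intersect(test_set, rownames(fm$features))

  say("stage 2b: SVM ensemble (", length(pos_pool), " pos, ",
      length(negative_pool), " neg pool, ", length(test_feat), " test, ",
      config$n_randomizations, " randomizations)")
  gamma <- if (is.na(config$svm_gamma)) NULL else config$svm_gamma
  ens <- stage("svm", ensemble_predict(
    fm$features, pos_pool, negative_pool, test_feat,
    n_randomizations = config$n_randomizations,
    keep_fraction = config$keep_fraction,
    cost = config$svm_cost, gamma = gamma, seed = config$seed))
  utils::write.table(ens$votes, file.path(outdir, "svm_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage 3: functional annotation screen (",
      length(ens$candidates), " candidates)")
  catalogs <- list(
    pirsf = stage("funcscreen", read_gmt(config$pirsf_gmt, "PIRSF")),
    go = stage("funcscreen", read_gmt(config$go_gmt, "GO")),
    kegg = stage("funcscreen", read_gmt(config$kegg_gmt, "KEGG")))
  fs <- stage("funcscreen", functional_screen(
    ens$candidates, positives, catalogs, config$alpha, config$min_overlap,
    config$p_adjust))
  utils::write.table(fs$indicators, file.path(outdir, "indicators.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(fs$final, file.path(outdir, "final_candidates.txt"))

  say("baseline: Fisher/Bonferroni GWAS")
  pv <- stage("gwas", fisher_scan(to_allelic(qc$pass)))
  thr <- if (is.na(config$gwas_threshold)) NULL else config$gwas_threshold
  bonf <- stage("gwas", bonferroni_screen(pv, config$gwas_alpha,
                                          threshold = thr))
  utils::write.table(bonf$results, file.path(outdir, "gwas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gwas_assign <- assign_snps_to_genes(
    snp_pos[snp_pos$snp_id %in% bonf$significant, , drop = FALSE],
    genes, config$max_distance)
  gwas_genes <- sort(unique(gwas_assign$gene_id[!is.na(gwas_assign$gene_id)]))
  overlap <- compare_methods(fs$final, gwas_genes)

  report <- list(
    config = unclass(config),
    stages = list(
      snps_input = nrow(counts),
      snps_qc_pass = nrow(qc$pass),
      snps_significant = length(bf$significant),
      test_set_genes = length(test_set),
      svm_candidates = length(ens$candidates),
      final_candidates = length(fs$final),
      gwas_significant_snps = length(bonf$significant),
      gwas_genes = length(gwas_genes)),
    sets = list(
      significant_snps = sort(bf$significant),
      test_set = sort(test_set),
      svm_candidates = ens$candidates,
      final_candidates = fs$final,
      gwas_genes = gwas_genes),
    overlap = overlap[c("n_a", "n_b", "n_intersection", "jaccard")],
    gwas_threshold = bonf$threshold,
    files = list(qc_rejected = "qc_rejected.tsv", bfln = "bfln.tsv",
                 test_set = "test_set.txt", features = "features.tsv",
                 svm_predictions = "svm_predictions.tsv",
                 indicators = "indicators.tsv",
                 final_candidates = "final_candidates.txt",
                 gwas = "gwas.tsv"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: ", length(fs$final), " final candidates")
  invisible(report)
}

#' Write a complete synthetic fixture set
#'
#' Generates, with one seed, every file the pipeline consumes plus the
#' ground truth: genotype counts with planted causal SNPs, a toy genome
#' with disease loci covering the causal genes, class-conditional protein
#' sequences/crystal parameters (positive-like features for known disease
#' genes and causal genes), clustered annotation catalogs, and a ready
#' `config.yaml`. Presets: `"endtoend"` (the planted-recovery study:
#' 2000 SNPs, 200 genes, 20 causal, feature separation 4, strong
#' annotation clustering), `"null"` (no causal SNPs, no feature signal,
#' no clustering) and `"power"` (genotype stage only, graded effects).
#'
#' @param preset `"endtoend"`, `"null"` or `"power"`.
#' @param seed integer master seed.
#' @param outdir directory to write into (created).
#' @return invisibly, a list with the `config` path, all file paths and the
#'   `truth` list (also serialized to `truth.json`).
#' @export
write_fixture <- function(preset = c("endtoend", "null", "power"), seed,
                          outdir) {
  preset <- match.arg(preset)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pp <- function(f) file.path(outdir, f)
  n_snps <- 2000; n_genes <- 200; n_causal <- 20
  separation <- switch(preset, endtoend = 4, null = 0, power = 0)
  clustering <- switch(preset, endtoend = 0.95, 0)
  delta <- switch(preset, endtoend = 0.2, null = 0, power = 0.1)

  genome <- simulate_genome(n_genes, n_snps, n_loci = 5,
                            seed = seed, n_genes_in_loci = 40)
  locus_genes <- genome$truth$genes_in_loci
  causal_genes <- if (preset == "null") character(0) else
    sort(utils::head(locus_genes, n_causal))
  # known disease genes: some inside loci, more outside (they are excluded
  # from both the test set and the negative pool); the remaining in-locus
  # genes are innocent bystanders the screens must reject
  known_in <- utils::head(setdiff(locus_genes, causal_genes), 10)
  known_out <- utils::head(setdiff(genome$genes$id, locus_genes), 50)
  known <- sort(c(known_in, known_out))
  assigned <- genome$truth$snp_gene
  causal_snps <- names(assigned)[!is.na(assigned) & assigned %in% causal_genes]

  model <- population_model(p = 0.3, theta = c(0.5 - delta, 0.5, 0.5 + delta),
                            theta_null = 0.42, n_cases = 900,
                            n_controls = 1200, mode = "fixed")
  sim <- simulate_genotype_counts(model, n_snps, seed = seed + 1,
                                  maf_range = c(0.1, 0.5),
                                  snp_ids = genome$snps$snp_id,
                                  causal_ids = causal_snps)
  counts <- merge(genome$snps, sim$counts, by = "snp_id", sort = TRUE)
  write_counts(counts, pp("counts.tsv"))
  write_bed(genome$genes, pp("genes.bed"))
  write_bed(genome$loci, pp("loci.bed"))

  pos_like <- c(known, causal_genes)
  other <- setdiff(genome$genes$id, pos_like)
  feats <- simulate_protein_features(
    n_pos = length(pos_like), n_neg = length(other),
    separation = separation, seed = seed + 2, ids = c(pos_like, other))
  features_to_files(feats$features, pp("proteins.fasta"), pp("crystal.tsv"),
                    seed = seed + 3)
  writeLines(known, pp("positives.txt"))

  ann <- simulate_annotations(genome$genes$id, pos_like,
                              clustering_strength = clustering,
                              seed = seed + 4)
  write_gmt(ann$catalogs$pirsf, pp("pirsf.gmt"))
  write_gmt(ann$catalogs$go, pp("go.gmt"))
  write_gmt(ann$catalogs$kegg, pp("kegg.gmt"))

  cfg <- list(counts = pp("counts.tsv"), genes_bed = pp("genes.bed"),
              loci_bed = pp("loci.bed"), fasta = pp("proteins.fasta"),
              crystal = pp("crystal.tsv"), positives = pp("positives.txt"),
              pirsf_gmt = pp("pirsf.gmt"), go_gmt = pp("go.gmt"),
              kegg_gmt = pp("kegg.gmt"), seed = seed)
  yaml::write_yaml(cfg, pp("config.yaml"))

  truth <- list(preset = preset, seed = seed,
                causal_genes = causal_genes, causal_snps = sort(causal_snps),
                known_disease_genes = known,
                genes_in_loci = locus_genes,
                disease_categories = ann$truth,
                effect_delta = delta, separation = separation,
                clustering_strength = clustering)
  jsonlite::write_json(truth, pp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = pp("config.yaml"), files = cfg, truth = truth))
}
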