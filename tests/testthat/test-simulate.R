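test_that("genotype simulation obeys Hardy-Weinberg and case probabilities", {
  model <- population_model(p = 0.5, theta = c(0.5, 0.5, 0.5),
                            n_cases = 5000, n_controls = 5000, mode = "fixed")
  sim <- simulate_genotype_counts(model, 1, seed = 2)
  cnt <- sim$counts
  m <- c(cnt$n0A + cnt$n0U, cnt$n1A + cnt$n1U, cnt$n2A + cnt$n2U)
  n <- sum(m)
  se <- 3 * sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(m / n - c(0.25, 0.5, 0.25)) <= se))
  # theta = 0.5 everywhere: case fraction near one half per genotype
  frac <- c(cnt$n0A, cnt$n1A, cnt$n2A) / m
  expect_true(all(abs(frac - 0.5) <= 3 * sqrt(0.25 / m)))
})

test_that("generators are bit-reproducible under a fixed seed", {
  model <- population_model(p = 0.3, theta = c(0.3, 0.5, 0.7),
                            margins = c(50, 50, 50), mode = "margins")
  a <- simulate_genotype_counts(model, 20, causal_fraction = 0.5, seed = 9)
  b <- simulate_genotype_counts(model, 20, causal_fraction = 0.5, seed = 9)
  expect_identical(a, b)
  g1 <- simulate_genome(10, 50, 2, seed = 5)
  g2 <- simulate_genome(10, 50, 2, seed = 5)
  expect_identical(g1, g2)
  f1 <- simulate_protein_features(5, 5, separation = 3, seed = 5)
  f2 <- simulate_protein_features(5, 5, separation = 3, seed = 5)
  expect_identical(f1, f2)
  s1 <- simulate_annotations(sprintf("g%d", 1:30), sprintf("g%d", 1:5),
                             seed = 5)
  s2 <- simulate_annotations(sprintf("g%d", 1:30), sprintf("g%d", 1:5),
                             seed = 5)
  expect_identical(s1, s2)
})

test_that("causal effects raise the detection rate above the null", {
  null_model <- population_model(theta = c(0.5, 0.5, 0.5), theta_null = 0.5,
                                 margins = c(300, 300, 300), mode = "margins")
  alt_model <- population_model(theta = c(0.3, 0.5, 0.7), theta_null = 0.5,
                                margins = c(300, 300, 300), mode = "margins")
  hits <- function(model, frac) {
    mean(vapply(1:100, function(r) {
      s <- simulate_genotype_counts(model, 1, causal_fraction = frac,
                                    seed = 500 + r)
      bfln(s$counts)$bfln > 0
    }, logical(1)))
  }
  expect_gt(hits(alt_model, 1), hits(null_model, 0) + 0.3)
})

test_that("toy genomes respect locus membership and window contracts", {
  g <- simulate_genome(10, 60, 2, seed = 3, n_genes_in_loci = 5)
  gr_g <- GenomicRanges::GRanges(g$genes$chrom,
                                 IRanges::IRanges(g$genes$start, g$genes$end))
  gr_l <- GenomicRanges::GRanges(g$loci$chrom,
                                 IRanges::IRanges(g$loci$start, g$loci$end))
  ov <- GenomicRanges::countOverlaps(gr_g, gr_l)
  expect_equal(sum(ov > 0), 5)
  expect_setequal(g$genes$id[ov > 0], g$truth$genes_in_loci)
  # recorded truth assignments match an independent re-scan
  expect_identical(unname(g$truth$snp_gene),
                   unname(oracle_assign(g$snps, g$genes)))
  # genomes made only of far SNPs assign nothing
  far <- simulate_genome(5, 30, 1, seed = 3, snp_mix = c(0, 0, 1))
  expect_true(all(is.na(assign_snps_to_genes(far$snps, far$genes)$gene_id)))
})

test_that("feature generator respects the simplex and separation semantics", {
  f <- simulate_protein_features(200, 200, separation = 0, seed = 13)
  expect_equal(unname(rowSums(f$features[, 1:20])), rep(1, 400),
               tolerance = 1e-9)
  expect_true(all(f$features[, 27] >= 0 & f$features[, 27] <= 1))
  expect_true(all(f$features[, 27] + f$features[, 28] <= 1 + 1e-12))
  # separation 0: per-dimension class mean differences within 3 SE
  pos <- f$features[f$labels == "pos", ]
  neg <- f$features[f$labels == "neg", ]
  dmean <- colMeans(pos) - colMeans(neg)
  se <- sqrt(apply(pos, 2, var) / nrow(pos) + apply(neg, 2, var) / nrow(neg))
  expect_lte(mean(abs(dmean) > 3 * se), 2 / 28)
})

test_that("features survive the FASTA/crystal round trip up to sampling noise", {
  f <- simulate_protein_features(4, 4, separation = 2, seed = 21)
  fa <- withr::local_tempfile(fileext = ".fasta")
  xt <- withr::local_tempfile(fileext = ".tsv")
  features_to_files(f$features, fa, xt, seq_length = 2000, seed = 22)
  rec <- read_protein_records(fa, xt)
  back <- build_feature_matrix(rec)$features[rownames(f$features), ]
  expect_equal(back[, 21:28], f$features[, 21:28], tolerance = 1e-9)
  expect_lt(max(abs(back[, 1:20] - f$features[, 1:20])), 0.05)
})

test_that("annotation clustering is calibrated at zero and detected when strong", {
  uni <- sprintf("g%03d", 1:300)
  disease <- uni[1:25]
  null_ann <- simulate_annotations(uni, disease, n_categories = 60,
                                   clustering_strength = 0, seed = 6)
  pn <- unlist(lapply(null_ann$catalogs, function(cat)
    enriched_categories(disease, cat, alpha = 1, min_overlap = 0)$p))
  frac05 <- mean(pn <= 0.05)
  expect_lte(frac05, 0.05 + 3 * sqrt(0.05 * 0.95 / length(pn)))
  strong <- simulate_annotations(uni, disease, n_categories = 60,
                                 clustering_strength = 0.95, seed = 6)
  for (ns in c("pirsf", "go", "kegg")) {
    enr <- enriched_categories(disease, strong$catalogs[[ns]],
                               alpha = 0.05, min_overlap = 2)
    expect_true(all(strong$truth[[ns]] %in% enr$category))
    expect_true(all(uni %in% strong$catalogs[[ns]]$universe))
  }
})
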