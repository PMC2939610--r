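#' Population model for genotype-count simulation
#'
#' The prospective case-control model: each individual has a genotype
#' (AA/AB/BB, Hardy-Weinberg proportions at allele frequency `p`) and is a
#' case with probability `theta[j]` given genotype j. Three modes:
#' `"fixed"` draws genotypes for `n_cases + n_controls` individuals and
#' assigns case status per genotype; `"margins"` fixes the per-genotype
#' totals `margins` and assigns case status per genotype; `"marginal_null"`
#' fixes the margins and draws one shared theta ~ Uniform(0, 1) per SNP
#' (the design under which the expected Bayes factor is exactly 1).
#'
#' @param p allele frequency of A, in (0, 1).
#' @param theta length-3 per-genotype case probabilities (AA, AB, BB).
#' @param theta_null shared case probability for non-causal SNPs.
#' @param n_cases,n_controls cohort design sizes (mode `"fixed"`).
#' @param margins length-3 per-genotype totals (margins modes).
#' @param mode see above.
#' @return a validated `population_model` list.
#' @export
population_model <- function(p = 0.3, theta = c(0.5, 0.5, 0.5),
                             theta_null = NULL, n_cases = NULL,
                             n_controls = NULL, margins = NULL,
                             mode = c("fixed", "margins", "marginal_null")) {
  mode <- match.arg(mode)
  stopifnot(p > 0, p < 1, length(theta) == 3, all(theta >= 0), all(theta <= 1))
  if (is.null(theta_null)) theta_null <- theta[2]
  if (mode == "fixed") {
    stopifnot(!is.null(n_cases), !is.null(n_controls),
              n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0)
  } else {
    stopifnot(!is.null(margins), length(margins) == 3, all(margins >= 0))
  }
  structure(list(p = p, theta = theta, theta_null = theta_null,
                 n_cases = n_cases, n_controls = n_controls,
                 margins = margins, mode = mode),
            class = "population_model")
}

#' Simulate genotype count tables with planted causal SNPs
#'
#' Individuals are assigned genotypes (Hardy-Weinberg) and then case status
#' with probability `theta[genotype]` for causal SNPs or the shared
#' `theta_null` for null SNPs; per-genotype case counts are tabulated via
#' the equivalent binomial draws. In `"marginal_null"` mode every SNP draws
#' its own shared theta ~ Uniform(0, 1) on fixed genotype margins.
#'
#' @param model a [population_model()].
#' @param n_snps number of SNPs.
#' @param causal_fraction fraction of SNPs using the causal `theta` vector.
#' @param seed integer seed (bit-reproducible output).
#' @param maf_range optional c(lo, hi): per-SNP allele frequencies drawn
#'   uniformly in this range instead of the model's fixed `p`.
#' @param snp_ids optional identifiers (default `snp0001`, ...).
#' @param causal_ids optional: exactly these SNPs are causal (overrides
#'   `causal_fraction`).
#' @return list `counts` (genotype count data frame) and `truth`
#'   (`causal_snps`, `effect` = theta\[3\] - theta\[1\]).
#' @export
simulate_genotype_counts <- function(model, n_snps, causal_fraction = 0,
                                     seed = 1, maf_range = NULL,
                                     snp_ids = NULL, causal_ids = NULL) {
  stopifnot(inherits(model, "population_model"), n_snps >= 1,
            causal_fraction >= 0, causal_fraction <= 1)
  if (is.null(snp_ids))
    snp_ids <- sprintf("snp%04d", seq_len(n_snps))
  stopifnot(length(snp_ids) == n_snps)
  withr::with_seed(seed, {
    if (is.null(causal_ids)) {
      n_causal <- round(causal_fraction * n_snps)
      causal_ids <- if (n_causal > 0) sample(snp_ids, n_causal) else character(0)
    }
    causal <- snp_ids %in% causal_ids
    counts <- matrix(0L, n_snps, 6,
                     dimnames = list(NULL, COUNT_COLS))
    for (i in seq_len(n_snps)) {
      p <- if (is.null(maf_range)) model$p else
        stats::runif(1, maf_range[1], maf_range[2])
      hw <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
      m <- switch(model$mode,
        fixed = as.integer(stats::rmultinom(1, model$n_cases + model$n_controls, hw)),
        model$margins)
      th <- if (model$mode == "marginal_null") rep(stats::runif(1), 3)
            else if (causal[i]) model$theta else rep(model$theta_null, 3)
      nja <- stats::rbinom(3, m, th)
      counts[i, ] <- c(nja, m - nja)
    }
    out <- data.frame(snp_id = snp_ids, counts, stringsAsFactors = FALSE)
    list(counts = out,
         truth = list(causal_snps = sort(causal_ids),
                      effect = model$theta[3] - model$theta[1]))
  })
}

#' Simulate a toy genome: genes, SNPs and disease loci
#'
#' Places `n_genes` non-overlapping gene intervals on the given chromosomes
#' (the tail of each chromosome is left gene-free so that far SNPs exist),
#' marks `n_genes_in_loci` genes as locus members grouped into `n_loci`
#' disease loci (a locus spans a run of consecutive selected genes and is
#' padded only into the flanking intergenic gaps, so exactly the selected
#' genes overlap loci), and scatters SNPs inside genes, near genes (within
#' `near_window`) and far from all genes in the proportions `snp_mix`.
#'
#' @param n_genes,n_snps,n_loci counts of simulated entities.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @param gene_length length of every gene interval, bases.
#' @param n_genes_in_loci genes covered by disease loci
#'   (default 30 percent).
#' @param snp_mix length-3 proportions c(inside, near, far).
#' @param near_window "near" SNP window in bases.
#' @return list `genes`, `snps`, `loci` (interval / position data frames)
#'   and `truth` (`genes_in_loci`, per-SNP intended `snp_gene` assignment at
#'   `near_window`).
#' @export
simulate_genome <- function(n_genes, n_snps, n_loci,
                            chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                            seed = 1, gene_length = 2e4,
                            n_genes_in_loci = NULL,
                            snp_mix = c(0.6, 0.3, 0.1),
                            near_window = 5e5) {
  stopifnot(n_genes >= 1, n_snps >= 1, n_loci >= 1)
  if (is.null(n_genes_in_loci)) n_genes_in_loci <- ceiling(0.3 * n_genes)
  stopifnot(n_genes_in_loci <= n_genes, n_loci <= max(n_genes_in_loci, 1))
  snp_mix <- snp_mix / sum(snp_mix)
  n_chrom <- length(chrom_lengths)
  # genes live in the first 2/3 of each chromosome; the rest is desert
  gene_zone <- floor(chrom_lengths * 2 / 3)
  slot_gap <- 2 * near_window / 5          # 200 kb between gene slots
  slots_per_chrom <- floor(gene_zone / (gene_length + slot_gap))
  if (sum(slots_per_chrom) < n_genes)
    stop("chromosomes too short to pack ", n_genes, " non-overlapping genes")
  if (any(chrom_lengths - gene_zone < 2 * near_window))
    stop("chromosome tails too short for far-from-gene SNPs")

  withr::with_seed(seed, {
    chrom_of <- rep(names(chrom_lengths),
                    pmin(slots_per_chrom, ceiling(n_genes / n_chrom) + 1))
    chrom_of <- sort(chrom_of)[seq_len(n_genes)]
    genes <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      k <- sum(chrom_of == ch)
      if (k == 0) return(NULL)
      starts <- round(seq(1e5, gene_zone[[ch]] - gene_length, length.out = k))
      data.frame(chrom = ch, start = starts, end = starts + gene_length - 1,
                 stringsAsFactors = FALSE)
    }))
    ord <- order(genes$chrom, genes$start)
    genes <- genes[ord, , drop = FALSE]
    genes$id <- sprintf("gene%03d", seq_len(n_genes))
    genes <- genes[c("id", "chrom", "start", "end")]

    # choose n_loci runs of consecutive genes totalling n_genes_in_loci
    run_sizes <- tabulate(sample(n_loci, n_genes_in_loci, replace = TRUE),
                          nbins = n_loci)
    run_sizes[run_sizes == 0] <- 1
    while (sum(run_sizes) > n_genes_in_loci)
      run_sizes[which.max(run_sizes)] <- run_sizes[which.max(run_sizes)] - 1L
    sel <- logical(n_genes)
    loci <- NULL
    # place runs greedily on gene indices, keeping a one-gene buffer
    avail <- seq_len(n_genes)
    for (r in seq_len(n_loci)) {
      len <- run_sizes[r]
      ok_starts <- Filter(function(s) {
        idx <- s:(s + len - 1)
        max(idx) <= n_genes &&
          length(unique(genes$chrom[idx])) == 1 &&
          all(idx %in% avail) &&
          !any(c(min(idx) - 1, max(idx) + 1) %in% which(sel))
      }, avail)
      if (length(ok_starts) == 0) stop("cannot place disease loci; too dense")
      s <- if (length(ok_starts) == 1) ok_starts else sample(ok_starts, 1)
      idx <- s:(s + len - 1)
      sel[idx] <- TRUE
      avail <- setdiff(avail, c(idx, min(idx) - 1, max(idx) + 1))
      ch <- genes$chrom[s]
      same <- which(genes$chrom == ch)
      prev_end <- if (min(idx) > min(same)) genes$end[min(idx) - 1] else 0
      next_start <- if (max(idx) < max(same)) genes$start[max(idx) + 1]
                    else chrom_lengths[[ch]]
      loci <- rbind(loci, data.frame(
        id = sprintf("locus%02d", r), chrom = ch,
        start = floor((prev_end + genes$start[min(idx)]) / 2) + 1,
        end = floor((genes$end[max(idx)] + next_start) / 2),
        stringsAsFactors = FALSE))
    }

    # SNP placement
    cat_n <- stats::rmultinom(1, n_snps, snp_mix)[, 1]
    pos <- character(0)
    place_inside <- function(k) {
      g <- genes[sample(n_genes, k, replace = TRUE), ]
      data.frame(chrom = g$chrom,
                 pos = g$start + floor(stats::runif(k) * (g$end - g$start + 1)))
    }
    place_near <- function(k) {
      g <- genes[sample(n_genes, k, replace = TRUE), ]
      off <- sample(c(-1, 1), k, replace = TRUE) *
        floor(stats::runif(k, 1, slot_gap / 2 - 1))
      p <- ifelse(off < 0, g$start + off, g$end + off)
      data.frame(chrom = g$chrom, pos = pmax(1, p))
    }
    place_far <- function(k) {
      ch <- sample(names(chrom_lengths), k, replace = TRUE)
      lo <- gene_zone[ch] + near_window + 1
      hi <- chrom_lengths[ch]
      data.frame(chrom = ch, pos = floor(stats::runif(k, lo, hi)))
    }
    snps <- rbind(place_inside(cat_n[1]), place_near(cat_n[2]),
                  place_far(cat_n[3]))
    snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
                       snps, stringsAsFactors = FALSE)

    # intended assignment by direct per-SNP scan
    truth_assign <- vapply(seq_len(n_snps), function(i) {
      g <- genes[genes$chrom == snps$chrom[i], , drop = FALSE]
      d <- pmax(g$start - snps$pos[i], snps$pos[i] - g$end, 0)
      j <- which(d == min(d))
      j <- j[order(g$id[j])][1]
      if (d[j] <= near_window) g$id[j] else NA_character_
    }, character(1))

    list(genes = genes, snps = snps, loci = loci,
         truth = list(genes_in_loci = genes$id[sel],
                      snp_gene = stats::setNames(truth_assign, snps$snp_id)))
  })
}

#' Simulate class-conditional protein feature vectors
#'
#' Generates 28-dimension feature vectors from class-conditional Gaussians
#' over the feature dimensions, then restores the type constraints:
#' compositions are floored at a small positive value and renormalized to
#' the simplex, cell lengths floored at 5 Angstroms, angles clipped to
#' (1, 179) degrees and helix/sheet fractions to [0, 1] with
#' helix + sheet <= 1. The positive-class mean is shifted, in per-dimension
#' standard-deviation units, by a vector of total magnitude `separation`
#' spread over `signal_dims` with alternating sign (so the shift survives
#' the simplex renormalization); `separation = 0` gives identical class
#' distributions.
#'
#' @param n_pos,n_neg training-pool sizes per class.
#' @param n_test_pos,n_test_neg test vectors drawn from each class.
#' @param separation mean-shift magnitude in standard-deviation units.
#' @param signal_dims which of the 28 dims carry the shift.
#' @param seed integer seed.
#' @param ids optional gene ids (length = total vectors).
#' @return list `features` (matrix, rownames = ids), `labels`
#'   (`"pos"`/`"neg"`), `role` (`"train"`/`"test"`), `truth`.
#' @export
simulate_protein_features <- function(n_pos, n_neg, n_test_pos = 0,
                                      n_test_neg = 0, separation = 0,
                                      signal_dims = 1:28, seed = 1,
                                      ids = NULL) {
  stopifnot(separation >= 0, all(signal_dims %in% 1:28))
  n <- n_pos + n_neg + n_test_pos + n_test_neg
  labels <- rep(c("pos", "neg", "pos", "neg"),
                c(n_pos, n_neg, n_test_pos, n_test_neg))
  role <- rep(c("train", "test"), c(n_pos + n_neg, n_test_pos + n_test_neg))
  if (is.null(ids)) ids <- sprintf("prot%04d", seq_len(n))
  stopifnot(length(ids) == n)
  mu <- c(seq(0.07, 0.03, length.out = 20),      # composition means
          60, 60, 60, 90, 90, 90, 0.25, 0.20)
  sig <- c(rep(0.02, 20), 12, 12, 12, 15, 15, 15, 0.07, 0.06)
  shift <- numeric(28)
  shift[signal_dims] <- separation / sqrt(length(signal_dims)) *
    (-1)^(seq_along(signal_dims) - 1)
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * 28), n, 28)
    z[labels == "pos", ] <- sweep(z[labels == "pos", , drop = FALSE], 2,
                                  shift, "+")
    feats <- sweep(sweep(z, 2, sig, "*"), 2, mu, "+")
    dimnames(feats) <- list(ids, FEATURE_NAMES)
    comp <- pmax(feats[, 1:20, drop = FALSE], 1e-4)
    feats[, 1:20] <- comp / rowSums(comp)
    feats[, 21:23] <- pmax(feats[, 21:23, drop = FALSE], 5)
    feats[, 24:26] <- pmin(pmax(feats[, 24:26, drop = FALSE], 1), 179)
    hel <- pmin(pmax(feats[, 27], 0), 1)
    she <- pmin(pmax(feats[, 28], 0), 1 - hel)
    feats[, 27] <- hel
    feats[, 28] <- she
    list(features = feats, labels = labels, role = role,
         truth = list(separation = separation, signal_dims = signal_dims))
  })
}

#' Turn feature vectors into FASTA sequences and a crystal TSV
#'
#' A sequence of length `seq_length` is sampled per protein with residue
#' probabilities equal to its composition block, so the recomputed
#' composition approximates the vector up to multinomial noise; the
#' secondary block is written to the crystal table as-is (helix/sheet as
#' fractions).
#'
#' @param features genes x 28 matrix with rownames.
#' @param fasta,crystal output paths.
#' @param seq_length sampled sequence length.
#' @param seed integer seed.
#' @export
features_to_files <- function(features, fasta, crystal, seq_length = 1000,
                              seed = 1) {
  withr::with_seed(seed, {
    seqs <- apply(features[, 1:20, drop = FALSE], 1, function(p)
      paste(sample(AA20, seq_length, replace = TRUE, prob = p), collapse = ""))
  })
  writeLines(paste0(">", rownames(features), "\n", seqs), fasta)
  xt <- data.frame(gene_id = rownames(features),
                   features[, 21:28, drop = FALSE],
                   stringsAsFactors = FALSE)
  names(xt) <- c("gene_id", "a", "b", "c", "alpha", "beta", "gamma",
                 "helix", "sheet")
  utils::write.table(xt, crystal, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, crystal = crystal))
}

#' Simulate annotation catalogs with co-clustering disease genes
#'
#' Each namespace gets `n_categories`; every gene receives `n_background`
#' uniform background annotations. A few designated "disease categories"
#' additionally receive each gene of `disease_genes` with probability
#' `clustering_strength`, so at high strength those categories are
#' hypergeometrically enriched for disease genes; at strength 0 the catalog
#' is an exchangeable null.
#'
#' @param genes gene universe.
#' @param disease_genes functionally co-clustering genes (subset of
#'   `genes`); typically known disease genes plus planted causal genes.
#' @param n_categories categories per namespace.
#' @param n_disease_categories designated disease categories per namespace.
#' @param clustering_strength probability in [0, 1].
#' @param n_background background annotations per gene.
#' @param seed integer seed.
#' @return list `catalogs` (named `pirsf`, `go`, `kegg`) and `truth`
#'   (designed disease categories per namespace).
#' @export
simulate_annotations <- function(genes, disease_genes, n_categories = 50,
                                 n_disease_categories = 3,
                                 clustering_strength = 0.9,
                                 n_background = 2, seed = 1) {
  stopifnot(all(disease_genes %in% genes),
            clustering_strength >= 0, clustering_strength <= 1,
            n_disease_categories < n_categories)
  namespaces <- c(pirsf = "PIRSF", go = "GO", kegg = "KEGG")
  withr::with_seed(seed, {
    out <- lapply(names(namespaces), function(ns) {
      cats <- sprintf("%s_%03d", toupper(ns), seq_len(n_categories))
      dcats <- cats[seq_len(n_disease_categories)]
      ann <- lapply(genes, function(g) sample(cats, n_background))
      names(ann) <- genes
      for (g in disease_genes) {
        hit <- dcats[stats::runif(n_disease_categories) < clustering_strength]
        ann[[g]] <- unique(c(ann[[g]], hit))
      }
      pairs <- data.frame(gene = rep(names(ann), lengths(ann)),
                          cat = unlist(ann, use.names = FALSE),
                          stringsAsFactors = FALSE)
      cat2gene <- split(pairs$gene, factor(pairs$cat, levels = cats))
      cat2gene <- cat2gene[lengths(cat2gene) > 0]
      list(catalog = annotation_catalog(cat2gene, namespaces[[ns]],
                                        universe = genes),
           disease_categories = dcats)
    })
    names(out) <- names(namespaces)
    list(catalogs = lapply(out, `[[`, "catalog"),
         truth = lapply(out, `[[`, "disease_categories"))
  })
}
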