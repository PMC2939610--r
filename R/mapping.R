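#' Read a BED file of genes or disease loci
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' internal 1-based inclusive convention on read (via [rtracklayer]).
#'
#' @param path BED file (columns chrom, start, end, name).
#' @return data frame `id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("feat", seq_along(gr))
  data.frame(id = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param df data frame `id`, `chrom`, `start`, `end` (1-based inclusive).
#' @param path output BED path.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               name = df$id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Assign SNPs to genes within a distance window
#'
#' Each SNP is assigned to the gene containing it, or failing that to the
#' nearest gene on the same chromosome within `max_distance` bases (distance
#' to the nearest interval boundary, 0 inside). SNPs farther than
#' `max_distance` from every gene are left unassigned. Ties on distance are
#' broken by the lexicographically smallest `gene_id`, so the result does
#' not depend on the order of the gene table.
#'
#' The 500 kb default window reflects that most enhancers/repressors and
#' linkage-disequilibrium blocks lie within 500 kb of a gene.
#'
#' @param snps data frame `snp_id`, `chrom`, `pos` (1-based).
#' @param genes data frame `id` (or `gene_id`), `chrom`, `start`, `end`.
#' @param max_distance maximum SNP-to-gene distance in bases.
#' @return data frame `snp_id`, `gene_id` (NA if unassigned), `distance`.
#' @export
assign_snps_to_genes <- function(snps, genes, max_distance = 500000L) {
  stopifnot(max_distance >= 0)
  genes <- normalize_intervals(genes, "gene")
  out <- data.frame(snp_id = as.character(snps$snp_id),
                    gene_id = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || nrow(genes) == 0) return(out)
  # lexicographic order once; which.min then realizes the tie-break
  genes <- genes[order(genes$id), , drop = FALSE]
  for (ch in unique(snps$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    idx <- which(snps$chrom == ch)
    if (nrow(g) == 0 || length(idx) == 0) next
    d <- outer(g$start, snps$pos[idx], "-")          # start - pos
    d2 <- outer(snps$pos[idx], g$end, "-")           # pos - end
    dist <- pmax(d, t(d2), 0)                        # genes x snps
    best <- apply(dist, 2, which.min)
    bestd <- dist[cbind(best, seq_along(idx))]
    ok <- bestd <= max_distance
    out$gene_id[idx[ok]] <- g$id[best[ok]]
    out$distance[idx[ok]] <- bestd[ok]
  }
  out
}

normalize_intervals <- function(df, what) {
  idcol <- intersect(c("id", paste0(what, "_id"), "locus_id"), names(df))[1]
  if (is.na(idcol)) stop("interval table needs an id column")
  out <- data.frame(id = as.character(df[[idcol]]),
                    chrom = as.character(df$chrom),
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("interval with start > end")
  if (any(out$start < 1)) stop("intervals are 1-based; start must be >= 1")
  out
}

#' First-dimensional (genetic) screen
#'
#' Builds the test set for the structural screen: genes that received at
#' least one significant SNP (log Bayes factor > 0) under
#' [assign_snps_to_genes()] and whose interval overlaps at least one disease
#' locus on the same chromosome (any shared base).
#'
#' @param significant_snps character vector of SNP ids with `bfln > 0`.
#' @param snps data frame `snp_id`, `chrom`, `pos`.
#' @param genes gene intervals (`id`/`gene_id`, `chrom`, `start`, `end`).
#' @param loci disease-locus intervals (same columns).
#' @param max_distance passed to [assign_snps_to_genes()].
#' @return sorted character vector of test-set gene ids.
#' @export
genetic_screen <- function(significant_snps, snps, genes, loci,
                           max_distance = 500000L) {
  genes <- normalize_intervals(genes, "gene")
  if (nrow(loci) == 0) {
    warning("empty disease-locus collection: genetic screen returns no genes")
    return(character(0))
  }
  loci <- normalize_intervals(loci, "locus")
  hits <- assign_snps_to_genes(snps[snps$snp_id %in% significant_snps, ,
                                    drop = FALSE], genes, max_distance)
  hit_genes <- unique(hits$gene_id[!is.na(hits$gene_id)])
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
  gr_loci <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start, loci$end))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_loci)
  in_loci <- genes$id[unique(S4Vectors::queryHits(ov))]
  sort(intersect(hit_genes, in_loci))
}
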