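#' Collapse genotype counts to allelic counts
#'
#' Each AA individual carries two A alleles, each AB one of each, each BB
#' two B alleles, so `case_a = 2*n0A + n1A`, `case_b = 2*n2A + n1A`, and
#' likewise for controls. Allele totals are twice the individual totals.
#'
#' @param counts genotype count data frame.
#' @return data frame `snp_id`, `case_a`, `case_b`, `ctrl_a`, `ctrl_b`.
#' @export
to_allelic <- function(counts) {
  validate_genotype_counts(counts)
  data.frame(snp_id = counts$snp_id,
             case_a = 2 * counts$n0A + counts$n1A,
             case_b = 2 * counts$n2A + counts$n1A,
             ctrl_a = 2 * counts$n0U + counts$n1U,
             ctrl_b = 2 * counts$n2U + counts$n1U,
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With all margins fixed, the count in the top-left cell is hypergeometric;
#' the two-sided p-value sums the point probabilities of every table at most
#' as probable as the observed one (the usual small-relative-tolerance tie
#' rule guards against floating-point near-ties). A zero margin makes the
#' table degenerate and returns p = 1.
#'
#' @param a,b top row counts; `c_`,`d` bottom row counts (vectorized).
#' @return numeric vector of two-sided p-values in `(0, 1]`.
#' @export
fisher_exact <- function(a, b, c_, d) {
  stopifnot(length(a) == length(b), length(b) == length(c_),
            length(c_) == length(d))
  if (any(c(a, b, c_, d) < 0)) stop("negative cell count")
  mapply(function(a, b, c_, d) {
    m1 <- a + b; m2 <- c_ + d; k <- a + c_
    if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
    lo <- max(0, k - m2); hi <- min(k, m1)
    support <- lo:hi
    pp <- stats::dhyper(support, m1, m2, k)
    min(1, sum(pp[pp <= pp[support == a] * (1 + 1e-7)]))
  }, a, b, c_, d)
}

#' Fisher exact scan over allelic tables
#'
#' @param allelic data frame from [to_allelic()].
#' @return data frame `snp_id`, `p_value`.
#' @export
fisher_scan <- function(allelic) {
  data.frame(snp_id = allelic$snp_id,
             p_value = fisher_exact(allelic$case_a, allelic$case_b,
                                    allelic$ctrl_a, allelic$ctrl_b),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance screen
#'
#' Significance threshold = `alpha / n_tests` (family-wise error control),
#' or a user-supplied literal `threshold` overriding the computation. SNPs
#' with `p < threshold` are significant.
#'
#' @param pvalues data frame `snp_id`, `p_value`.
#' @param alpha family-wise error rate.
#' @param n_tests number of tests; defaults to `nrow(pvalues)`.
#' @param threshold optional literal per-test threshold.
#' @return list `significant` (SNP ids), `threshold`, and `results`
#'   (`pvalues` plus a `significant` column, sorted by p).
#' @export
bonferroni_screen <- function(pvalues, alpha = 0.05, n_tests = NULL,
                              threshold = NULL) {
  if (is.null(n_tests)) n_tests <- max(nrow(pvalues), 1L)
  stopifnot(n_tests >= 1)
  if (is.null(threshold)) threshold <- alpha / n_tests
  sig <- pvalues$p_value < threshold
  res <- data.frame(pvalues, significant = sig, stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  list(significant = pvalues$snp_id[sig], threshold = threshold,
       results = res)
}

#' Overlap report between two gene sets
#'
#' Symmetric summary of the genes found by the multidimensional screen
#' versus the traditional GWAS baseline: set sizes, intersection and
#' Jaccard index (defined as 1 when both sets are empty).
#'
#' @param set_a,set_b character vectors from the same gene universe.
#' @return list `n_a`, `n_b`, `n_intersection`, `n_union`, `intersection`,
#'   `jaccard`.
#' @export
compare_methods <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  inter <- sort(intersect(set_a, set_b))
  uni <- union(set_a, set_b)
  list(n_a = length(set_a), n_b = length(set_b),
       n_intersection = length(inter), n_union = length(uni),
       intersection = inter,
       jaccard = if (length(uni) == 0) 1 else length(inter) / length(uni))
}
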