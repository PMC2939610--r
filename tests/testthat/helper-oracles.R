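# Independent oracles used across the suite. They deliberately avoid the
# code paths they check: log-factorials by cumulative summation of logs
# (not lgamma), nearest-interval search by a plain per-SNP loop, and
# hypergeometric enumeration from exact binomial coefficients.

# ln n! as sum(log(1..n)); ln B(a,b) in exact factorial form for integer a,b
lfact_sum <- function(n) if (n == 0) 0 else sum(log(seq_len(n)))
lbeta_fact <- function(a, b) lfact_sum(a - 1) + lfact_sum(b - 1) -
  lfact_sum(a + b - 1)

oracle_bfln <- function(n0A, n1A, n2A, n0U, n1U, n2U) {
  nA <- n0A + n1A + n2A
  nU <- n0U + n1U + n2U
  lbeta_fact(n0A + 1, n0U + 1) + lbeta_fact(n1A + 1, n1U + 1) +
    lbeta_fact(n2A + 1, n2U + 1) - lbeta_fact(nA + 1, nU + 1)
}

# random 2x3 tables with bounded total
random_tables <- function(n, max_total, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      tot <- sample(0:max_total, 1)
      as.vector(stats::rmultinom(1, tot, rep(1 / 6, 6)))
    }, numeric(6)))
  })
}

counts_df <- function(m, ids = sprintf("s%04d", seq_len(nrow(m)))) {
  df <- data.frame(snp_id = ids, m, stringsAsFactors = FALSE)
  names(df) <- c("snp_id", "n0A", "n1A", "n2A", "n0U", "n1U", "n2U")
  df
}

# brute-force nearest-gene assignment (containment, boundary distance,
# lexicographic tie-break), one SNP at a time
oracle_assign <- function(snps, genes, max_distance = 500000) {
  vapply(seq_len(nrow(snps)), function(i) {
    best_id <- NA_character_
    best_d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != snps$chrom[i]) next
      d <- max(genes$start[j] - snps$pos[i], snps$pos[i] - genes$end[j], 0)
      if (d < best_d || (d == best_d && genes$id[j] < best_id)) {
        best_d <- d
        best_id <- genes$id[j]
      }
    }
    if (best_d <= max_distance) best_id else NA_character_
  }, character(1))
}

# two-sided Fisher p by exhaustive enumeration with exact binomial
# coefficients (doubles are exact for the margins used in tests)
oracle_fisher <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  pp <- choose(m1, support) * choose(m2, k - support) / choose(N, k)
  sum(pp[pp <= pp[support == a] * (1 + 1e-7)])
}

# hypergeometric upper tail P(X >= k) by enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# tiny annotation catalog builder
toy_catalog <- function(cat2gene, ns = "KEGG", universe = NULL) {
  annotation_catalog(cat2gene, ns, universe)
}
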