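#' Genotype count tables
#'
#' A genotype count table records, for one SNP, how many cases (affected) and
#' controls (unaffected) carry each of the three genotypes AA, AB and BB.
#' Collections of tables are plain data frames with columns `snp_id`,
#' `n0A`, `n1A`, `n2A` (cases with AA, AB, BB) and `n0U`, `n1U`, `n2U`
#' (controls), optionally `chrom` and `pos` (1-based).
#'
#' @param df data frame to validate.
#' @return `df`, invisibly, after validation.
#' @export
validate_genotype_counts <- function(df) {
  cols <- c("snp_id", COUNT_COLS)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("genotype count table lacks columns: ", paste(missing, collapse = ", "))
  cnt <- as.matrix(df[COUNT_COLS])
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  if (anyDuplicated(df$snp_id))
    stop("duplicated snp_id in genotype count table")
  invisible(df)
}

COUNT_COLS <- c("n0A", "n1A", "n2A", "n0U", "n1U", "n2U")

#' Natural log of the Beta function
#'
#' `ln B(a, b) = ln Gamma(a) + ln Gamma(b) - ln Gamma(a + b)`, evaluated in
#' log space so that arguments in the millions do not overflow.
#'
#' @param a,b positive reals (vectorized).
#' @return numeric vector of `ln B(a, b)`.
#' @export
#' @examples
#' log_beta(1, 1)  # 0
#' log_beta(3, 2)  # log(1/12)
log_beta <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("log_beta requires strictly positive arguments")
  lbeta(a, b)
}

#' Log Bayes factor for genotype association
#'
#' For each SNP, compares the marginal likelihood of the 2x3 case/control by
#' genotype table under association (independent uniform priors on the three
#' per-genotype case probabilities) against no association (one shared case
#' probability, uniform prior). Both marginals are Beta functions of the
#' counts, so
#'
#' `BFLn = sum_j ln B(njA + 1, njU + 1) - ln B(nA + 1, nU + 1)`
#'
#' with `nA`, `nU` the case and control totals. `BFLn > 0` supports
#' association (H1); `BFLn < 0` supports the null.
#'
#' @param counts genotype count data frame (see [validate_genotype_counts()]).
#' @return data frame `snp_id`, `bfln`, `supports_h1` in input order.
#' @export
#' @examples
#' bfln(data.frame(snp_id = "rs1", n0A = 2, n1A = 1, n2A = 0,
#'                 n0U = 0, n1U = 1, n2U = 2))  # log(70/27)
bfln <- function(counts) {
  validate_genotype_counts(counts)
  nA <- counts$n0A + counts$n1A + counts$n2A
  nU <- counts$n0U + counts$n1U + counts$n2U
  b <- lbeta(counts$n0A + 1, counts$n0U + 1) +
    lbeta(counts$n1A + 1, counts$n1U + 1) +
    lbeta(counts$n2A + 1, counts$n2U + 1) -
    lbeta(nA + 1, nU + 1)
  data.frame(snp_id = counts$snp_id, bfln = b, supports_h1 = b > 0,
             stringsAsFactors = FALSE)
}

#' Quality-control filter for genotype count tables
#'
#' Removes SNPs failing any of three standard pre-association checks:
#' minor allele frequency below `min_maf` (alleles pooled over cases and
#' controls), total genotyped count below `min_call * cohort_size` (a proxy
#' for call rate), or departure from Hardy-Weinberg equilibrium in controls
#' (1-df chi-square goodness of fit) with p below `max_hwe_p`. A SNP with no
#' controls skips the HWE rule (recorded in `notes`).
#'
#' @param counts genotype count data frame.
#' @param min_maf minimum minor allele frequency, in `[0, 0.5]`.
#' @param min_call minimum fraction of the cohort with a genotype, in `[0, 1]`.
#' @param max_hwe_p reject when the control HWE p-value is below this.
#' @param cohort_size denominator for the call-rate proxy; defaults to the
#'   largest total count observed across SNPs.
#' @return list with `pass` (surviving tables), `rejected` (data frame
#'   `snp_id`, `rule`, `value`; first failing rule per SNP), and `notes`
#'   (character vector of per-SNP remarks such as skipped HWE tests).
#' @export
qc_filter <- function(counts, min_maf = 0.01, min_call = 0.95,
                      max_hwe_p = 1e-6, cohort_size = NULL) {
  validate_genotype_counts(counts)
  if (nrow(counts) == 0) stop("qc_filter: empty input")
  stopifnot(min_maf >= 0, min_maf <= 0.5, min_call >= 0, min_call <= 1,
            max_hwe_p >= 0, max_hwe_p <= 1)
  m0 <- counts$n0A + counts$n0U
  m1 <- counts$n1A + counts$n1U
  m2 <- counts$n2A + counts$n2U
  total <- m0 + m1 + m2
  if (is.null(cohort_size)) cohort_size <- max(total)

  a_cnt <- 2 * m0 + m1
  b_cnt <- 2 * m2 + m1
  maf <- ifelse(total > 0, pmin(a_cnt, b_cnt) / (2 * total), 0)
  call_frac <- if (cohort_size > 0) total / cohort_size else rep(1, nrow(counts))

  hwe_p <- mapply(hwe_chisq_p, counts$n0U, counts$n1U, counts$n2U)
  no_controls <- (counts$n0U + counts$n1U + counts$n2U) == 0
  notes <- character(0)
  if (any(no_controls))
    notes <- paste0(counts$snp_id[no_controls], ": no controls, HWE rule skipped")

  rule <- rep(NA_character_, nrow(counts))
  value <- rep(NA_real_, nrow(counts))
  fail_maf <- maf < min_maf
  fail_call <- !fail_maf & call_frac < min_call
  fail_hwe <- !fail_maf & !fail_call & !no_controls &
    !is.na(hwe_p) & hwe_p < max_hwe_p
  rule[fail_maf] <- "maf"; value[fail_maf] <- maf[fail_maf]
  rule[fail_call] <- "call"; value[fail_call] <- call_frac[fail_call]
  rule[fail_hwe] <- "hwe"; value[fail_hwe] <- hwe_p[fail_hwe]
  rejected <- !is.na(rule)
  list(pass = counts[!rejected, , drop = FALSE],
       rejected = data.frame(snp_id = counts$snp_id[rejected],
                             rule = rule[rejected], value = value[rejected],
                             stringsAsFactors = FALSE),
       notes = notes)
}

# 1-df chi-square goodness-of-fit p for Hardy-Weinberg proportions.
# Allele frequency estimated from the same counts; zero-expected cells
# (monomorphic data) contribute nothing, giving chi2 = 0.
hwe_chisq_p <- function(o0, o1, o2) {
  n <- o0 + o1 + o2
  if (n == 0) return(NA_real_)
  p <- (2 * o0 + o1) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(o0, o1, o2)
  keep <- e > 0
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Screen SNPs by Bayes factor
#'
#' Scores every table with [bfln()] and returns the identifiers of SNPs whose
#' log Bayes factor is strictly positive (nominal evidence for association),
#' together with the full score table sorted by decreasing `bfln`.
#'
#' @param counts genotype count data frame (normally QC-passed).
#' @return list with `significant` (character vector of SNP ids with
#'   `bfln > 0`) and `scores` (data frame sorted by `bfln`, descending).
#' @export
screen_snps <- function(counts) {
  if (nrow(counts) == 0)
    return(list(significant = character(0),
                scores = data.frame(snp_id = character(0), bfln = numeric(0),
                                    supports_h1 = logical(0))))
  scores <- bfln(counts)
  scores <- scores[order(-scores$bfln, scores$snp_id), , drop = FALSE]
  rownames(scores) <- NULL
  list(significant = scores$snp_id[scores$supports_h1], scores = scores)
}

#' Read and write genotype count tables
#'
#' Tab-separated with header
#' `snp_id chrom pos n0A n1A n2A n0U n1U n2U` (`pos` 1-based). `chrom`/`pos`
#' are optional on read.
#'
#' @param path file path.
#' @return `read_counts`: validated genotype count data frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$snp_id <- as.character(df$snp_id)
  validate_genotype_counts(df)
  df
}

#' @rdname read_counts
#' @param counts genotype count data frame.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write Bayes-factor scores
#'
#' TSV `snp_id bfln supports_h1`, sorted by `bfln` descending.
#'
#' @param scores data frame from [screen_snps()] or [bfln()].
#' @param path output file.
#' @export
write_bfln <- function(scores, path) {
  scores <- scores[order(-scores$bfln, scores$snp_id), , drop = FALSE]
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
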