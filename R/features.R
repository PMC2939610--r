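#' The 28-dimension physicochemical feature layout
#'
#' Dimensions 1-20 are the amino-acid composition (alphabetical one-letter
#' order), 21-26 the crystallographic unit-cell parameters (lengths a, b, c
#' in Angstroms; angles alpha, beta, gamma in degrees), 27 the helical
#' fraction and 28 the beta-sheet fraction of the protein. Dimensions 21-28
#' are referred to as the "secondary" feature block.
#'
#' @export
FEATURE_NAMES <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   "cell_a", "cell_b", "cell_c",
                   "cell_alpha", "cell_beta", "cell_gamma",
                   "helix", "sheet")

AA20 <- FEATURE_NAMES[1:20]

#' @rdname FEATURE_NAMES
#' @export
SECONDARY_DIMS <- 21:28

#' Amino-acid composition of a protein sequence
#'
#' Fraction of each of the 20 standard residues among the standard residues
#' of the sequence, in fixed alphabetical order (ACDEFGHIKLMNPQRSTVWY).
#' Non-standard letters (X, B, Z, ...) are excluded from both numerator and
#' denominator; their count is attached as attribute `n_nonstandard` and a
#' warning is raised when any occur.
#'
#' @param sequence amino-acid string.
#' @return named numeric vector of 20 fractions summing to 1.
#' @export
compute_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  aa <- Biostrings::AAString(toupper(sequence))
  cnt <- Biostrings::letterFrequency(aa, letters = AA20)
  n_std <- sum(cnt)
  if (n_std == 0) stop("sequence contains no standard amino-acid residues")
  n_bad <- length(aa) - n_std
  if (n_bad > 0)
    warning(n_bad, " non-standard residue(s) excluded from composition")
  out <- as.numeric(cnt) / n_std
  names(out) <- AA20
  attr(out, "n_nonstandard") <- n_bad
  out
}

#' Read protein records: sequences plus crystal parameters
#'
#' Sequences come from a FASTA file keyed by gene id (first word of the
#' header); crystal-structure parameters from a TSV
#' `gene_id a b c alpha beta gamma helix sheet` with empty cells meaning
#' missing. Helix/sheet values above 1.5 are interpreted as percentages and
#' divided by 100 (with a message), so either unit is accepted. When a gene
#' has several FASTA records the first wins (with a message).
#'
#' @param fasta path to the FASTA file.
#' @param crystal path to the crystal TSV, or NULL for sequence-only records.
#' @return data frame `gene_id`, `sequence`, `a`, `b`, `c`, `alpha`, `beta`,
#'   `gamma`, `helix`, `sheet` (NA = missing).
#' @export
read_protein_records <- function(fasta, crystal = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    message("duplicate FASTA ids; keeping the first record of each")
    keep <- !duplicated(ids)
    seqs <- seqs[keep]; ids <- ids[keep]
  }
  rec <- data.frame(gene_id = ids, sequence = as.character(seqs),
                    a = NA_real_, b = NA_real_, c = NA_real_,
                    alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                    helix = NA_real_, sheet = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(crystal)) {
    x <- utils::read.delim(crystal, stringsAsFactors = FALSE)
    x$gene_id <- as.character(x$gene_id)
    for (col in c("helix", "sheet")) {
      pct <- !is.na(x[[col]]) & x[[col]] > 1.5
      if (any(pct)) {
        message(sum(pct), " ", col, " value(s) > 1.5 read as percent")
        x[[col]][pct] <- x[[col]][pct] / 100
      }
    }
    m <- match(rec$gene_id, x$gene_id)
    for (col in c("a", "b", "c", "alpha", "beta", "gamma", "helix", "sheet"))
      rec[[col]] <- x[[col]][m]
  }
  rec
}

#' Build 28-dimension feature vectors from protein records
#'
#' Assembles, per gene, the composition block (from the sequence) and the
#' secondary block (unit cell, helix, sheet) in the fixed [FEATURE_NAMES]
#' order. Missing structural fields stay NA in the feature matrix and are
#' flagged in the missing mask; imputation happens later in
#' [standardize_features()].
#'
#' @param records data frame from [read_protein_records()].
#' @return list with `features` (genes x 28 numeric matrix, rownames =
#'   gene ids), `missing` (logical matrix of the same shape) and
#'   `n_nonstandard` (per-gene excluded residue counts).
#' @export
build_feature_matrix <- function(records) {
  n <- nrow(records)
  stopifnot(n > 0)
  feats <- matrix(NA_real_, n, 28, dimnames = list(records$gene_id, FEATURE_NAMES))
  nbad <- integer(n)
  for (i in seq_len(n)) {
    comp <- withCallingHandlers(compute_composition(records$sequence[i]),
                                warning = function(w) invokeRestart("muffleWarning"))
    nbad[i] <- attr(comp, "n_nonstandard")
    feats[i, 1:20] <- comp
  }
  sec <- as.matrix(records[c("a", "b", "c", "alpha", "beta", "gamma",
                             "helix", "sheet")])
  lens <- sec[, 1:3, drop = FALSE]
  if (any(!is.na(lens) & lens <= 0)) stop("unit-cell lengths must be positive")
  angs <- sec[, 4:6, drop = FALSE]
  if (any(!is.na(angs) & (angs <= 0 | angs >= 180)))
    stop("unit-cell angles must lie in (0, 180) degrees")
  fracs <- sec[, 7:8, drop = FALSE]
  if (any(!is.na(fracs) & (fracs < 0 | fracs > 1)))
    stop("helix/sheet fractions must lie in [0, 1]")
  hs <- rowSums(fracs)
  if (any(!is.na(hs) & hs > 1 + 1e-9))
    stop("helix + sheet fraction exceeds 1")
  feats[, 21:28] <- sec
  list(features = feats, missing = is.na(feats), n_nonstandard = nbad)
}

#' Subset a feature matrix to a named block
#'
#' @param features genes x 28 matrix.
#' @param subset `"full"` (all 28 dims) or `"secondary"` (dims 21-28).
#' @return the selected columns.
#' @export
feature_subset <- function(features, subset = c("full", "secondary")) {
  subset <- match.arg(subset)
  if (subset == "secondary") features[, SECONDARY_DIMS, drop = FALSE]
  else features
}

#' Standardize feature matrices (train-estimated z-scaling)
#'
#' Per-dimension centering and scaling with mean and standard deviation
#' estimated on the training matrix only; NAs are imputed with the training
#' mean of that dimension before scaling (`impute = "mean"`) or the rows
#' dropped (`impute = "drop"`, training rows only). Zero-variance training
#' dimensions are mapped to 0 everywhere (with a message). Mixed-unit
#' features (composition fractions, Angstrom lengths, degree angles) make
#' RBF-kernel classifiers scale-sensitive, hence scaling by default.
#'
#' @param train numeric matrix (rows = proteins).
#' @param apply optional matrix to transform with the train-estimated scaler.
#' @param impute `"mean"` or `"drop"`.
#' @return list `train`, `apply` (NULL if not given), `center`, `scale`.
#' @export
standardize_features <- function(train, apply = NULL,
                                 impute = c("mean", "drop")) {
  impute <- match.arg(impute)
  stopifnot(is.matrix(train), nrow(train) > 0)
  if (impute == "drop") {
    keep <- stats::complete.cases(train)
    train <- train[keep, , drop = FALSE]
    if (nrow(train) == 0) stop("no complete training rows after drop")
  }
  center <- colMeans(train, na.rm = TRUE)
  center[is.nan(center)] <- 0                     # all-NA dimension
  # population (divide-by-n) sd, so a two-point dimension {0, 2} maps to
  # exactly {-1, +1}
  scl <- vapply(seq_len(ncol(train)), function(j) {
    v <- train[, j][!is.na(train[, j])]
    if (length(v) == 0) 0 else sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  names(scl) <- colnames(train)
  if (any(scl == 0))
    message(sum(scl == 0), " zero-variance dimension(s) scaled to 0")
  transform <- function(m) {
    m <- sweep(m, 2, center, check.margin = FALSE)
    for (j in seq_len(ncol(m))) {
      m[is.na(m[, j]), j] <- 0                    # mean imputation post-center
      m[, j] <- if (scl[j] > 0) m[, j] / scl[j] else 0
    }
    m
  }
  list(train = transform(train),
       apply = if (is.null(apply)) NULL else transform(apply),
       center = center, scale = scl)
}

#' Read and write feature tables
#'
#' TSV with `gene_id` followed by the 28 feature columns in
#' [FEATURE_NAMES] order; empty cells are missing.
#'
#' @param features genes x 28 matrix with gene ids as rownames.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(gene_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @return `read_features`: genes x 28 numeric matrix.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!identical(colnames(m), FEATURE_NAMES))
    stop("feature table columns do not match the 28-dimension layout")
  rownames(m) <- df$gene_id
  m
}
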