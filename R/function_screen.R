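#' Annotation catalogs
#'
#' A catalog holds one namespace of gene-set annotations (PIRSF protein
#' families, GO terms or KEGG pathways) as mutually inverse maps
#' gene -> categories and category -> genes over a background universe.
#'
#' @param cat2gene named list: category id -> character vector of gene ids.
#' @param namespace one of `"PIRSF"`, `"GO"`, `"KEGG"`.
#' @param universe background gene universe; defaults to all annotated genes.
#' @return an `annotation_catalog` list with `namespace`, `gene2cat`,
#'   `cat2gene`, `universe`.
#' @export
annotation_catalog <- function(cat2gene, namespace = c("PIRSF", "GO", "KEGG"),
                               universe = NULL) {
  namespace <- match.arg(namespace)
  cat2gene <- lapply(cat2gene, function(g) sort(unique(as.character(g))))
  annotated <- sort(unique(unlist(cat2gene, use.names = FALSE)))
  if (is.null(universe)) universe <- annotated
  if (!all(annotated %in% universe))
    stop("annotated genes outside the stated universe")
  pairs <- data.frame(
    cat = rep(names(cat2gene), lengths(cat2gene)),
    gene = unlist(cat2gene, use.names = FALSE), stringsAsFactors = FALSE)
  gene2cat <- split(pairs$cat, pairs$gene)
  structure(list(namespace = namespace, gene2cat = gene2cat,
                 cat2gene = cat2gene, universe = sort(unique(universe))),
            class = "annotation_catalog")
}

#' Read a GMT annotation file into a catalog
#'
#' GMT: one gene set per line, `category<TAB>description<TAB>gene1<TAB>...`.
#' Parsed with [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @inheritParams annotation_catalog
#' @export
read_gmt <- function(path, namespace = c("PIRSF", "GO", "KEGG"),
                     universe = NULL) {
  annotation_catalog(fgsea::gmtPathways(path), namespace, universe)
}

#' Write a catalog to GMT
#'
#' @param catalog an `annotation_catalog`.
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$cat2gene), function(cat) {
    paste(c(cat, catalog$namespace, catalog$cat2gene[[cat]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Categories enriched among disease genes
#'
#' For each category of size `n` in a universe of `N` genes containing `K`
#' disease genes, the probability of seeing `k` or more disease genes in the
#' category by chance is the one-sided hypergeometric tail
#' `P(X >= k), X ~ Hypergeom(N, K, n)`. Categories with `p <= alpha` and
#' `k >= min_overlap` are called enriched.
#'
#' @param disease_genes character vector within the catalog universe.
#' @param catalog an `annotation_catalog`.
#' @param alpha significance level for the tail probability.
#' @param min_overlap minimum disease genes in the category.
#' @param p_adjust `"none"` (default; the screen is deliberately inclusive)
#'   or any method of [stats::p.adjust()] such as `"BH"`.
#' @return data frame `category`, `k`, `K`, `n`, `N`, `p` (and `p_adj` when
#'   adjusted), restricted to enriched categories, sorted by `p`.
#' @export
enriched_categories <- function(disease_genes, catalog, alpha = 0.05,
                                min_overlap = 2, p_adjust = "none") {
  stopifnot(inherits(catalog, "annotation_catalog"))
  N <- length(catalog$universe)
  if (N == 0) stop("empty annotation universe")
  disease_genes <- unique(disease_genes)
  if (!all(disease_genes %in% catalog$universe))
    stop("disease genes outside the catalog universe")
  K <- length(disease_genes)
  cats <- names(catalog$cat2gene)
  n <- lengths(catalog$cat2gene)
  k <- vapply(catalog$cat2gene,
              function(g) sum(g %in% disease_genes), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  df <- data.frame(category = cats, k = k, K = K, n = as.integer(n), N = N,
                   p = p, stringsAsFactors = FALSE)
  crit <- df$p
  if (p_adjust != "none") {
    df$p_adj <- stats::p.adjust(df$p, method = p_adjust)
    crit <- df$p_adj
  }
  df <- df[crit <= alpha & df$k >= min_overlap, , drop = FALSE]
  df <- df[order(df$p, df$category), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-gene functional-similarity indicator
#'
#' For each gene, `f_ns = 1` iff the gene is annotated to at least one
#' enriched category in namespace ns, and the combined indicator is
#' `f = f_PIRSF | f_GO | f_KEGG`; `f = 1` defines a final candidate. Genes
#' absent from every catalog get all-zero indicators (no similarity can be
#' demonstrated).
#'
#' @param genes character vector of gene ids.
#' @param catalogs named list of `annotation_catalog`s
#'   (`pirsf`, `go`, `kegg`).
#' @param enriched named list of [enriched_categories()] outputs (or plain
#'   category-id vectors), same names.
#' @return data frame `gene_id`, `f_pirsf`, `f_go`, `f_kegg`, `f` (0/1).
#' @export
indicator_f <- function(genes, catalogs, enriched) {
  stopifnot(all(c("pirsf", "go", "kegg") %in% names(catalogs)),
            all(c("pirsf", "go", "kegg") %in% names(enriched)))
  one_ns <- function(ns) {
    cats <- enriched[[ns]]
    if (is.data.frame(cats)) cats <- cats$category
    g2c <- catalogs[[ns]]$gene2cat
    vapply(genes, function(g) {
      ann <- g2c[[g]]
      as.integer(!is.null(ann) && any(ann %in% cats))
    }, integer(1), USE.NAMES = FALSE)
  }
  f_pirsf <- one_ns("pirsf"); f_go <- one_ns("go"); f_kegg <- one_ns("kegg")
  data.frame(gene_id = genes, f_pirsf = f_pirsf, f_go = f_go, f_kegg = f_kegg,
             f = as.integer(f_pirsf | f_go | f_kegg), stringsAsFactors = FALSE)
}

#' Third-dimensional (functional annotation) screen
#'
#' Computes the enriched-category sets of the three namespaces from the
#' known disease genes, evaluates the indicator `f` on every candidate, and
#' retains candidates with `f = 1` — genes sharing at least one
#' disease-enriched protein family, GO term or KEGG pathway.
#'
#' @param candidates gene ids from the structural (SVM) screen.
#' @param disease_genes known disease genes.
#' @param catalogs named list of catalogs (`pirsf`, `go`, `kegg`).
#' @inheritParams enriched_categories
#' @return list `final` (retained gene ids, sorted), `indicators` (the full
#'   indicator table), `enriched` (per-namespace enriched-category tables).
#' @export
functional_screen <- function(candidates, disease_genes, catalogs,
                              alpha = 0.05, min_overlap = 2,
                              p_adjust = "none") {
  enriched <- lapply(catalogs, function(cat) {
    enriched_categories(intersect(disease_genes, cat$universe), cat,
                        alpha, min_overlap, p_adjust)
  })
  ind <- indicator_f(candidates, catalogs, enriched)
  list(final = sort(ind$gene_id[ind$f == 1]), indicators = ind,
       enriched = enriched)
}
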