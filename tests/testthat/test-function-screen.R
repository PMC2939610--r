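universe20 <- sprintf("g%02d", 1:20)

test_that("catalog maps are mutual inverses over a stated universe", {
  cat <- toy_catalog(list(C1 = c("g01", "g02"), C2 = c("g02", "g03")),
                     universe = universe20)
  expect_setequal(cat$gene2cat[["g02"]], c("C1", "C2"))
  expect_setequal(cat$cat2gene[["C2"]], c("g02", "g03"))
  pairs_fwd <- sort(paste(rep(names(cat$cat2gene), lengths(cat$cat2gene)),
                          unlist(cat$cat2gene)))
  pairs_rev <- sort(paste(unlist(cat$gene2cat),
                          rep(names(cat$gene2cat), lengths(cat$gene2cat))))
  expect_identical(pairs_fwd, pairs_rev)
  expect_error(annotation_catalog(list(C1 = "zz"), "GO", universe = "g01"),
               "universe")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # worked case: universe 20, 5 disease genes, category of 4 holding 3
  disease <- universe20[1:5]
  cat <- toy_catalog(list(HIT = c("g01", "g02", "g03", "g06"),
                          COLD = c("g10", "g11"),
                          ALL = universe20),
                     universe = universe20)
  enr <- enriched_categories(disease, cat, alpha = 0.05, min_overlap = 2)
  expect_identical(enr$category, "HIT")
  expect_equal(enr$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(enr$p, oracle_hyper_tail(3, 5, 4, 20), tolerance = 1e-12)
  # a category with no disease genes has tail probability 1
  all_p <- enriched_categories(disease, cat, alpha = 1, min_overlap = 0)
  expect_equal(all_p$p[all_p$category == "COLD"], 1)
  # the whole universe can never be over-represented
  expect_equal(all_p$p[all_p$category == "ALL"], 1)
  # degenerate alpha
  expect_equal(nrow(enriched_categories(disease, cat, alpha = 0)), 0)
})

test_that("enrichment p-values agree with enumeration on random catalogs", {
  withr::with_seed(12, {
    for (i in 1:20) {
      N <- sample(10:30, 1)
      uni <- sprintf("u%02d", 1:N)
      K <- sample(2:(N - 2), 1)
      n <- sample(1:N, 1)
      disease <- sample(uni, K)
      cat <- toy_catalog(list(C = sample(uni, n)), universe = uni)
      got <- enriched_categories(disease, cat, alpha = 1, min_overlap = 0)
      k <- sum(cat$cat2gene$C %in% disease)
      expect_equal(got$p, oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("lowering alpha never grows the enriched or candidate sets", {
  sim <- simulate_annotations(universe20, universe20[1:6],
                              n_categories = 12, clustering_strength = 0.8,
                              n_background = 2, seed = 4)
  cat <- sim$catalogs$kegg
  prev <- Inf
  for (a in c(0.5, 0.1, 0.02, 0.001)) {
    cur <- nrow(enriched_categories(universe20[1:6], cat, alpha = a,
                                    min_overlap = 1))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the indicator truth table is reproduced", {
  cats <- list(
    pirsf = toy_catalog(list(PF_E = "g04", PF_X = c("g01", "g02", "g03")),
                        "PIRSF", universe20),
    go = toy_catalog(list(GO_E = c("g03", "g04"), GO_X = c("g01", "g02")),
                     "GO", universe20),
    kegg = toy_catalog(list(KE_E = c("g02", "g03", "g04"), KE_X = "g01"),
                       "KEGG", universe20))
  enriched <- list(pirsf = "PF_E", go = "GO_E", kegg = "KE_E")
  ind <- indicator_f(c("g01", "g02", "g03", "g04"), cats, enriched)
  expect_equal(ind$f_pirsf, c(0, 0, 0, 1))
  expect_equal(ind$f_go, c(0, 0, 1, 1))
  expect_equal(ind$f_kegg, c(0, 1, 1, 1))
  expect_equal(ind$f, c(0, 1, 1, 1))
  expect_equal(ind$f, as.integer(ind$f_pirsf | ind$f_go | ind$f_kegg))
  # a gene missing from every catalog gets all zeros
  lost <- indicator_f("g19", cats, enriched)
  expect_equal(unlist(lost[1, -1]), c(f_pirsf = 0, f_go = 0, f_kegg = 0, f = 0))
})

test_that("functional screen retains genes sharing enriched categories", {
  uni <- sprintf("g%03d", 1:60)
  disease <- uni[1:10]
  # disease genes pile into two KEGG pathways; candidate g051 shares one,
  # candidate g052 is annotated only elsewhere
  kegg <- toy_catalog(list(K1 = c(disease[1:6], "g051"),
                           K2 = disease[5:10],
                           K3 = c("g052", "g053", "g054")),
                      "KEGG", uni)
  flat <- toy_catalog(list(P1 = c("g055", "g056")), "PIRSF", uni)
  flat_go <- toy_catalog(list(O1 = c("g057", "g058")), "GO", uni)
  cats <- list(pirsf = flat, go = flat_go, kegg = kegg)
  out <- functional_screen(c("g051", "g052"), disease, cats,
                           alpha = 0.05, min_overlap = 2)
  expect_identical(out$final, "g051")
  expect_true(all(out$final %in% c("g051", "g052")))
  expect_equal(out$indicators$f,
               as.integer(out$indicators$f_pirsf | out$indicators$f_go |
                            out$indicators$f_kegg))
})

test_that("GMT files round-trip through the catalog reader", {
  cat <- toy_catalog(list(C1 = c("g01", "g02", "g03"), C2 = c("g04", "g05")),
                     "KEGG")
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cat, f)
  back <- read_gmt(f, "KEGG")
  expect_identical(back$cat2gene, cat$cat2gene)
  expect_identical(back$universe, cat$universe)
})
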