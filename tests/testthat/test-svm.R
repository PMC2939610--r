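test_that("training-set sampling is balanced, disjoint and seeded", {
  pos <- sprintf("p%d", 1:5)
  neg <- sprintf("n%d", 1:100)
  ts <- sample_training_set(pos, neg, seed = 1)
  expect_identical(ts$positives, pos)
  expect_length(ts$negatives, 5)
  expect_false(anyDuplicated(ts$negatives) > 0)
  expect_true(all(ts$negatives %in% neg))
  expect_identical(sample_training_set(pos, neg, seed = 1)$negatives,
                   ts$negatives)
  expect_false(identical(sample_training_set(pos, neg, seed = 2)$negatives,
                         ts$negatives))
  expect_error(sample_training_set(pos, sprintf("n%d", 1:3), 1), "smaller")
  expect_error(sample_training_set(pos, c("p1", neg), 1), "overlap")
})

test_that("negatives are drawn uniformly across randomizations", {
  pos <- sprintf("p%d", 1:5)
  neg <- sprintf("n%d", 1:1000)
  draws <- unlist(lapply(1:1000, function(i)
    sample_training_set(pos, neg, seed = i)$negatives))
  freq <- table(factor(draws, levels = neg)) / 1000
  p <- 5 / 1000
  band <- 3 * sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(freq - p) <= band + 1e-12) ||
                mean(abs(freq - p) <= band) > 0.99)
})

test_that("Qp, Qn, Qa follow the pooled confusion-count formulas", {
  perf <- classifier_performance(tp = 8, fn = 2, tn = 7, fp = 3)
  expect_equal(perf$qp, 0.8)
  expect_equal(perf$qn, 0.7)
  expect_equal(perf$qa, 0.75)
  # qa is the count-weighted blend of sensitivity and specificity
  expect_equal(perf$qa,
               (perf$qp * (perf$tp + perf$fn) + perf$qn * (perf$tn + perf$fp)) /
                 (perf$tp + perf$fn + perf$tn + perf$fp))
  degenerate <- classifier_performance(0, 0, 5, 5)
  expect_true(is.na(degenerate$qp))
})

test_that("cross-validation is near-perfect on well-separated classes", {
  f <- simulate_protein_features(50, 50, separation = 10, seed = 31)
  perf <- cross_validate(f$features, f$labels, n_folds = 5, seed = 31)
  expect_gte(perf$qa, 0.98)
  expect_equal(perf$tp + perf$fn + perf$tn + perf$fp, 100)
})

test_that("cross-validation sits at chance when classes are identical", {
  qa <- vapply(1:5, function(s) {
    f <- simulate_protein_features(60, 60, separation = 0, seed = 100 + s)
    cross_validate(f$features, f$labels, n_folds = 5, seed = s)$qa
  }, numeric(1))
  expect_gt(mean(qa), 0.35)
  expect_lt(mean(qa), 0.65)
})

test_that("feature-subset evaluation summarizes Qa per subset", {
  f <- simulate_protein_features(30, 80, separation = 6, signal_dims = 1:20,
                                 seed = 17)
  pos <- rownames(f$features)[f$labels == "pos"]
  neg <- rownames(f$features)[f$labels == "neg"]
  one <- evaluate_feature_sets(f$features, pos, neg, n_randomizations = 1,
                               n_folds = 4, seed = 5)
  expect_equal(one$min, one$mean)
  expect_equal(one$max, one$mean)
  expect_equal(one$sd, c(0, 0))
  multi <- evaluate_feature_sets(f$features, pos, neg, n_randomizations = 12,
                                 n_folds = 4, seed = 5)
  # signal lives in dims 1-20, so the full 28-dim classifier must beat the
  # 8-dim secondary block
  expect_gt(multi$mean[multi$subset == "full"],
            multi$mean[multi$subset == "secondary"])
  expect_true(all(multi$min <= multi$mean & multi$mean <= multi$max))
})

test_that("ensemble intersection keeps planted positives, drops negatives", {
  f <- simulate_protein_features(30, 120, n_test_pos = 8, n_test_neg = 8,
                                 separation = 8, seed = 23)
  ids <- rownames(f$features)
  pos <- ids[f$labels == "pos" & f$role == "train"]
  neg <- ids[f$labels == "neg" & f$role == "train"]
  test <- ids[f$role == "test"]
  truth_pos <- ids[f$role == "test" & f$labels == "pos"]
  ens <- ensemble_predict(f$features, pos, neg, test,
                          n_randomizations = 50, seed = 7)
  v <- ens$votes
  expect_gte(mean(v$vote_fraction[v$gene_id %in% truth_pos]), 0.95)
  expect_lte(mean(v$vote_fraction[!v$gene_id %in% truth_pos]), 0.05)
  expect_true(all(ens$candidates %in% truth_pos))
  # strict intersection <=> vote fraction exactly 1
  expect_setequal(ens$candidates, v$gene_id[v$in_intersection])
  # relaxing keep_fraction can only grow the candidate set
  relaxed <- ensemble_predict(f$features, pos, neg, test,
                              n_randomizations = 50, keep_fraction = 0.9,
                              seed = 7)
  expect_true(all(ens$candidates %in% relaxed$candidates))
  # bit-reproducible under the same master seed
  again <- ensemble_predict(f$features, pos, neg, test,
                            n_randomizations = 50, seed = 7)
  expect_identical(again$votes, ens$votes)
})

test_that("ensemble rejects overlapping test sets and handles empty ones", {
  f <- simulate_protein_features(5, 20, separation = 2, seed = 3)
  ids <- rownames(f$features)
  pos <- ids[f$labels == "pos"]
  neg <- ids[f$labels == "neg"]
  expect_error(ensemble_predict(f$features, pos, neg, pos[1],
                                n_randomizations = 2), "overlaps")
  empty <- ensemble_predict(f$features, pos, neg, character(0),
                            n_randomizations = 2)
  expect_identical(empty$candidates, character(0))
  expect_equal(nrow(empty$votes), 0)
})
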