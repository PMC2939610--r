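#' Sample a balanced training set from randomized negatives
#'
#' The non-disease-gene space is too diverse to sample once, so classifiers
#' are trained on many randomized sets: every positive gene plus an
#' equal-size uniform without-replacement draw from the negative pool
#' (positive:negative = 1:1).
#'
#' @param positive_pool character vector of known disease-gene ids.
#' @param negative_pool character vector of negative-candidate gene ids,
#'   disjoint from `positive_pool`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return list `positives`, `negatives`, `seed`.
#' @export
sample_training_set <- function(positive_pool, negative_pool, seed) {
  if (length(negative_pool) < length(positive_pool))
    stop("negative pool smaller than positive pool")
  if (length(intersect(positive_pool, negative_pool)) > 0)
    stop("positive and negative pools overlap")
  negs <- withr::with_seed(seed,
    sample(negative_pool, length(positive_pool), replace = FALSE))
  list(positives = positive_pool, negatives = negs, seed = seed)
}

#' Pooled classifier performance
#'
#' Sensitivity `Qp = TP/(TP+FN)`, specificity `Qn = TN/(TN+FP)` and overall
#' accuracy `Qa = (TP+TN)/(TP+TN+FP+FN)` from pooled confusion counts.
#' A zero denominator yields NA for that ratio.
#'
#' @param tp,fn,tn,fp non-negative integer counts.
#' @return list `tp`, `fn`, `tn`, `fp`, `qp`, `qn`, `qa`.
#' @export
classifier_performance <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       qp = rat(tp, tp + fn), qn = rat(tn, tn + fp),
       qa = rat(tp + tn, tp + tn + fp + fn))
}

# Fit the RBF-kernel SVM used throughout (libsvm via e1071). Feature
# standardization is done by the caller, so scale = FALSE here.
fit_svm <- function(x, y, cost = 1, gamma = NULL) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  e1071::svm(x, factor(y, levels = c("pos", "neg")), kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Predict labels and signed margins (positive margin = positive side).
predict_svm <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  if (grepl("^neg", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  list(label = as.character(pr), margin = dv)
}

#' n-fold cross-validation of the RBF-kernel classifier
#'
#' Shuffles the pooled positive and negative samples (seeded), splits them
#' into `n_folds` folds, trains on `n_folds - 1` and tests on the held-out
#' fold, pooling TP/TN/FP/FN over folds before computing Qp/Qn/Qa. Features
#' are standardized per split with train-only statistics. If a training
#' split lacks one class, the data are reshuffled once; a second failure is
#' an error.
#'
#' @param x numeric feature matrix (rows = proteins).
#' @param y class labels, `"pos"` / `"neg"`.
#' @param n_folds number of folds (>= 2).
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; default `1/ncol(x)`.
#' @param seed integer seed for the shuffle.
#' @return a [classifier_performance()] list.
#' @export
cross_validate <- function(x, y, n_folds = 5, cost = 1, gamma = NULL,
                           seed = 1) {
  stopifnot(n_folds >= 2, nrow(x) == length(y), nrow(x) >= n_folds)
  y <- as.character(y)
  stopifnot(all(y %in% c("pos", "neg")))
  run <- function(ord) {
    fold <- rep(seq_len(n_folds), length.out = length(ord))
    tp <- tn <- fp <- fn <- 0L
    for (k in seq_len(n_folds)) {
      tr <- ord[fold != k]; te <- ord[fold == k]
      if (length(unique(y[tr])) < 2) return(NULL)
      sc <- standardize_features(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      model <- fit_svm(sc$train, y[tr], cost, gamma)
      pred <- predict_svm(model, sc$apply)$label
      tp <- tp + sum(pred == "pos" & y[te] == "pos")
      fn <- fn + sum(pred == "neg" & y[te] == "pos")
      tn <- tn + sum(pred == "neg" & y[te] == "neg")
      fp <- fp + sum(pred == "pos" & y[te] == "neg")
    }
    classifier_performance(tp, fn, tn, fp)
  }
  perf <- run(withr::with_seed(seed, sample(length(y))))
  if (is.null(perf))
    perf <- run(withr::with_seed(seed + 1L, sample(length(y))))
  if (is.null(perf))
    stop("a cross-validation training split contained a single class twice")
  perf
}

#' Compare feature subsets over randomized training sets
#'
#' Repeats [sample_training_set()] + [cross_validate()] `n_randomizations`
#' times for each feature subset (by default the 8-dimension secondary block
#' and the full 28 dimensions) and summarizes the overall accuracy Qa as
#' min, max, mean and sd per subset.
#'
#' @param features genes x 28 matrix, rownames = gene ids.
#' @param positive_pool,negative_pool gene-id vectors (rows of `features`).
#' @param subsets named list of column index vectors.
#' @param n_randomizations number of randomized training sets.
#' @param n_folds folds per cross-validation.
#' @param cost,gamma SVM hyperparameters (see [cross_validate()]).
#' @param seed master seed; randomization i uses `seed + i`.
#' @return data frame `subset`, `n_dims`, `min`, `max`, `mean`, `sd` of Qa.
#' @export
evaluate_feature_sets <- function(features, positive_pool, negative_pool,
                                  subsets = list(secondary = SECONDARY_DIMS,
                                                 full = 1:28),
                                  n_randomizations = 1000, n_folds = 5,
                                  cost = 1, gamma = NULL, seed = 1) {
  res <- lapply(names(subsets), function(nm) {
    cols <- subsets[[nm]]
    qa <- vapply(seq_len(n_randomizations), function(i) {
      ts <- sample_training_set(positive_pool, negative_pool, seed + i)
      ids <- c(ts$positives, ts$negatives)
      yy <- rep(c("pos", "neg"), c(length(ts$positives), length(ts$negatives)))
      cross_validate(features[ids, cols, drop = FALSE], yy, n_folds,
                     cost, gamma, seed = seed + i)$qa
    }, numeric(1))
    data.frame(subset = nm, n_dims = length(cols), min = min(qa),
               max = max(qa), mean = mean(qa), sd = stats::sd(qa),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$sd[is.na(out$sd)] <- 0      # single randomization
  out
}

#' Ensemble prediction by intersection over randomized trainings
#'
#' Trains one classifier per randomized 1:1 training set and labels every
#' test gene with each; a gene is a candidate only if classified positive in
#' at least `keep_fraction` of the randomizations (the default 1.0 is the
#' strict intersection over all of them). The mean signed distance to the
#' separating hyperplane is returned as a disease-likeness score.
#'
#' @param features genes x p matrix, rownames = gene ids.
#' @param positive_pool,negative_pool training gene ids.
#' @param test_set gene ids to classify; must be disjoint from both pools.
#' @param n_randomizations number of randomized training sets.
#' @param keep_fraction minimum positive-vote fraction to keep a gene.
#' @param cost,gamma SVM hyperparameters.
#' @param seed master seed; randomization i uses `seed + i`.
#' @return list `candidates` (sorted gene ids), `votes` (data frame
#'   `gene_id`, `vote_fraction`, `mean_margin`, `in_intersection`), and
#'   `n_randomizations`.
#' @export
ensemble_predict <- function(features, positive_pool, negative_pool, test_set,
                             n_randomizations = 10000, keep_fraction = 1.0,
                             cost = 1, gamma = NULL, seed = 1) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  if (length(intersect(test_set, c(positive_pool, negative_pool))) > 0)
    stop("test set overlaps a training pool")
  if (length(test_set) == 0)
    return(list(candidates = character(0),
                votes = data.frame(gene_id = character(0),
                                   vote_fraction = numeric(0),
                                   mean_margin = numeric(0),
                                   in_intersection = logical(0)),
                n_randomizations = n_randomizations))
  # one scaler for the whole ensemble, estimated on the training pools only
  # (re-estimating it per randomized subset adds nothing but vote noise)
  pool <- c(positive_pool, negative_pool)
  sc <- standardize_features(features[pool, , drop = FALSE],
                             features[test_set, , drop = FALSE])
  xpool <- sc$train
  rownames(xpool) <- pool
  xtest <- sc$apply
  votes <- numeric(length(test_set))
  margins <- numeric(length(test_set))
  for (i in seq_len(n_randomizations)) {
    ts <- sample_training_set(positive_pool, negative_pool, seed + i)
    ids <- c(ts$positives, ts$negatives)
    yy <- rep(c("pos", "neg"), c(length(ts$positives), length(ts$negatives)))
    model <- fit_svm(xpool[ids, , drop = FALSE], yy, cost, gamma)
    pred <- predict_svm(model, xtest)
    votes <- votes + (pred$label == "pos")
    margins <- margins + pred$margin
  }
  vf <- votes / n_randomizations
  keep <- vf >= keep_fraction
  df <- data.frame(gene_id = test_set, vote_fraction = vf,
                   mean_margin = margins / n_randomizations,
                   in_intersection = vf >= 1, stringsAsFactors = FALSE)
  df <- df[order(-df$vote_fraction, -df$mean_margin, df$gene_id), ]
  rownames(df) <- NULL
  list(candidates = sort(test_set[keep]), votes = df,
       n_randomizations = n_randomizations)
}
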