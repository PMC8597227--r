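#' Sample negative miRNA-disease pairs
#'
#' Draws `ratio` presumed-negative cells (zeros of `A`) per observed positive,
#' uniformly without replacement, under the given seed.
#'
#' @param A binary association matrix.
#' @param ratio negatives per positive (default 5).
#' @param seed integer seed.
#' @return data.frame with integer columns `mirna`, `disease` and `label = 0`.
#' @export
sample_negatives <- function(A, ratio = 5, seed = 1) {
  stopifnot(is.matrix(A), all(A %in% c(0, 1)), ratio >= 1)
  zeros <- which(A == 0, arr.ind = TRUE)
  n_pos <- sum(A)
  want <- as.integer(round(ratio * n_pos))
  if (nrow(zeros) < want) {
    stop("not enough zero cells (", nrow(zeros), ") for ", want,
         " negatives", call. = FALSE)
  }
  set.seed(derive_seed(seed, "negative-sampling"))
  pick <- zeros[sample.int(nrow(zeros), want), , drop = FALSE]
  data.frame(mirna = as.integer(pick[, 1]), disease = as.integer(pick[, 2]),
             label = 0L)
}

#' Build the labeled experimental pair set
#'
#' All positives of `A` plus [sample_negatives()] at the given ratio: the
#' experimental data that cross-validation folds.
#'
#' @inheritParams sample_negatives
#' @return data.frame with columns `mirna`, `disease`, `label`.
#' @export
make_labeled_pairs <- function(A, ratio = 5, seed = 1) {
  pos <- which(A == 1, arr.ind = TRUE)
  rbind(
    data.frame(mirna = as.integer(pos[, 1]),
               disease = as.integer(pos[, 2]), label = 1L),
    sample_negatives(A, ratio, seed)
  )
}

#' Stratified k-fold split of labeled pairs
#'
#' Shuffles within each label class and deals the concatenated sequence
#' round-robin, so folds are disjoint, cover all pairs, differ in size by at
#' most one, and keep the class ratio near-constant.
#'
#' @param pairs labeled pair data.frame.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` folds, each a list with data.frames `train`, `test`
#'   and integer index vectors `train_idx`, `test_idx` into `pairs`.
#' @export
kfold_split <- function(pairs, k = 5, seed = 1) {
  n <- nrow(pairs)
  stopifnot(k >= 2, n >= k)
  set.seed(derive_seed(seed, "kfold"))
  order_by_class <- unlist(
    lapply(split(seq_len(n), pairs$label), sample),
    use.names = FALSE
  )
  fold_of <- integer(n)
  fold_of[order_by_class] <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    list(train = pairs[train_idx, , drop = FALSE],
         test = pairs[test_idx, , drop = FALSE],
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, ties counting one half (Mann-Whitney form via midranks).
#'
#' @param labels binary labels with at least one of each class.
#' @param scores numeric scores.
#' @return AUC in `[0,1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step interpolation: sum over the descending-score sweep of precision
#' times the recall increment (average-precision form).
#'
#' @inheritParams auc
#' @return AUPR in `[0,1]`.
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) {
    stop("AUPR needs both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / P
  sum(precision * diff(c(0, recall)))
}

#' F1 score at a threshold
#'
#' Pairs scoring at or above the threshold are called positive.
#'
#' @inheritParams auc
#' @param threshold score cut (default 0.5).
#' @return F1 in `[0,1]` (0 when no positive calls or positives exist).
#' @export
f1_score <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Train one fold: masked adjacency + (optionally) EOE features + predictor.
fit_fold <- function(sims, A, fold, eoe_cfg, pred_cfg, fold_seed) {
  test_pos <- fold$test[fold$test$label == 1, c("mirna", "disease")]
  adj <- bipartite_adjacency(A, mask = test_pos)
  # instrumented leakage guards
  if (nrow(test_pos) > 0 &&
      any(adj[cbind(test_pos$mirna, nrow(A) + test_pos$disease)] != 0)) {
    stop("internal error: held-out positive leaked into adjacency",
         call. = FALSE)
  }
  if (nrow(merge(fold$train, fold$test,
                 by = c("mirna", "disease"))) > 0) {
    stop("internal error: train/test pair overlap", call. = FALSE)
  }
  A_train <- A
  A_train[cbind(test_pos$mirna, test_pos$disease)] <- 0
  eoe_cfg$seed <- fold_seed
  pred_cfg$seed <- fold_seed
  if (pred_cfg$use_eoe) {
    graph <- assemble_graph(sims$MS, sims$DS, A_train)
    est <- train_eoe(graph, eoe_cfg,
                     exclude_md = fold$test[, c("mirna", "disease")])
    features <- list(mirna = est$mirna_vecs, disease = est$disease_vecs)
  } else {
    features <- list(mirna = unname(sims$MS), disease = unname(sims$DS))
  }
  model <- train_predictor(features, adj, fold$train, pred_cfg)
  scores <- predict_pairs(model, fold$test)
  list(model = model, scores = scores)
}

#' Run k-fold cross-validation of the full pipeline
#'
#' Protocol: sample negatives once globally at the configured ratio, fold
#' positives and negatives stratified, then per fold rebuild the masked
#' bipartite adjacency, retrain the EOE embedding (held-out cells excluded
#' from its loss) and the predictor on the training pairs only, score the
#' test pairs, and compute AUC / AUPR / F1.
#'
#' @param A binary association matrix with dimnames.
#' @param ontology optional [disease_ontology()] for the semantic models.
#' @param similarities optional precomputed [compute_similarities()] output
#'   (skips the similarity stage).
#' @param folds number of CV folds (default 5).
#' @param ratio negatives per positive (default 5).
#' @param seed master seed for the whole run.
#' @param params a [kernel_params()].
#' @param eoe an [eoe_config()].
#' @param predictor a [predictor_config()] (`use_eoe = FALSE` gives the
#'   SGC-only ablation).
#' @param shuffle_labels permute the labels of the experimental pairs before
#'   folding -- the null control, whose AUC should hover around 0.5.
#' @return object of class `cv_report`: per-fold metrics, their means, the
#'   per-fold test scores, and a config snapshot.
#' @export
run_cv <- function(A, ontology = NULL, similarities = NULL, folds = 5,
                   ratio = 5, seed = 1, params = kernel_params(),
                   eoe = eoe_config(), predictor = predictor_config(),
                   shuffle_labels = FALSE) {
  stopifnot(is.matrix(A))
  sims <- if (is.null(similarities)) {
    compute_similarities(A, ontology, params)
  } else {
    similarities
  }
  pairs <- make_labeled_pairs(A, ratio = ratio, seed = seed)
  if (shuffle_labels) {
    set.seed(derive_seed(seed, "label-shuffle"))
    pairs$label <- sample(pairs$label)
  }
  split <- kfold_split(pairs, k = folds, seed = seed)
  fold_rows <- vector("list", folds)
  score_tables <- vector("list", folds)
  for (f in seq_len(folds)) {
    fit <- fit_fold(sims, A, split[[f]], eoe, predictor,
                    fold_seed = derive_seed(seed, paste0("fold-", f)))
    test <- split[[f]]$test
    fold_rows[[f]] <- data.frame(
      fold = f,
      auc = auc(test$label, fit$scores),
      aupr = auprc(test$label, fit$scores),
      f1 = f1_score(test$label, fit$scores, predictor$threshold)
    )
    score_tables[[f]] <- data.frame(
      fold = f,
      mirna = rownames(A)[test$mirna],
      disease = colnames(A)[test$disease],
      score = fit$scores, label = test$label
    )
  }
  metrics <- do.call(rbind, fold_rows)
  structure(
    list(
      metrics = metrics,
      means = colMeans(metrics[, c("auc", "aupr", "f1")]),
      scores = do.call(rbind, score_tables),
      config = list(folds = folds, ratio = ratio, seed = seed,
                    params = unclass(params), eoe = unclass(eoe),
                    predictor = unclass(predictor),
                    shuffle_labels = shuffle_labels),
      seed = seed
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$config$folds, "-fold, seed ", x$seed, ")\n", sep = "")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("means: AUC %.4f  AUPR %.4f  F1 %.4f\n",
              x$means["auc"], x$means["aupr"], x$means["f1"]))
  invisible(x)
}

#' Train the pipeline on all data (no held-out fold)
#'
#' Convenience wrapper used for final candidate ranking: computes
#' similarities, trains EOE (if configured) and the predictor on all labeled
#' pairs, with the full adjacency.
#'
#' @inheritParams run_cv
#' @return a `predictor_state`.
#' @export
train_full_model <- function(A, ontology = NULL, similarities = NULL,
                             ratio = 5, seed = 1, params = kernel_params(),
                             eoe = eoe_config(),
                             predictor = predictor_config()) {
  sims <- if (is.null(similarities)) {
    compute_similarities(A, ontology, params)
  } else {
    similarities
  }
  pairs <- make_labeled_pairs(A, ratio = ratio, seed = seed)
  eoe$seed <- derive_seed(seed, "full-eoe")
  predictor$seed <- derive_seed(seed, "full-predictor")
  features <- if (predictor$use_eoe) {
    graph <- assemble_graph(sims$MS, sims$DS, A)
    est <- train_eoe(graph, eoe)
    list(mirna = est$mirna_vecs, disease = est$disease_vecs)
  } else {
    list(mirna = unname(sims$MS), disease = unname(sims$DS))
  }
  train_predictor(features, bipartite_adjacency(A), pairs, predictor)
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA without a known association to the disease and returns
#' the top `k`, sorted by score (descending) with a stable tie-break on the
#' miRNA label, so known associations are never proposed.
#'
#' @param model a trained `predictor_state`.
#' @param disease disease name.
#' @param A the binary association matrix the model was trained on.
#' @param k number of candidates (default 20; truncated to availability).
#' @return data.frame with columns `rank`, `mirna`, `score`.
#' @export
rank_candidates <- function(model, disease, A, k = 20) {
  stopifnot(inherits(model, "predictor_state"))
  j <- match(disease, model$disease_labels)
  if (is.na(j)) stop("unknown disease: ", disease, call. = FALSE)
  cand <- which(A[, j] == 0)
  if (length(cand) == 0) {
    return(data.frame(rank = integer(0), mirna = character(0),
                      score = numeric(0)))
  }
  scores <- predict_pairs(model, data.frame(mirna = cand, disease = j))
  labs <- model$mirna_labels[cand]
  ord <- order(-scores, labs)
  top <- head(ord, k)
  data.frame(rank = seq_along(top), mirna = labs[top], score = scores[top])
}

#' Cross-validated metrics versus embedding dimension
#'
#' Reruns [run_cv()] for each requested shared-space dimension `z` and
#' collects the mean metrics in a tidy table (the dimension-sensitivity
#' sweep).
#'
#' @param dims integer vector of dimensions.
#' @param ... arguments passed to [run_cv()] (the predictor's `z` is
#'   overridden per row).
#' @param predictor base [predictor_config()].
#' @return data.frame with columns `dimension`, `auc`, `aupr`, `f1`.
#' @export
sweep_dimension <- function(dims, ..., predictor = predictor_config()) {
  stopifnot(length(dims) >= 1)
  rows <- lapply(dims, function(d) {
    cfg <- predictor
    cfg$z <- as.integer(d)
    rep <- run_cv(..., predictor = cfg)
    data.frame(dimension = d, auc = rep$means[["auc"]],
               aupr = rep$means[["aupr"]], f1 = rep$means[["f1"]])
  })
  do.call(rbind, rows)
}
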