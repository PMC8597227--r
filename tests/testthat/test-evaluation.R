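# Negative sampling, fold construction, metrics and the ranking harness.

test_that("negative sampling hits the exact ratio over zero cells", {
  set.seed(1)
  A <- matrix(0, 10, 10, dimnames = list(paste0("m", 1:10),
                                         paste0("d", 1:10)))
  A[sample(100, 10)] <- 1
  neg <- sample_negatives(A, ratio = 5, seed = 3)
  expect_equal(nrow(neg), 50)
  expect_true(all(A[cbind(neg$mirna, neg$disease)] == 0))
  expect_equal(anyDuplicated(neg[, c("mirna", "disease")]), 0)

  A2 <- matrix(c(1, 0, 0, 0), 2, 2,
               dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_equal(nrow(sample_negatives(A2, 1, 1)), 1)
  expect_error(sample_negatives(A2, 5, 1), "not enough")

  expect_identical(sample_negatives(A, 5, 7), sample_negatives(A, 5, 7))
  draws <- vapply(1:100, function(s) {
    paste(sample_negatives(A2, 1, s)$mirna,
          sample_negatives(A2, 1, s)$disease)
  }, character(1))
  expect_gt(length(unique(draws)), 1)
})

test_that("k-fold split partitions pairs with stratified balance", {
  A <- matrix(0, 6, 6, dimnames = list(paste0("m", 1:6), paste0("d", 1:6)))
  A[cbind(1:6, 1:6)] <- 1
  pairs <- make_labeled_pairs(A, ratio = 5, seed = 2)  # 6 pos + 30 neg
  folds <- kfold_split(pairs, k = 5, seed = 2)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(test_idx, seq_len(nrow(pairs)))
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1))
  expect_lte(max(sizes) - min(sizes), 1)
  for (f in folds) {
    expect_gte(sum(f$test$label == 1), 1)
    expect_equal(sort(c(f$train_idx, f$test_idx)), seq_len(nrow(pairs)))
  }

  ten <- data.frame(mirna = 1:10, disease = 1, label = rep(c(0, 1), 5))
  sizes <- vapply(kfold_split(ten, 5, 1), function(f) nrow(f$test),
                  integer(1))
  expect_equal(sizes, rep(2L, 5))
})

test_that("AUC matches hand values and the tie rule", {
  expect_equal(auc(c(1, 0, 1), c(0.9, 0.8, 0.3)), 0.5)
  expect_equal(auc(c(1, 0), c(0.6, 0.6)), 0.5)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_error(auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC equals the brute-force pairwise probability", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    scores <- round(runif(n), 2)  # coarse grid forces ties
    expect_equal(auc(labels, scores), auc_brute(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUPR and F1 behave on separable and hand cases", {
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # ranked p,n,p: precision at recalls 1/2 and 1 -> 1/2*(1 + 2/3)
  expect_equal(auprc(c(1, 0, 1), c(0.9, 0.8, 0.3)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # predictions (1,1,0): TP=1, FP=1, FN=1 -> 2*1/(2*1+1+1)
  expect_equal(f1_score(c(1, 0, 1), c(0.9, 0.8, 0.3), 0.5), 0.5,
               tolerance = 1e-12)
  expect_equal(f1_score(c(0, 0), c(0.1, 0.2), 0.5), 0)
})

test_that("cross-validation on the tiny world recovers signal and reports honestly", {
  b <- fixture_preset("tiny", seed = 2)
  sims <- suppressWarnings(compute_similarities(b$A, b$ontology))
  cfg <- predictor_config(z = 8, mlp_hidden = 8, epochs = 80, patience = 0,
                          seed = 1)
  eoe <- eoe_config(epochs = 60, seed = 1)
  rep <- run_cv(b$A, similarities = sims, folds = 3, ratio = 2, seed = 5,
                eoe = eoe, predictor = cfg)
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$metrics), 3)
  expect_true(all(rep$metrics$auc >= 0 & rep$metrics$auc <= 1))
  expect_equal(unname(rep$means["auc"]), mean(rep$metrics$auc))
  expect_equal(unname(rep$means["f1"]), mean(rep$metrics$f1))
  # scores cover every test pair exactly once
  n_pairs <- nrow(make_labeled_pairs(b$A, ratio = 2, seed = 5))
  expect_equal(nrow(rep$scores), n_pairs)
})

test_that("pipeline AUC rises with planted signal strength", {
  run_at <- function(p_in, p_out) {
    b <- make_fixture_bundle(40, 30, n_groups = 4, p_in = p_in,
                             p_out = p_out, seed = 8)
    sims <- suppressWarnings(compute_similarities(b$A, b$ontology))
    rep <- run_cv(b$A, similarities = sims, folds = 3, ratio = 3, seed = 8,
                  eoe = eoe_config(epochs = 100, seed = 1),
                  predictor = predictor_config(z = 16, mlp_hidden = 16,
                                               epochs = 150, patience = 0,
                                               seed = 1))
    rep$means[["auc"]]
  }
  weak <- run_at(0.11, 0.10)   # almost no planted structure
  strong <- run_at(0.45, 0.02)
  expect_gt(strong, weak + 0.1)
})

test_that("candidate ranking excludes known links and sorts stably", {
  b <- fixture_preset("tiny", seed = 3)
  sims <- suppressWarnings(compute_similarities(b$A, b$ontology))
  model <- train_full_model(b$A, similarities = sims, ratio = 2, seed = 2,
                            eoe = eoe_config(epochs = 40, seed = 2),
                            predictor = predictor_config(
                              z = 8, mlp_hidden = 8, epochs = 40,
                              patience = 0, seed = 2))
  dis <- colnames(b$A)[1]
  top <- rank_candidates(model, dis, b$A, k = 5)
  expect_lte(nrow(top), 5)
  expect_true(all(b$A[cbind(match(top$mirna, rownames(b$A)),
                            match(dis, colnames(b$A)))] == 0))
  expect_true(all(diff(top$score) <= 1e-12))
  # k beyond availability returns everything without error
  all_cand <- rank_candidates(model, dis, b$A, k = 10000)
  expect_equal(nrow(all_cand), sum(b$A[, dis] == 0))
  expect_error(rank_candidates(model, "no-such-disease", b$A), "unknown")
})

test_that("dimension sweep emits one row per dimension, reproducibly", {
  b <- fixture_preset("tiny", seed = 4)
  sims <- suppressWarnings(compute_similarities(b$A, b$ontology))
  base <- predictor_config(mlp_hidden = 8, epochs = 30, patience = 0,
                           seed = 3)
  tab <- sweep_dimension(c(4, 8), A = b$A, similarities = sims, folds = 2,
                         ratio = 2, seed = 3,
                         eoe = eoe_config(epochs = 30, seed = 3),
                         predictor = base)
  expect_equal(tab$dimension, c(4, 8))
  expect_equal(nrow(tab), 2)
  tab2 <- sweep_dimension(c(4, 8), A = b$A, similarities = sims, folds = 2,
                          ratio = 2, seed = 3,
                          eoe = eoe_config(epochs = 30, seed = 3),
                          predictor = base)
  expect_identical(tab, tab2)
})
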