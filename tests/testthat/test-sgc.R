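# SGC propagation operator, forward pass, MLP scoring and training.

test_that("operator normalization matches hand values", {
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  op <- build_operator(adj)
  expect_equal(op$S, matrix(0.5, 2, 2))

  # empty graph -> identity
  expect_equal(build_operator(matrix(0, 3, 3))$S, diag(3))
  expect_error(build_operator(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("operator matches explicit D^{-1/2} (A+I) D^{-1/2} on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    adj <- matrix(rbinom(n * n, 1, 0.2), n, n)
    adj <- 1 * ((adj + t(adj)) > 0)
    diag(adj) <- 0
    op <- build_operator(adj)
    At <- adj + diag(n)
    Dh <- diag(1 / sqrt(rowSums(At)))
    expect_equal(op$S, Dh %*% At %*% Dh, tolerance = 1e-12)
    expect_equal(op$S, t(op$S), tolerance = 1e-12)
    expect_lte(max(abs(eigen(op$S, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-9)
  }
})

test_that("propagate equals naive repeated multiplication", {
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  S <- build_operator(adj)$S
  X <- matrix(c(1, 0), 2, 1)
  expect_equal(propagate(X, S, 0), X)
  expect_equal(propagate(X, S, 1), matrix(0.5, 2, 1))
  expect_equal(propagate(X, S, 2), propagate(X, S, 1)) # idempotent here

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    adj <- matrix(rbinom(n * n, 1, 0.2), n, n)
    adj <- 1 * ((adj + t(adj)) > 0); diag(adj) <- 0
    S <- build_operator(adj)$S
    X <- matrix(rnorm(n * 3), n, 3)
    k <- sample(0:5, 1)
    naive <- X
    for (i in seq_len(k)) naive <- S %*% naive
    expect_equal(propagate(X, S, k), naive, tolerance = 1e-10)
  }
})

test_that("feature mapping stacks miRNAs first, diseases second", {
  st <- list(mirna_vecs = matrix(c(1, 2), 1, 2),
             disease_vecs = matrix(c(3, 4), 1, 2))
  expect_equal(map_features(st, diag(2), diag(2)),
               rbind(c(1, 2), c(3, 4)))
  expect_equal(map_features(st, matrix(0, 2, 2), matrix(0, 2, 2)),
               matrix(0, 2, 2))
  expect_equal(map_features(st, matrix(c(1, 1), 2, 1),
                            matrix(c(1, 1), 2, 1)),
               matrix(c(3, 7), 2, 1))
  expect_error(map_features(st, diag(3), diag(2)), "match")
})

test_that("sgc_forward composes transform-then-propagate per layer", {
  set.seed(8)
  n <- 7
  adj <- matrix(rbinom(n * n, 1, 0.3), n, n)
  adj <- 1 * ((adj + t(adj)) > 0); diag(adj) <- 0
  op <- build_operator(adj)
  X <- matrix(rnorm(n * 4), n, 4)
  # identity transforms, one layer, K steps == plain propagation
  expect_equal(sgc_forward(X, op, list(diag(4)), k = 3),
               propagate(X, op, 3), tolerance = 1e-12)
  # two identity layers with K = 2 == S^4 X
  expect_equal(sgc_forward(X, op, list(diag(4), diag(4)), k = 2),
               propagate(X, op, 4), tolerance = 1e-12)
  # shape contract
  out <- sgc_forward(X, op, list(matrix(rnorm(16), 4, 4),
                                 matrix(rnorm(16), 4, 4)), k = 2)
  expect_equal(dim(out), c(n, 4))
})

test_that("MLP scoring behaves as specified", {
  mlp <- list(W1 = matrix(0, 4, 3), b1 = numeric(3),
              w2 = matrix(0, 3, 1), b2 = 0)
  expect_equal(score_pair(c(1, 2), c(3, 4), mlp), 0.5)

  set.seed(2)
  mlp2 <- eoesgc:::mlp_init(4, 8, seed = 3)
  s0 <- score_pair(c(1, 0), c(0, 1), mlp2)
  mlp3 <- mlp2; mlp3$b2 <- mlp2$b2 + 1
  expect_gt(score_pair(c(1, 0), c(0, 1), mlp3), s0)
  # pure per-pair function: same inputs, same score
  expect_equal(score_pair(c(1, 0), c(0, 1), mlp2), s0)
})

test_that("binary cross-entropy matches hand values", {
  expect_equal(bce_loss(1, 0.5), -log(0.5), tolerance = 1e-6)
  expect_equal(bce_loss(0, 0.5), -log(0.5), tolerance = 1e-6)
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)),
               -mean(log(c(0.9, 0.9))), tolerance = 1e-9)
})

test_that("predictor gradients match finite differences", {
  set.seed(6)
  b <- make_associations(6, 5, n_groups = 2, p_in = 0.8, p_out = 0.1,
                         seed = 6)
  adj <- bipartite_adjacency(b$A)
  feats <- list(mirna = matrix(rnorm(6 * 4), 6, 4),
                disease = matrix(rnorm(5 * 4), 5, 4))
  pairs <- make_labeled_pairs(b$A, ratio = 1, seed = 6)
  cfg <- predictor_config(z = 3, mlp_hidden = 4, seed = 6, patience = 0)
  params <- eoesgc:::predictor_init(4, 4, cfg)
  op <- build_operator(adj)
  Pk <- propagate(diag(11), op, cfg$k)
  cache <- eoesgc:::predictor_forward(params, feats, Pk, pairs, cfg)
  grads <- eoesgc:::predictor_backward(params, feats, Pk, pairs, cfg, cache)
  loss_at <- function(p) {
    c2 <- eoesgc:::predictor_forward(p, feats, Pk, pairs, cfg)
    bce_loss(pairs$label, c2$fw$yhat)
  }
  eps <- 1e-6
  for (nm in c("W_M", "T1", "T2", "W1", "w2")) {
    p <- params
    i <- 1; j <- min(2, ncol(p[[nm]]))
    p[[nm]][i, j] <- p[[nm]][i, j] + eps; up <- loss_at(p)
    p[[nm]][i, j] <- p[[nm]][i, j] - 2 * eps; dn <- loss_at(p)
    expect_equal(grads[[nm]][i, j], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("predictor training is deterministic and loss decreases", {
  b <- make_associations(10, 8, n_groups = 2, p_in = 0.7, p_out = 0.05,
                         seed = 2)
  adj <- bipartite_adjacency(b$A)
  feats <- list(mirna = diag(10), disease = diag(8))
  pairs <- make_labeled_pairs(b$A, ratio = 2, seed = 2)
  cfg <- predictor_config(z = 8, mlp_hidden = 8, epochs = 60, patience = 0,
                          seed = 4)
  m1 <- train_predictor(feats, adj, pairs, cfg)
  m2 <- train_predictor(feats, adj, pairs, cfg)
  expect_identical(predict_pairs(m1, pairs), predict_pairs(m2, pairs))
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
})
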