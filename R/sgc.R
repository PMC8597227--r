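#' Predictor configuration
#'
#' Defaults follow the reference configuration of the method: two simplified
#' graph-convolution layers, each aggregating two-hop neighbourhoods
#' (`k = 2`), output dimension `z = 64`, and an MLP head whose first fully
#' connected layer has 64 neurons.
#'
#' @param layers number of SGC layers (default 2).
#' @param k propagation steps per layer (default 2).
#' @param z shared feature-space dimension (default 64).
#' @param mlp_hidden hidden width of the MLP head on the concatenated
#'   2z-dimensional pair feature (default 64).
#' @param interlayer_activation `"none"` (the defining SGC simplification) or
#'   `"relu"` between convolution layers.
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs maximum training epochs (default 300).
#' @param patience early-stopping patience on validation AUC, counted in
#'   validation checks (one check every `eval_every` epochs); the weights
#'   from the best check are restored. 0 disables early stopping
#'   (default 10).
#' @param eval_every epochs between validation checks (default 10).
#' @param val_fraction fraction of training pairs held out for early
#'   stopping (stratified; default 0.1, ignored when `patience = 0`).
#' @param threshold score cut classifying a pair positive for F1 (default
#'   0.5).
#' @param use_eoe when `FALSE`, skips the EOE stage and feeds the raw
#'   similarity rows to the convolution (the SGC-only ablation).
#' @param seed integer seed for weight init and the validation split.
#' @return object of class `predictor_config`.
#' @export
predictor_config <- function(layers = 2, k = 2, z = 64, mlp_hidden = 64,
                             interlayer_activation = c("none", "relu"),
                             learning_rate = 1e-3, epochs = 300,
                             patience = 10, eval_every = 10,
                             val_fraction = 0.1,
                             threshold = 0.5, use_eoe = TRUE, seed = 1) {
  interlayer_activation <- match.arg(interlayer_activation)
  stopifnot(layers >= 1, k >= 0, z >= 1, mlp_hidden >= 1,
            learning_rate > 0, epochs >= 1, patience >= 0, eval_every >= 1,
            val_fraction >= 0, val_fraction < 1,
            threshold >= 0, threshold <= 1)
  structure(list(layers = as.integer(layers), k = as.integer(k),
                 z = as.integer(z), mlp_hidden = as.integer(mlp_hidden),
                 interlayer_activation = interlayer_activation,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 val_fraction = val_fraction, threshold = threshold,
                 use_eoe = isTRUE(use_eoe), seed = as.integer(seed)),
            class = "predictor_config")
}

#' Symmetrically normalized propagation operator
#'
#' `S = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of `A + I`.
#' Rows of isolated nodes reduce to a self-weight of 1; the spectral radius
#' of `S` is at most 1.
#'
#' @param adj symmetric binary adjacency matrix.
#' @return object of class `propagation_operator` with fields `S` and
#'   `degree` (degrees of `A + I`).
#' @export
build_operator <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 0) stop("adjacency must be symmetric",
                                       call. = FALSE)
  At <- adj + diag(nrow(adj))
  deg <- rowSums(At)
  inv_sqrt <- 1 / sqrt(deg)
  S <- At * outer(inv_sqrt, inv_sqrt)
  dimnames(S) <- dimnames(adj)
  structure(list(S = S, degree = deg), class = "propagation_operator")
}

#' Propagate features k steps
#'
#' `S^k X` computed by k successive multiplications; `k = 0` returns `X`
#' unchanged.
#'
#' @param X node feature matrix.
#' @param S propagation matrix (or a [build_operator()] result).
#' @param k nonnegative integer step count.
#' @return propagated feature matrix.
#' @export
propagate <- function(X, S, k) {
  stopifnot(k >= 0)
  if (inherits(S, "propagation_operator")) S <- S$S
  for (i in seq_len(k)) X <- S %*% X
  X
}

#' Map EOE embeddings into the shared feature space
#'
#' Applies the type-specific linear maps and stacks the results in the fixed
#' node order (miRNAs `1..m`, then diseases).
#'
#' @param eoe_state an `eoe_state` (or any list with `mirna_vecs`,
#'   `disease_vecs`).
#' @param W_M miRNA map, `p_m x z`.
#' @param W_D disease map, `p_d x z`.
#' @return `(m+n) x z` feature matrix.
#' @export
map_features <- function(eoe_state, W_M, W_D) {
  if (ncol(eoe_state$mirna_vecs) != nrow(W_M) ||
      ncol(eoe_state$disease_vecs) != nrow(W_D)) {
    stop("mapping matrix dimensions do not match embeddings", call. = FALSE)
  }
  rbind(eoe_state$mirna_vecs %*% W_M, eoe_state$disease_vecs %*% W_D)
}

#' SGC forward pass
#'
#' Each layer applies its linear transform and then `k` propagation steps:
#' `H_l = S^k (H_{l-1} T_l)`, with no nonlinearity between layers unless
#' configured otherwise.
#'
#' @param X stacked input features (`(m+n) x z`).
#' @param operator a [build_operator()] result.
#' @param transforms list of `z x z` layer transforms.
#' @param k propagation steps per layer.
#' @param interlayer_activation `"none"` or `"relu"` (applied between
#'   layers, never after the last).
#' @return final node embedding matrix, same shape as `X`.
#' @export
sgc_forward <- function(X, operator, transforms, k = 2,
                        interlayer_activation = "none") {
  Pk <- propagate(diag(nrow(operator$S)), operator, k)
  H <- X
  L <- length(transforms)
  for (l in seq_len(L)) {
    H <- Pk %*% (H %*% transforms[[l]])
    if (interlayer_activation == "relu" && l < L) H <- relu(H)
  }
  H
}

mlp_init <- function(in_dim, hidden, seed) {
  set.seed(derive_seed(seed, "mlp-init"))
  list(
    W1 = matrix(stats::rnorm(in_dim * hidden, sd = sqrt(2 / (in_dim + hidden))),
                in_dim, hidden),
    b1 = numeric(hidden),
    w2 = matrix(stats::rnorm(hidden, sd = sqrt(2 / (hidden + 1))), hidden, 1),
    b2 = 0
  )
}

mlp_forward <- function(E, mlp) {
  Z1 <- sweep(E %*% mlp$W1, 2, mlp$b1, `+`)
  A1 <- relu(Z1)
  z2 <- drop(A1 %*% mlp$w2) + mlp$b2
  list(Z1 = Z1, A1 = A1, z2 = z2, yhat = sigmoid(z2))
}

#' Score one miRNA-disease pair
#'
#' Concatenates the two z-dimensional embeddings, feeds them through the
#' two-layer MLP (rectified hidden layer, sigmoid output).
#'
#' @param emb_mirna,emb_disease embedding vectors of length z.
#' @param mlp MLP weights (`W1`, `b1`, `w2`, `b2`).
#' @return association score in (0,1).
#' @export
score_pair <- function(emb_mirna, emb_disease, mlp) {
  e <- matrix(c(emb_mirna, emb_disease), nrow = 1)
  if (ncol(e) != nrow(mlp$W1)) stop("embedding length mismatch",
                                    call. = FALSE)
  mlp_forward(e, mlp)$yhat
}

#' Binary cross-entropy loss
#'
#' `-(y log yhat + (1-y) log(1-yhat))`, elementwise mean over vectors, with
#' probabilities clamped away from 0 and 1.
#'
#' @param y labels in \{0,1\}.
#' @param yhat scores in (0,1).
#' @param eps clamp.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(y, yhat, eps = 1e-12) {
  yhat <- clamp_prob(yhat, eps)
  mean(-(y * log(yhat) + (1 - y) * log(1 - yhat)))
}

predictor_init <- function(p_m, p_d, config) {
  set.seed(derive_seed(config$seed, "predictor-init"))
  z <- config$z
  gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  params <- list(W_M = gl(p_m, z), W_D = gl(p_d, z))
  for (l in seq_len(config$layers)) params[[paste0("T", l)]] <- gl(z, z)
  mlp <- mlp_init(2 * z, config$mlp_hidden, config$seed)
  c(params, mlp)
}

# Forward pass through map -> SGC -> MLP for a batch of (i_m, j_d) pairs.
predictor_forward <- function(params, feats, Pk, pairs, config) {
  m <- nrow(feats$mirna)
  X0 <- rbind(feats$mirna %*% params$W_M, feats$disease %*% params$W_D)
  H <- list(X0)
  pre <- list()
  act <- config$interlayer_activation == "relu"
  for (l in seq_len(config$layers)) {
    Hl <- Pk %*% (H[[l]] %*% params[[paste0("T", l)]])
    pre[[l]] <- Hl
    if (act && l < config$layers) Hl <- relu(Hl)
    H[[l + 1]] <- Hl
  }
  HF <- H[[config$layers + 1]]
  E <- cbind(HF[pairs$mirna, , drop = FALSE],
             HF[m + pairs$disease, , drop = FALSE])
  fw <- mlp_forward(E, params)
  list(X0 = X0, H = H, pre = pre, HF = HF, E = E, fw = fw)
}

predictor_backward <- function(params, feats, Pk, pairs, config, cache) {
  m <- nrow(feats$mirna)
  n_b <- nrow(pairs)
  z <- config$z
  dz2 <- matrix((cache$fw$yhat - pairs$label) / n_b, ncol = 1)
  grads <- list(
    w2 = crossprod(cache$fw$A1, dz2),
    b2 = sum(dz2)
  )
  dA1 <- dz2 %*% t(params$w2)
  dZ1 <- dA1 * (cache$fw$Z1 > 0)
  grads$W1 <- crossprod(cache$E, dZ1)
  grads$b1 <- colSums(dZ1)
  dE <- dZ1 %*% t(params$W1)
  dHF <- matrix(0, nrow(cache$HF), z)
  rs_m <- rowsum(dE[, seq_len(z), drop = FALSE], pairs$mirna)
  dHF[as.integer(rownames(rs_m)), ] <- rs_m
  rs_d <- rowsum(dE[, z + seq_len(z), drop = FALSE], pairs$disease)
  dHF[m + as.integer(rownames(rs_d)), ] <-
    dHF[m + as.integer(rownames(rs_d)), , drop = FALSE] + rs_d
  act <- config$interlayer_activation == "relu"
  dH <- dHF
  for (l in rev(seq_len(config$layers))) {
    if (act && l < config$layers) dH <- dH * (cache$pre[[l]] > 0)
    dM <- crossprod(Pk, dH) # Pk symmetric but keep exact transpose
    grads[[paste0("T", l)]] <- crossprod(cache$H[[l]], dM)
    dH <- dM %*% t(params[[paste0("T", l)]])
  }
  grads$W_M <- crossprod(feats$mirna, dH[seq_len(m), , drop = FALSE])
  grads$W_D <- crossprod(feats$disease, dH[m + seq_len(nrow(feats$disease)),
                                           , drop = FALSE])
  grads
}

#' Train the prediction head end-to-end
#'
#' Jointly trains the two feature maps, the per-layer SGC transforms and the
#' MLP on binary cross-entropy over the supplied labeled pairs, with
#' full-batch Adam. Propagation runs over the (fold-masked) bipartite
#' association adjacency only. Optional early stopping monitors AUC on a
#' stratified validation split of the training pairs.
#'
#' @param features list with `mirna` (n_m x p_m) and `disease` (n_d x p_d)
#'   input feature matrices (EOE embeddings, or raw similarity rows for the
#'   SGC-only ablation).
#' @param adjacency bipartite adjacency from [bipartite_adjacency()] (test
#'   edges already masked).
#' @param pairs data.frame with integer columns `mirna`, `disease` and
#'   binary `label`.
#' @param config a [predictor_config()].
#' @param verbose print loss every 20 epochs.
#' @return object of class `predictor_state` holding all weights, the final
#'   node embeddings on this adjacency, loss history and the config.
#' @export
train_predictor <- function(features, adjacency, pairs,
                            config = predictor_config(), verbose = FALSE) {
  stopifnot(is.list(features), is.data.frame(pairs),
            all(c("mirna", "disease", "label") %in% names(pairs)))
  m <- nrow(features$mirna)
  n <- nrow(features$disease)
  stopifnot(nrow(adjacency) == m + n)
  op <- build_operator(adjacency)
  Pk <- propagate(diag(m + n), op, config$k)
  params <- predictor_init(ncol(features$mirna), ncol(features$disease),
                           config)

  train <- pairs
  val <- NULL
  if (config$patience > 0 && config$val_fraction > 0 && nrow(pairs) >= 20) {
    set.seed(derive_seed(config$seed, "predictor-valsplit"))
    idx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$label),
                         function(ii) {
                           sample(ii, max(1, round(config$val_fraction *
                                                     length(ii))))
                         }), use.names = FALSE)
    if (length(unique(pairs$label[idx])) == 2 &&
        length(unique(pairs$label[-idx])) == 2) {
      val <- pairs[idx, , drop = FALSE]
      train <- pairs[-idx, , drop = FALSE]
    }
  }

  opt <- adam_init(params)
  history <- numeric(0)
  val_history <- numeric(0)
  best_auc <- -Inf
  best_params <- params
  stall <- 0L
  for (ep in seq_len(config$epochs)) {
    cache <- predictor_forward(params, features, Pk, train, config)
    loss <- bce_loss(train$label, cache$fw$yhat)
    if (!is.finite(loss)) {
      stop("predictor training diverged at epoch ", ep, call. = FALSE)
    }
    history <- c(history, loss)
    grads <- predictor_backward(params, features, Pk, train, config, cache)
    step <- adam_step(params, grads, opt, lr = config$learning_rate)
    params <- step$params
    opt <- step$state
    if (!is.null(val) && ep %% config$eval_every == 0) {
      vf <- predictor_forward(params, features, Pk, val, config)
      vauc <- auc(val$label, vf$fw$yhat)
      val_history <- c(val_history, vauc)
      if (vauc > best_auc + 1e-6) {
        best_auc <- vauc
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    if (verbose && ep %% 20 == 0) {
      message("predictor epoch ", ep, " loss ", format(loss, digits = 6))
    }
  }
  if (!is.null(val)) params <- best_params
  final <- predictor_forward(params, features, Pk,
                             pairs[1, , drop = FALSE], config)
  structure(
    list(params = params, config = config,
         n_mirna = m, n_disease = n,
         mirna_labels = rownames(adjacency)[seq_len(m)],
         disease_labels = rownames(adjacency)[m + seq_len(n)],
         embeddings = final$HF, loss_history = history,
         val_history = val_history),
    class = "predictor_state"
  )
}

#' @export
print.predictor_state <- function(x, ...) {
  cat("predictor_state:", x$n_mirna, "miRNAs,", x$n_disease, "diseases, z =",
      x$config$z, "|", length(x$loss_history), "epochs trained\n")
  invisible(x)
}

#' Score miRNA-disease pairs with a trained predictor
#'
#' Uses the node embeddings computed on the adjacency the model was trained
#' with (pure function of the stored state; batch order has no effect).
#'
#' @param state a [train_predictor()] result.
#' @param pairs data.frame with integer columns `mirna`, `disease`.
#' @return numeric score vector in (0,1).
#' @export
predict_pairs <- function(state, pairs) {
  stopifnot(inherits(state, "predictor_state"))
  HF <- state$embeddings
  E <- cbind(HF[pairs$mirna, , drop = FALSE],
             HF[state$n_mirna + pairs$disease, , drop = FALSE])
  as.numeric(mlp_forward(E, state$params)$yhat)
}
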