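#' EOE training configuration
#'
#' @param epochs number of full-gradient epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param optimizer only `"adam"` is implemented.
#' @param negative negative-pair strategy: `"all_pairs"` (exact, tractable at
#'   the few-hundred-node scale this method targets) or a positive integer k
#'   for `k` sampled non-edges per edge, drawn once at training start.
#' @param seed integer seed controlling harmony-matrix init and sampling.
#' @param init `"similarity"` initializes node vectors from the rows of the
#'   thresholded similarity matrices (so embedding dimensions equal the node
#'   counts); `"spectral"` uses a rank-`init_rank` truncated eigen
#'   factorization of each similarity matrix for speed.
#' @param init_rank rank for spectral init.
#' @param eps log-clamp keeping the loss finite.
#' @return object of class `eoe_config`.
#' @export
eoe_config <- function(epochs = 200, learning_rate = 1e-3,
                       optimizer = "adam", negative = "all_pairs",
                       seed = 1, init = c("similarity", "spectral"),
                       init_rank = 32, eps = 1e-12) {
  init <- match.arg(init)
  stopifnot(epochs >= 1, learning_rate > 0, identical(optimizer, "adam"),
            identical(negative, "all_pairs") ||
              (is.numeric(negative) && negative >= 1))
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, negative = negative,
                 seed = as.integer(seed), init = init,
                 init_rank = as.integer(init_rank), eps = eps),
            class = "eoe_config")
}

#' Proximity between two nodes of the same type
#'
#' `sigmoid(u . v)`: large positive inner products mean near-certain links.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in (0,1).
#' @export
proximity_same <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  as.numeric(sigmoid(sum(u * v)))
}

#' Proximity between nodes of different types
#'
#' Disease and miRNA vectors live in different feature spaces; the learned
#' harmony matrix `M` supplies the bilinear form: `sigmoid(d^T M m)`.
#'
#' @param d disease vector (length p_d).
#' @param m miRNA vector (length p_m).
#' @param M harmony matrix (p_d x p_m).
#' @return scalar in (0,1).
#' @export
proximity_cross <- function(d, m, M) {
  if (length(d) != nrow(M) || length(m) != ncol(M)) {
    stop("dimension mismatch between d, M, m", call. = FALSE)
  }
  as.numeric(sigmoid(drop(crossprod(d, M %*% m))))
}

# Per-pair logit-gradient coefficient masks plus edge/non-edge bookkeeping.
# For each same-type unordered pair (i<j): edges contribute -W*log(p),
# non-edges -log(1-p); the derivative wrt the logit is -W*(1-p) resp. p.
# "excluded" cells (held-out CV pairs in the cross block, or unsampled
# non-edges under a sampled negative strategy) contribute nothing.
eoe_masks <- function(graph, config, exclude_md = NULL) {
  n_m <- length(graph$mirna_labels)
  n_d <- length(graph$disease_labels)
  edge_m <- graph$MS != 0 & upper.tri(graph$MS)
  edge_d <- graph$DS != 0 & upper.tri(graph$DS)
  edge_md <- graph$A == 1
  non_m <- graph$MS == 0 & upper.tri(graph$MS)
  non_d <- graph$DS == 0 & upper.tri(graph$DS)
  non_md <- graph$A == 0
  if (!is.null(exclude_md)) {
    ex <- as.matrix(exclude_md)[, 1:2, drop = FALSE]
    storage.mode(ex) <- "integer"
    edge_md[ex] <- FALSE
    non_md[ex] <- FALSE
  }
  if (!identical(config$negative, "all_pairs")) {
    k <- as.integer(config$negative)
    set.seed(derive_seed(config$seed, "eoe-negative-sampling"))
    pick <- function(non, n_edges) {
      idx <- which(non)
      keep <- idx[sample.int(length(idx),
                             min(length(idx), k * max(n_edges, 1)))]
      out <- non & FALSE
      out[keep] <- TRUE
      out
    }
    non_m <- pick(non_m, sum(edge_m))
    non_d <- pick(non_d, sum(edge_d))
    non_md <- pick(non_md, sum(edge_md))
  }
  list(edge_m = edge_m, edge_d = edge_d, edge_md = edge_md,
       non_m = non_m, non_d = non_d, non_md = non_md,
       n_m = n_m, n_d = n_d)
}

eoe_loss_grad <- function(state, graph, masks, eps = 1e-12,
                          want_grad = TRUE) {
  D <- state$disease_vecs
  Mm <- state$mirna_vecs
  H <- state$harmony
  P_d <- sigmoid(tcrossprod(D))
  P_m <- sigmoid(tcrossprod(Mm))
  P_dm <- sigmoid(D %*% H %*% t(Mm)) # n_d x n_m

  # association block is indexed miRNA x disease in the graph; transpose
  edge_md <- t(masks$edge_md)
  non_md <- t(masks$non_md)
  W_dm <- graph$w_dm

  loss <- -sum(graph$DS[masks$edge_d] * log(clamp_prob(P_d[masks$edge_d], eps))) -
    sum(graph$MS[masks$edge_m] * log(clamp_prob(P_m[masks$edge_m], eps))) -
    W_dm * sum(log(clamp_prob(P_dm[edge_md], eps))) -
    sum(log(clamp_prob(1 - P_d[masks$non_d], eps))) -
    sum(log(clamp_prob(1 - P_m[masks$non_m], eps))) -
    sum(log(clamp_prob(1 - P_dm[non_md], eps)))
  if (!want_grad) return(list(loss = loss))

  # symmetric coefficient matrices G with G_ij = d loss / d logit_ij
  G_d <- matrix(0, nrow(P_d), ncol(P_d))
  G_d[masks$edge_d] <- -graph$DS[masks$edge_d] * (1 - P_d[masks$edge_d])
  G_d[masks$non_d] <- P_d[masks$non_d]
  G_d <- G_d + t(G_d)
  G_m <- matrix(0, nrow(P_m), ncol(P_m))
  G_m[masks$edge_m] <- -graph$MS[masks$edge_m] * (1 - P_m[masks$edge_m])
  G_m[masks$non_m] <- P_m[masks$non_m]
  G_m <- G_m + t(G_m)
  G_dm <- matrix(0, nrow(P_dm), ncol(P_dm))
  G_dm[edge_md] <- -W_dm * (1 - P_dm[edge_md])
  G_dm[non_md] <- P_dm[non_md]

  grad <- list(
    disease_vecs = G_d %*% D + G_dm %*% Mm %*% t(H),
    mirna_vecs = G_m %*% Mm + t(G_dm) %*% D %*% H,
    harmony = t(D) %*% G_dm %*% Mm
  )
  list(loss = loss, grad = grad)
}

#' EOE loss over a coupled graph
#'
#' The six-term link loss: weighted negative log-proximity over the three
#' edge sets (disease-disease, miRNA-miRNA, disease-miRNA) plus negative
#' `log(1 - p)` over the corresponding non-edge sets, so linked nodes are
#' pulled together and unlinked nodes pushed apart. Intra-type pairs are
#' counted once (unordered); intra-type edge weights are the similarity
#' values, inter-type weights the graph's `w_dm`.
#'
#' @param state an `eoe_state` (see [train_eoe()]).
#' @param graph a [assemble_graph()] result.
#' @param config an [eoe_config()] (controls the negative-pair strategy).
#' @param exclude_md optional (miRNA, disease) index pairs excluded from both
#'   the edge and non-edge cross-type sets (held-out CV cells).
#' @return nonnegative scalar loss.
#' @export
eoe_loss <- function(state, graph, config = eoe_config(),
                     exclude_md = NULL) {
  masks <- eoe_masks(graph, config, exclude_md)
  eoe_loss_grad(state, graph, masks, eps = config$eps,
                want_grad = FALSE)$loss
}

eoe_init_state <- function(graph, config) {
  if (config$init == "similarity") {
    D <- graph$DS
    Mm <- graph$MS
  } else {
    lowrank <- function(S, r) {
      e <- eigen(S, symmetric = TRUE)
      r <- min(r, sum(e$values > 1e-10))
      e$vectors[, seq_len(r), drop = FALSE] %*%
        diag(sqrt(e$values[seq_len(r)]), r)
    }
    D <- lowrank(graph$DS, config$init_rank)
    Mm <- lowrank(graph$MS, config$init_rank)
  }
  set.seed(derive_seed(config$seed, "eoe-harmony-init"))
  H <- matrix(stats::rnorm(ncol(D) * ncol(Mm), sd = 0.01),
              nrow = ncol(D), ncol = ncol(Mm))
  structure(
    list(disease_vecs = unname(as.matrix(D)),
         mirna_vecs = unname(as.matrix(Mm)), harmony = H),
    class = "eoe_state"
  )
}

#' Train the EOE model on a coupled graph
#'
#' Full-gradient Adam on the link loss of [eoe_loss()], jointly over the
#' disease vectors, miRNA vectors and the harmony matrix. Node vectors start
#' from the rows of the thresholded similarity matrices (the similarity
#' profile is the original feature); the harmony matrix starts small-random
#' under the configured seed. Deterministic given the seed.
#'
#' @param graph a [assemble_graph()] result.
#' @param config an [eoe_config()].
#' @param exclude_md optional held-out (miRNA, disease) index pairs, see
#'   [eoe_loss()].
#' @param verbose print the loss every 50 epochs.
#' @return an `eoe_state`: list with `disease_vecs` (n_d x p_d),
#'   `mirna_vecs` (n_m x p_m), `harmony` (p_d x p_m), `loss_history`,
#'   `config`.
#' @export
train_eoe <- function(graph, config = eoe_config(), exclude_md = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(graph, "coupled_graph"), inherits(config, "eoe_config"))
  masks <- eoe_masks(graph, config, exclude_md)
  state <- eoe_init_state(graph, config)
  params <- state[c("disease_vecs", "mirna_vecs", "harmony")]
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lg <- eoe_loss_grad(state, graph, masks, eps = config$eps)
    if (!is.finite(lg$loss)) {
      stop("EOE training diverged at epoch ", ep, " (loss = ", lg$loss, ")",
           call. = FALSE)
    }
    history[ep] <- lg$loss
    step <- adam_step(params, lg$grad, opt, lr = config$learning_rate)
    params <- step$params
    opt <- step$state
    state$disease_vecs <- params$disease_vecs
    state$mirna_vecs <- params$mirna_vecs
    state$harmony <- params$harmony
    if (verbose && ep %% 50 == 0) {
      message("EOE epoch ", ep, " loss ", format(lg$loss, digits = 6))
    }
  }
  state$loss_history <- history
  state$config <- config
  state
}

#' @export
print.eoe_state <- function(x, ...) {
  cat("eoe_state:", nrow(x$mirna_vecs), "miRNA vectors (p =",
      ncol(x$mirna_vecs), "),", nrow(x$disease_vecs), "disease vectors (p =",
      ncol(x$disease_vecs), ")\n")
  invisible(x)
}
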