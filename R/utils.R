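# Internal numeric helpers shared across modules.

#' Numerically stable logistic function
#'
#' @param x numeric vector or matrix.
#' @return values in (0,1), same shape as `x`.
#' @keywords internal
#' @noRd
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out
}

# Clamp probabilities away from {0,1} so log() stays finite.
clamp_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Derive a stream-specific 32-bit seed from a master seed
#'
#' All randomness in the package flows from one user seed through this
#' splitter: each consumer names its stream, so adding a stream never
#' perturbs the draws of another.
#'
#' @param seed master integer seed.
#' @param stream character stream label.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 131 + cp) %% 1977326743
  as.integer((abs(seed) %% 1977326743 * 31 + h) %% 2147483646 + 1)
}

# Adam optimizer over a named list of numeric arrays (shapes preserved).
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Symmetry / range guard used by every similarity producer.
check_similarity_matrix <- function(S, what = "similarity matrix",
                                    tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  if (min(S) < -tol || max(S) > 1 + tol) {
    stop(what, " entries must lie in [0,1]", call. = FALSE)
  }
  invisible(S)
}

check_same_labels <- function(a, b, what = "matrices") {
  if (!identical(rownames(a), rownames(b))) {
    stop(what, " have mismatched labels", call. = FALSE)
  }
  invisible(TRUE)
}
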