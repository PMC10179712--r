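# Attention fusion of the branch embeddings and the regression head.
#
# Each branch embedding Z_i is scored w_i = W2 . tanh(W1 Z_i) with W1, W2
# shared across branches; a softmax over the scores gives attention
# weights, and the weighted embeddings are concatenated before a
# three-layer fully connected head predicts the affinity.

#' Construct fusion / head parameters
#'
#' @param n_branches number of fused branches (3, or 2 for the no-motif
#'   ablation).
#' @param embed_dim branch embedding width (128).
#' @param att_dim width of the shared attention projection.
#' @param hidden hidden widths of the head (1024, 512 per the published
#'   sizing); the final layer is linear with a single output.
#' @param dropout dropout rate after each hidden head layer in training.
#' @param use_attention `FALSE` gives the plain-concatenation ablation
#'   (equal implicit weights; no attention parameters created).
#' @param seed optional seed for reproducible initialisation.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(n_branches = 3, embed_dim = 128, att_dim = 128,
                          hidden = c(1024, 512), dropout = 0.2,
                          use_attention = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  in_dim <- n_branches * embed_dim
  p <- list(
    n_branches = n_branches, embed_dim = embed_dim, dropout = dropout,
    use_attention = use_attention,
    Wh1 = glorot(in_dim, hidden[1]), bh1 = numeric(hidden[1]),
    Wh2 = glorot(hidden[1], hidden[2]), bh2 = numeric(hidden[2]),
    Wh3 = glorot(hidden[2], 1), bh3 = 0
  )
  if (use_attention) {
    p$W1 <- glorot(att_dim, embed_dim)  # acts on column vectors: W1 %*% z
    p$W2 <- stats::runif(att_dim, -0.1, 0.1)
  }
  structure(p, class = "fusion_params")
}

.fuse_forward <- function(zs, params) {
  if (params$use_attention) {
    q <- lapply(zs, function(z) tanh(as.vector(params$W1 %*% z)))
    w <- vapply(q, function(qi) sum(params$W2 * qi), numeric(1))
    alpha <- softmax(w)
  } else {
    q <- NULL
    alpha <- rep(1, length(zs))
  }
  zc <- unlist(mapply(function(a, z) a * z, alpha, zs, SIMPLIFY = FALSE),
               use.names = FALSE)
  list(zc = zc, alpha = alpha, cache = list(zs = zs, q = q, alpha = alpha))
}

.fuse_backward <- function(dzc, cache, params) {
  zs <- cache$zs
  k <- length(zs)
  d <- params$embed_dim
  slices <- split(dzc, rep(seq_len(k), each = d))
  dz <- mapply(function(a, s) a * s, cache$alpha, slices, SIMPLIFY = FALSE)
  g <- list()
  if (params$use_attention) {
    dalpha <- vapply(seq_len(k), function(i) sum(slices[[i]] * zs[[i]]),
                     numeric(1))
    dw <- cache$alpha * (dalpha - sum(cache$alpha * dalpha))
    dW1 <- matrix(0, nrow(params$W1), ncol(params$W1))
    dW2 <- numeric(length(params$W2))
    for (i in seq_len(k)) {
      qi <- cache$q[[i]]
      dq <- params$W2 * dw[i]
      dW2 <- dW2 + qi * dw[i]
      dqpre <- dq * (1 - qi^2)
      dW1 <- dW1 + outer(dqpre, zs[[i]])
      dz[[i]] <- dz[[i]] + as.vector(crossprod(params$W1, dqpre))
    }
    g$W1 <- dW1; g$W2 <- dW2
  }
  list(dz = dz, grads = g)
}

#' Attention fusion of the three branch embeddings
#'
#' Scores each embedding with the shared projection, softmax-normalises the
#' scores into attention weights `alpha`, and concatenates the weighted
#' embeddings into the drug-target pair vector `Zc`.
#'
#' @param zd,zm,zp drug atom-level, drug motif-level and protein
#'   embeddings (each of length `embed_dim`).
#' @param params a [fusion_params()] with `n_branches = 3`.
#' @return `list(zc = <3 * embed_dim vector>, alpha = <3 weights>)`.
#' @export
attention_fuse <- function(zd, zm, zp, params) {
  lens <- c(length(zd), length(zm), length(zp))
  if (any(lens != params$embed_dim)) {
    stop_mgdta("attention_fuse: embeddings must all have length ",
               params$embed_dim, ", got ", paste(lens, collapse = "/"))
  }
  fw <- .fuse_forward(list(zd, zm, zp), params)
  list(zc = fw$zc, alpha = fw$alpha)
}

.head_forward <- function(zc, params, training = FALSE) {
  keep <- 1 - params$dropout
  h1pre <- as.vector(zc %*% params$Wh1) + params$bh1
  m1 <- if (training) (stats::runif(length(h1pre)) < keep) / keep else 1
  h1 <- relu(h1pre) * m1
  h2pre <- as.vector(h1 %*% params$Wh2) + params$bh2
  m2 <- if (training) (stats::runif(length(h2pre)) < keep) / keep else 1
  h2 <- relu(h2pre) * m2
  y <- sum(h2 * params$Wh3) + params$bh3
  list(out = y, cache = list(zc = zc, h1pre = h1pre, h1 = h1,
                             h2pre = h2pre, h2 = h2, m1 = m1, m2 = m2))
}

.head_backward <- function(dy, cache, params) {
  g <- list()
  g$Wh3 <- matrix(cache$h2 * dy, ncol = 1)
  g$bh3 <- dy
  dh2 <- as.vector(params$Wh3) * dy * cache$m2
  dh2pre <- dh2 * (cache$h2pre > 0)
  g$Wh2 <- outer(cache$h1, dh2pre)
  g$bh2 <- dh2pre
  dh1 <- as.vector(params$Wh2 %*% dh2pre) * cache$m1
  dh1pre <- dh1 * (cache$h1pre > 0)
  g$Wh1 <- outer(cache$zc, dh1pre)
  g$bh1 <- dh1pre
  dzc <- as.vector(params$Wh1 %*% dh1pre)
  list(dzc = dzc, grads = g)
}

#' Predict affinity from a fused pair vector
#'
#' Three consecutive fully connected layers (in -> 1024 -> 512 -> 1), ReLU
#' activations on the hidden layers, linear output; dropout after each
#' hidden layer during training only.
#'
#' @param zc fused pair vector from [attention_fuse()].
#' @param params a [fusion_params()].
#' @param training logical; enables dropout.
#' @return scalar predicted affinity.
#' @export
predict_affinity <- function(zc, params, training = FALSE) {
  if (length(zc) != params$n_branches * params$embed_dim) {
    stop_mgdta("predict_affinity: expected input of length ",
               params$n_branches * params$embed_dim, ", got ", length(zc))
  }
  .head_forward(zc, params, training)$out
}
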