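# Graph encoders: three conv layers (GCN or GAT) with a gated
# skip-connection between hidden layers, graph-level pooling, and a
# two-stage fully connected projection to a 128-dim embedding.
#
# Layer widths follow the N / 4N / 4N input sizing: layer 1 maps N -> 4N,
# layers 2 and 3 map 4N -> 4N, and the gate (which needs equal widths)
# interpolates each of layers 2-3 with the previous hidden state.
# Forward passes return caches so the analytic backward passes used by
# training can run without an autograd framework.

#' Construct encoder parameters
#'
#' Initialises all learnable weights for one graph branch: three conv
#' layer weight matrices (plus attention vectors for GAT), gate matrices
#' `U1`, `U2` and bias `b` for layers 2-3 when the gated skip-connection is
#' enabled, and the two projection layers down to `out_dim`.
#'
#' @param input_dim node feature width N (78 atoms, 92 motifs, 33
#'   residues).
#' @param conv `"gcn"` or `"gat"`.
#' @param pooling `"max"` or `"mean"` graph-level readout.
#' @param use_skip enable the gated skip-connection (disable for the
#'   no-skip ablation; the gate parameters are then not created).
#' @param n_heads GAT attention heads (heads share the linear map and are
#'   averaged; default 1).
#' @param hidden_mult hidden width multiplier (4 per the published sizing).
#' @param proj_dim width of the first projection stage.
#' @param out_dim embedding width (128).
#' @param dropout dropout rate applied after each projection stage during
#'   training.
#' @param seed optional seed for reproducible initialisation.
#' @return object of class `encoder_params`.
#' @export
encoder_params <- function(input_dim, conv = c("gcn", "gat"),
                           pooling = c("max", "mean"), use_skip = TRUE,
                           n_heads = 1, hidden_mult = 4, proj_dim = 256,
                           out_dim = 128, dropout = 0.2, seed = NULL) {
  conv <- match.arg(conv)
  pooling <- match.arg(pooling)
  if (!is.null(seed)) set.seed(seed)
  H <- input_dim * hidden_mult
  p <- list(
    input_dim = input_dim, hidden = H, conv = conv, pooling = pooling,
    use_skip = use_skip, n_heads = n_heads, dropout = dropout,
    out_dim = out_dim,
    W = list(glorot(input_dim, H), glorot(H, H), glorot(H, H)),
    Wp1 = glorot(H, proj_dim), bp1 = numeric(proj_dim),
    Wp2 = glorot(proj_dim, out_dim), bp2 = numeric(out_dim)
  )
  if (conv == "gat") {
    p$a <- lapply(1:3, function(l)
      lapply(seq_len(n_heads), function(h)
        list(a1 = stats::runif(H, -0.1, 0.1),
             a2 = stats::runif(H, -0.1, 0.1))))
  }
  if (use_skip) {
    p$U1 <- list(NULL, glorot(H, H), glorot(H, H))
    p$U2 <- list(NULL, glorot(H, H), glorot(H, H))
    p$bg <- list(NULL, numeric(H), numeric(H))
  }
  structure(p, class = "encoder_params")
}

# Symmetrically normalised adjacency with self-loops (weight 1), optional
# edge weights on the off-diagonal entries.
norm_adjacency <- function(n, edges, weights = NULL) {
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  x <- c(weights, weights, rep(1, n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  dh <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dh) %*% A %*% Matrix::Diagonal(x = dh)
}

#' One GCN propagation step
#'
#' `H' = ReLU(D^-1/2 (A + I) D^-1/2 H W)`; optional edge weights populate
#' the adjacency (the weighted protein graph), self-loops carry weight 1.
#'
#' @param H node features (n x F).
#' @param edges two-column matrix of unordered node index pairs.
#' @param W weight matrix (F x F').
#' @param n number of nodes (defaults to `nrow(H)`).
#' @param weights optional per-edge weights.
#' @return n x F' matrix.
#' @export
gcn_layer <- function(H, edges, W, n = nrow(H), weights = NULL) {
  if (ncol(H) != nrow(W)) {
    stop_mgdta("gcn_layer: feature width ", ncol(H),
               " does not match weight matrix rows ", nrow(W))
  }
  S <- norm_adjacency(n, edges, weights)
  relu(as.matrix(S %*% (H %*% W)))
}

# Directed edge list with self-loops for attention: receiver ei, sender ej.
.gat_edge_index <- function(n, edges) {
  if (is.null(edges) || nrow(edges) == 0) {
    list(ei = seq_len(n), ej = seq_len(n))
  } else {
    list(ei = c(edges[, 1], edges[, 2], seq_len(n)),
         ej = c(edges[, 2], edges[, 1], seq_len(n)))
  }
}

.gat_forward <- function(H, edges, W, heads, n = nrow(H), slope = 0.2) {
  G <- H %*% W
  idx <- .gat_edge_index(n, edges)
  ei <- idx$ei; ej <- idx$ej
  M <- matrix(0, n, ncol(G))
  hcache <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    a1 <- heads[[h]]$a1; a2 <- heads[[h]]$a2
    s <- as.vector(G %*% a1)
    t <- as.vector(G %*% a2)
    epre <- s[ei] + t[ej]
    eact <- ifelse(epre > 0, epre, slope * epre)
    mx <- as.vector(tapply(eact, ei, max))[ei]
    ex <- exp(eact - mx)
    denom <- rowsum(ex, ei)[, 1]
    alpha <- ex / denom[ei]
    Aal <- Matrix::sparseMatrix(i = ei, j = ej, x = alpha, dims = c(n, n))
    Mh <- as.matrix(Aal %*% G)
    M <- M + Mh / length(heads)
    hcache[[h]] <- list(alpha = alpha, epre = epre, Aal = Aal)
  }
  out <- relu(M)
  list(out = out, cache = list(H = H, G = G, M = M, ei = ei, ej = ej,
                               heads = hcache, W = W, slope = slope))
}

.gat_backward <- function(dout, cache, heads) {
  G <- cache$G
  ei <- cache$ei
  ej <- cache$ej
  dM <- dout * (cache$M > 0)
  n_heads <- length(heads)
  dG <- matrix(0, nrow(G), ncol(G))
  da <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    hc <- cache$heads[[h]]
    dMh <- dM / n_heads
    dG_msg <- as.matrix(Matrix::t(hc$Aal) %*% dMh)
    dalpha <- rowSums(dMh[ei, , drop = FALSE] * G[ej, , drop = FALSE])
    sdot <- rowsum(hc$alpha * dalpha, ei)[, 1]
    de <- hc$alpha * (dalpha - sdot[ei])
    depre <- de * ifelse(hc$epre > 0, 1, cache$slope)
    ds <- rowsum(depre, ei)[, 1]
    dt <- rowsum(depre, ej)[, 1]
    da[[h]] <- list(a1 = as.vector(crossprod(G, ds)),
                    a2 = as.vector(crossprod(G, dt)))
    dG <- dG + dG_msg + outer(ds, heads[[h]]$a1) + outer(dt, heads[[h]]$a2)
  }
  list(dH = tcrossprod(dG, cache$W),
       dW = crossprod(cache$H, dG),
       da = da)
}

#' One GAT propagation step
#'
#' Attention logits `e_ij = a . [W x_i || W x_j]` pass through LeakyReLU
#' (slope 0.2) and a per-neighbourhood softmax; messages `W x_j` are
#' aggregated with the attention weights and pass through ReLU.
#' Neighbourhoods include the node itself, so isolated nodes never face an
#' empty softmax. Edge weights are ignored (attention replaces them).
#'
#' @inheritParams gcn_layer
#' @param a attention parameters: either `list(a1 =, a2 =)` (vectors of
#'   length F') for one head, or a list of such heads (averaged).
#' @return n x F' matrix.
#' @export
gat_layer <- function(H, edges, W, a, n = nrow(H)) {
  if (ncol(H) != nrow(W)) {
    stop_mgdta("gat_layer: feature width ", ncol(H),
               " does not match weight matrix rows ", nrow(W))
  }
  heads <- if (!is.null(a$a1)) list(a) else a
  .gat_forward(H, edges, W, heads, n)$out
}

#' Attention weights of a GAT step
#'
#' Returns the directed edge list (receiver, sender, including self-loops)
#' and the normalised attention coefficient on each, for inspection and
#' testing; rows of the implied attention matrix sum to 1.
#'
#' @inheritParams gat_layer
#' @return data.frame with columns `i` (receiver), `j` (sender), `alpha`.
#' @export
gat_attention <- function(H, edges, W, a, n = nrow(H)) {
  heads <- if (!is.null(a$a1)) list(a) else a
  fw <- .gat_forward(H, edges, W, heads, n)
  al <- Reduce(`+`, lapply(fw$cache$heads, `[[`, "alpha")) / length(heads)
  data.frame(i = fw$cache$ei, j = fw$cache$ej, alpha = al)
}

#' Gated skip-connection
#'
#' `z = sigmoid(H_new U1 + H_old U2 + b)`, output
#' `z * H_new + (1 - z) * H_old`: a per-node, per-feature convex
#' combination of the new and previous hidden states, so depth can grow
#' without washing out earlier-scale features.
#'
#' @param H_new,H_old equal-shape feature matrices.
#' @param U1,U2 square gate matrices (F x F).
#' @param b gate bias (length F).
#' @return matrix of the same shape as the inputs.
#' @export
gated_skip <- function(H_new, H_old, U1, U2, b) {
  if (!identical(dim(H_new), dim(H_old))) {
    stop_mgdta("gated_skip: H_new and H_old must have identical shapes")
  }
  z <- sigmoid(sweep(H_new %*% U1 + H_old %*% U2, 2, b, `+`))
  z * H_new + (1 - z) * H_old
}

.gate_forward <- function(H_new, H_old, U1, U2, b) {
  pre <- sweep(H_new %*% U1 + H_old %*% U2, 2, b, `+`)
  z <- sigmoid(pre)
  list(out = z * H_new + (1 - z) * H_old,
       cache = list(H_new = H_new, H_old = H_old, z = z, U1 = U1, U2 = U2))
}

.gate_backward <- function(dout, cache) {
  with(cache, {
    dz <- dout * (H_new - H_old)
    dpre <- dz * z * (1 - z)
    list(dH_new = dout * z + tcrossprod(dpre, U1),
         dH_old = dout * (1 - z) + tcrossprod(dpre, U2),
         dU1 = crossprod(H_new, dpre),
         dU2 = crossprod(H_old, dpre),
         db = colSums(dpre))
  })
}

# Stack several graphs into one block-diagonal batch (standard GNN
# batching: disjoint union of the graphs, with a membership index).
.batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n_nodes, numeric(1))
  offs <- cumsum(c(0, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (is.null(e) || nrow(e) == 0) matrix(integer(0), 0, 2)
    else e + offs[i]
  }))
  has_w <- vapply(graphs, function(g) !is.null(g$edge_weights), logical(1))
  weights <- if (any(has_w)) {
    unlist(lapply(graphs, function(g)
      g$edge_weights %||% rep(1, nrow(g$edges %||% matrix(0, 0, 2)))))
  } else NULL
  list(X = X, edges = edges, weights = weights,
       gid = rep(seq_along(graphs), ns), n_graphs = length(graphs))
}

# Full encoder forward with cache; operates on a (possibly batched) graph.
# `gid` maps each node to its graph; the output has one row per graph.
# `training` turns on inverted dropout (masks from the current RNG
# stream).
.encoder_forward <- function(X, edges, edge_weights, params,
                             training = FALSE, gid = NULL) {
  n <- nrow(X)
  if (is.null(n) || n < 1) stop_mgdta("cannot encode an empty graph")
  if (ncol(X) != params$input_dim) {
    stop_mgdta("graph feature width ", ncol(X),
               " does not match encoder input_dim ", params$input_dim)
  }
  if (is.null(gid)) gid <- rep(1L, n)
  ng <- max(gid)
  use_w <- !is.null(edge_weights) && params$conv == "gcn"
  S <- if (params$conv == "gcn") {
    norm_adjacency(n, edges, if (use_w) edge_weights else NULL)
  } else NULL

  layers <- vector("list", 3)
  Hprev <- X
  for (l in 1:3) {
    if (params$conv == "gcn") {
      Z <- as.matrix(S %*% (Hprev %*% params$W[[l]]))
      Hl <- relu(Z)
      lc <- list(type = "gcn", Hin = Hprev, Z = Z)
    } else {
      fw <- .gat_forward(Hprev, edges, params$W[[l]], params$a[[l]], n)
      Hl <- fw$out
      lc <- list(type = "gat", cache = fw$cache)
    }
    if (l >= 2 && params$use_skip) {
      gf <- .gate_forward(Hl, Hprev, params$U1[[l]], params$U2[[l]],
                          params$bg[[l]])
      lc$gate <- gf$cache
      Hl <- gf$out
    }
    lc$out <- Hl
    layers[[l]] <- lc
    Hprev <- Hl
  }

  H3 <- Hprev
  if (params$pooling == "max") {
    amax <- matrix(0L, ng, ncol(H3))
    G <- matrix(0, ng, ncol(H3))
    rows <- split(seq_len(n), gid)
    for (g_i in seq_len(ng)) {
      r <- rows[[g_i]]
      a <- r[apply(H3[r, , drop = FALSE], 2, which.max)]
      amax[g_i, ] <- a
      G[g_i, ] <- H3[cbind(a, seq_len(ncol(H3)))]
    }
  } else {
    amax <- NULL
    G <- rowsum(H3, gid) / as.vector(table(gid))
  }

  keep <- 1 - params$dropout
  m1 <- if (training) {
    matrix((stats::runif(ng * ncol(params$Wp1)) < keep) / keep, ng)
  } else 1
  f1pre <- sweep(G %*% params$Wp1, 2, params$bp1, `+`)
  f1 <- relu(f1pre) * m1
  m2 <- if (training) {
    matrix((stats::runif(ng * params$out_dim) < keep) / keep, ng)
  } else 1
  out <- sweep(f1 %*% params$Wp2, 2, params$bp2, `+`) * m2

  list(out = if (ng == 1) as.vector(out) else out,
       cache = list(n = n, ng = ng, gid = gid, S = S, layers = layers,
                    H3 = H3, amax = amax, G = G, f1pre = f1pre, f1 = f1,
                    m1 = m1, m2 = m2))
}

# Backward through the encoder; `dout` has one row per graph (or a vector
# for a single graph). Returns parameter gradients shaped like `params`
# (learnable fields only).
.encoder_backward <- function(dout, cache, params) {
  g <- list(W = vector("list", 3))
  if (params$conv == "gat") g$a <- vector("list", 3)
  if (params$use_skip) {
    g$U1 <- vector("list", 3); g$U2 <- vector("list", 3)
    g$bg <- vector("list", 3)
  }
  if (!is.matrix(dout)) dout <- matrix(dout, nrow = cache$ng)

  dout <- dout * cache$m2
  g$Wp2 <- crossprod(cache$f1, dout)
  g$bp2 <- colSums(dout)
  df1 <- tcrossprod(dout, params$Wp2) * cache$m1
  df1pre <- df1 * (cache$f1pre > 0)
  g$Wp1 <- crossprod(cache$G, df1pre)
  g$bp1 <- colSums(df1pre)
  dG <- tcrossprod(df1pre, params$Wp1)

  n <- cache$n
  nc <- ncol(dG)
  if (params$pooling == "max") {
    dH <- matrix(0, n, nc)
    for (g_i in seq_len(cache$ng)) {
      idx <- cbind(cache$amax[g_i, ], seq_len(nc))
      dH[idx] <- dH[idx] + dG[g_i, ]
    }
  } else {
    counts <- as.vector(table(cache$gid))
    dH <- (dG / counts)[cache$gid, , drop = FALSE]
  }

  for (l in 3:1) {
    lc <- cache$layers[[l]]
    if (l >= 2 && params$use_skip) {
      gb <- .gate_backward(dH, lc$gate)
      g$U1[[l]] <- gb$dU1; g$U2[[l]] <- gb$dU2; g$bg[[l]] <- gb$db
      dH_layer <- gb$dH_new
      dH_skip <- gb$dH_old
    } else {
      dH_layer <- dH
      dH_skip <- 0
    }
    if (lc$type == "gcn") {
      dZ <- dH_layer * (lc$Z > 0)
      P <- as.matrix(cache$S %*% dZ)
      g$W[[l]] <- crossprod(lc$Hin, P)
      dH <- tcrossprod(P, params$W[[l]]) + dH_skip
    } else {
      gb <- .gat_backward(dH_layer, lc$cache, params$a[[l]])
      g$W[[l]] <- gb$dW
      g$a[[l]] <- gb$da
      dH <- gb$dH + dH_skip
    }
  }
  g
}

#' Encode a graph into a 128-dimensional embedding
#'
#' Runs the three conv layers (gated skip-connection from layer 2 on,
#' unless disabled), pools node features to a graph-level vector (max or
#' mean), and projects through two fully connected stages (dropout active
#' only when `training = TRUE`) to the embedding.
#'
#' @param graph an `atom_graph`, `motif_graph` or `protein_graph` (the
#'   protein graph's edge weights are consumed by GCN and ignored by GAT).
#' @param params matching [encoder_params()].
#' @param training logical; enables dropout.
#' @return numeric vector of length `params$out_dim` (128).
#' @export
encode <- function(graph, params, training = FALSE) {
  .encoder_forward(graph$node_features, graph$edges, graph$edge_weights,
                   params, training)$out
}
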