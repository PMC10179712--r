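test_that("gcn_layer matches hand-computed normalised propagation", {
  # single node, no edges, identity weights: A~ = D~ = [1], H' = relu(x)
  x <- matrix(c(-1, 2, 0.5), 1, 3)
  out <- gcn_layer(x, matrix(integer(0), 0, 2), diag(3))
  expect_equal(out, matrix(c(0, 2, 0.5), 1, 3), ignore_attr = TRUE)

  # two nodes, one edge, unit features: D~^-1/2 A~ D~^-1/2 = [[.5,.5],[.5,.5]]
  H <- matrix(1, 2, 2)
  out2 <- gcn_layer(H, cbind(1L, 2L), diag(2))
  expect_equal(out2, matrix(1, 2, 2), ignore_attr = TRUE)

  # distinct features, hand arithmetic on the 2x2 normalisation
  H3 <- matrix(c(1, 3, 2, 4), 2, 2)
  out3 <- gcn_layer(H3, cbind(1L, 2L), diag(2))
  expect_equal(out3, 0.5 * rbind(colSums(H3), colSums(H3)),
               ignore_attr = TRUE)
})

test_that("gcn_layer is permutation-equivariant", {
  set.seed(7)
  H <- matrix(rnorm(5 * 4), 5, 4)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(1L, 5L))
  W <- matrix(rnorm(4 * 4), 4, 4)
  out <- gcn_layer(H, edges, W)
  perm <- sample(5)
  inv <- order(perm)
  pe <- cbind(pmin(inv[edges[, 1]], inv[edges[, 2]]),
              pmax(inv[edges[, 1]], inv[edges[, 2]]))
  out_p <- gcn_layer(H[perm, ], pe, W)
  expect_equal(out_p, out[perm, ])
})

test_that("edge weights change gcn propagation; unit weights recover it", {
  set.seed(8)
  H <- matrix(rnorm(4 * 3), 4, 3)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  W <- matrix(rnorm(9), 3, 3)
  unweighted <- gcn_layer(H, edges, W)
  weighted_units <- gcn_layer(H, edges, W, weights = c(1, 1, 1))
  expect_equal(weighted_units, unweighted)
  weighted <- gcn_layer(H, edges, W, weights = c(2, 1, 1))
  expect_false(isTRUE(all.equal(weighted, unweighted)))
})

test_that("gat attention rows sum to one and match a brute-force softmax", {
  set.seed(9)
  H <- matrix(rnorm(3 * 4), 3, 4)   # 3-node path graph
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  W <- matrix(rnorm(4 * 4), 4, 4)
  a <- list(a1 = rnorm(4), a2 = rnorm(4))
  att <- gat_attention(H, edges, W, a)
  sums <- tapply(att$alpha, att$i, sum)
  expect_equal(unname(as.vector(sums)), rep(1, 3), tolerance = 1e-12)

  # independent evaluation of the attention equations for node 2
  G <- H %*% W
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  e2 <- vapply(c(1, 2, 3), function(j)
    lrelu(sum(a$a1 * G[2, ]) + sum(a$a2 * G[j, ])), numeric(1))
  want <- exp(e2 - max(e2)) / sum(exp(e2 - max(e2)))
  got <- att$alpha[att$i == 2][order(att$j[att$i == 2])]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("zero attention vectors give uniform neighbourhood weights", {
  set.seed(10)
  H <- matrix(rnorm(4 * 3), 4, 3)
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  att <- gat_attention(H, edges, matrix(rnorm(9), 3, 3),
                       list(a1 = numeric(3), a2 = numeric(3)))
  # node 1 has neighbourhood {1,2,3,4} (self included): uniform 1/4
  expect_equal(att$alpha[att$i == 1], rep(0.25, 4))
  # isolated-free: every node has at least its self-loop
  expect_true(all(seq_len(4) %in% att$i))
})

test_that("gated_skip interpolates and stays within elementwise bounds", {
  set.seed(11)
  Hn <- matrix(rnorm(12), 4, 3)
  Ho <- matrix(rnorm(12), 4, 3)
  # zero gate parameters: z = 0.5 everywhere, output is the mean
  out0 <- gated_skip(Hn, Ho, matrix(0, 3, 3), matrix(0, 3, 3),
                     numeric(3))
  expect_equal(out0, (Hn + Ho) / 2)
  # large positive bias saturates the gate towards H_new
  outb <- gated_skip(Hn, Ho, matrix(0, 3, 3), matrix(0, 3, 3),
                     rep(50, 3))
  expect_equal(outb, Hn, tolerance = 1e-12)
  # random gates: convex combination stays within the input envelope
  for (k in 1:20) {
    U1 <- matrix(rnorm(9), 3, 3)
    U2 <- matrix(rnorm(9), 3, 3)
    b <- rnorm(3)
    out <- gated_skip(Hn, Ho, U1, U2, b)
    expect_true(all(out <= pmax(Hn, Ho) + 1e-12))
    expect_true(all(out >= pmin(Hn, Ho) - 1e-12))
  }
  expect_error(gated_skip(Hn, Ho[1:3, ], U1, U2, b), "identical shapes")
})

test_that("encode produces a deterministic 128-dim embedding", {
  g <- build_atom_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  for (conv in c("gcn", "gat")) {
    for (pool in c("max", "mean")) {
      p <- encoder_params(78, conv = conv, pooling = pool, seed = 3)
      z1 <- encode(g, p)
      z2 <- encode(g, p)
      expect_length(z1, 128)
      expect_identical(z1, z2)
    }
  }
})

test_that("encode is invariant under node relabeling", {
  set.seed(12)
  g <- build_atom_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  perm <- sample(g$n_nodes)
  gp <- permute_graph(g, perm)
  for (conv in c("gcn", "gat")) {
    p <- encoder_params(78, conv = conv, seed = 4)
    expect_equal(encode(gp, p), encode(g, p), tolerance = 1e-12,
                 info = conv)
  }
})

test_that("disabling the gated skip-connection changes the encoding", {
  g <- build_atom_graph("Cc1ccc(N)cc1")
  with_skip <- encoder_params(78, use_skip = TRUE, seed = 5)
  no_skip <- encoder_params(78, use_skip = FALSE, seed = 5)
  expect_false(isTRUE(all.equal(encode(g, with_skip),
                                encode(g, no_skip))))
  expect_error(encode(list(node_features = matrix(numeric(0), 0, 78),
                           edges = NULL), with_skip), "empty graph")
})

test_that("batched encoding equals one-at-a-time encoding", {
  graphs <- lapply(c("CCO", "c1ccccc1", "CC(C)CC"), build_atom_graph)
  p <- encoder_params(78, seed = 6)
  bg <- mgdta:::.batch_graphs(graphs)
  out <- mgdta:::.encoder_forward(bg$X, bg$edges, bg$weights, p,
                                  gid = bg$gid)$out
  for (i in seq_along(graphs)) {
    expect_equal(out[i, ], encode(graphs[[i]], p), tolerance = 1e-12)
  }
})

test_that("analytic encoder gradients match finite differences", {
  set.seed(13)
  for (conv in c("gcn", "gat")) {
    p <- encoder_params(5, conv = conv, pooling = "mean", proj_dim = 12,
                        out_dim = 4, dropout = 0, n_heads = 1, seed = 13)
    X <- matrix(rnorm(4 * 5), 4, 5)
    edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
    wvec <- c(0.8, 0.6, 0.9)
    loss <- function(pp) {
      sum(mgdta:::.encoder_forward(X, edges, wvec, pp, FALSE)$out *
            c(1, -2, 0.5, 1.5))
    }
    fw <- mgdta:::.encoder_forward(X, edges, wvec, p, FALSE)
    g <- mgdta:::.encoder_backward(c(1, -2, 0.5, 1.5), fw$cache, p)
    num_grad <- function(get, set) {
      v <- get(p)
      out <- v * 0
      for (k in seq_along(v)) {
        vp <- v; vp[k] <- vp[k] + 1e-6
        vm <- v; vm[k] <- vm[k] - 1e-6
        out[k] <- (loss(set(p, vp)) - loss(set(p, vm))) / 2e-6
      }
      out
    }
    for (l in 1:3) {
      num <- num_grad(function(pp) pp$W[[l]],
                      function(pp, v) {pp$W[[l]] <- v; pp})
      expect_equal(g$W[[l]], num, tolerance = 1e-5,
                   ignore_attr = TRUE, info = paste(conv, "W", l))
    }
    num <- num_grad(function(pp) pp$U1[[2]],
                    function(pp, v) {pp$U1[[2]] <- v; pp})
    expect_equal(g$U1[[2]], num, tolerance = 1e-5, ignore_attr = TRUE)
    num <- num_grad(function(pp) pp$Wp1,
                    function(pp, v) {pp$Wp1 <- v; pp})
    expect_equal(g$Wp1, num, tolerance = 1e-5, ignore_attr = TRUE)
    if (conv == "gat") {
      num <- num_grad(function(pp) pp$a[[2]][[1]]$a1,
                      function(pp, v) {pp$a[[2]][[1]]$a1 <- v; pp})
      expect_equal(g$a[[2]][[1]]$a1, num, tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
})
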