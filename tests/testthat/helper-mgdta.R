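# Shared fixtures and independent oracles for the test suite.

# Relabel a graph's nodes by a permutation (new index = inv[old index]);
# used for permutation-invariance checks.
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  out <- graph
  out$node_features <- graph$node_features[perm, , drop = FALSE]
  if (!is.null(graph$edges) && nrow(graph$edges)) {
    a <- inv[graph$edges[, 1]]
    b <- inv[graph$edges[, 2]]
    out$edges <- cbind(pmin(a, b), pmax(a, b))
  }
  out
}

# Brute-force concordance index: explicit double loop over ordered pairs.
ci_bruteforce <- function(y, p) {
  num <- 0
  z <- 0
  n <- length(y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y[i] > y[j]) {
        z <- z + 1
        num <- num + if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0
      }
    }
  }
  num / z
}

# Brute-force paste-and-average splicing oracle: paints every window's
# prediction into an accumulator and divides by the coverage count.
splice_bruteforce <- function(seq_str, predictor, windowsize = 500) {
  len <- nchar(seq_str)
  win <- splice_windows(len, windowsize)
  acc <- matrix(0, len, len)
  cnt <- matrix(0, len, len)
  for (k in seq_len(nrow(win))) {
    i <- win$start[k]:win$end[k]
    m <- predictor(substr(seq_str, win$start[k], win$end[k]))
    acc[i, i] <- acc[i, i] + (m + t(m)) / 2
    cnt[i, i] <- cnt[i, i] + 1
  }
  out <- acc / pmax(cnt, 1)
  out
}

random_aa_seq <- function(n) {
  paste(sample(residue_alphabet()[1:20], n, replace = TRUE), collapse = "")
}

# Small scaled-down synthetic problem used by the learnability tests
# (short proteins keep one-CPU training in the minutes range; the
# generator default length range straddles 1000 for splice tests).
small_synth_config <- function(noise_sd, seed) {
  synthetic_config(seq_len_range = c(40, 120), noise_sd = noise_sd,
                   seed = seed)
}

# Mean concordance of fixed predictions against permuted labels: the
# permutation null for CI (expectation exactly 0.5 for tie-free inputs).
permuted_ci <- function(y, p, n_perm = 200, seed = 1) {
  set.seed(seed)
  mean(vapply(seq_len(n_perm), function(k)
    concordance_index(sample(y), p), numeric(1)))
}
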