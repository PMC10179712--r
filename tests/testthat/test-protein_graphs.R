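test_that("residue features have the published 33-dim layout", {
  tab <- residue_property_table()
  for (aa in c("A", "G", "W", "X", "U")) {
    v <- featurize_residue(aa, tab)
    expect_length(v, 33)
    expect_equal(sum(v[1:25]), 1)            # one-hot block
    expect_true(all(v[26:30] %in% c(0, 1)))  # class flags
    expect_true(all(v[31:33] >= 0 & v[31:33] <= 1))  # rescaled scalars
  }
  expect_false(identical(featurize_residue("G"), featurize_residue("A")))
  expect_error(featurize_residue("J"), "unknown amino-acid")
})

test_that("featurize_sequence stacks per-residue vectors", {
  m <- featurize_sequence("ACDG")
  expect_equal(dim(m), c(4, 33))
  expect_equal(m[2, ], featurize_residue("C"))
  expect_error(featurize_sequence("ACJ"), "alphabet")
})

test_that("short sequences bypass splicing entirely", {
  set.seed(1)
  s <- random_aa_seq(800)
  pred <- stub_contact_predictor("hash")
  cm <- splice_contact_map(s, pred)
  expect_equal(cm$matrix, pred(s))
})

test_that("constant predictors splice to a constant within the band", {
  s <- random_aa_seq(1500)
  cm <- splice_contact_map(s, stub_contact_predictor("constant",
                                                     value = 0.7))
  d <- abs(outer(1:1500, 1:1500, `-`))
  covered <- cm$matrix[d < 500]
  expect_true(all(covered == 0.7))   # overlap average of 0.7 and 0.7
  expect_true(all(cm$matrix[d >= 1000] == 0))
})

test_that("spliced maps equal the brute-force paste-and-average oracle", {
  pred <- stub_contact_predictor("hash")
  set.seed(42)
  for (len in c(1001, 1200, 1777, 2499)) {
    s <- random_aa_seq(len)
    got <- splice_contact_map(s, pred)
    want <- splice_bruteforce(s, pred)
    expect_equal(got$matrix, want, info = paste("len", len))
    expect_equal(got$matrix, t(got$matrix))
  }
})

test_that("every near-diagonal pair is covered by some window", {
  ws <- 500
  for (len in 1001:4000) {
    win <- splice_windows(len, ws)
    expect_true(all(win$end - win$start + 1 == 2 * ws))
    expect_true(all(win$start >= 1) && all(win$end <= len))
    # a pair (i, j) with |i - j| < ws is covered iff some window holds
    # both ends; with starts stepping by ws and a tail window anchored at
    # len - 2ws, consecutive starts differ by at most ws
    starts <- win$start
    expect_true(max(diff(c(starts, len - 2 * ws + 1))) <= ws)
    expect_equal(win$end[nrow(win)], len)
  }
})

test_that("predictor contract violations are rejected", {
  s <- random_aa_seq(50)
  bad_shape <- function(seq) matrix(0.5, 3, 3)
  expect_error(splice_contact_map(s, bad_shape), "contract violation")
  bad_range <- function(seq) {
    n <- nchar(seq)
    matrix(1.5, n, n)
  }
  expect_error(splice_contact_map(s, bad_range), "contract violation")
  expect_error(splice_contact_map("ACDJ", stub_contact_predictor()),
               "alphabet")
})

test_that("thresholding keeps exactly the >= 0.5 upper-triangle entries", {
  zero <- structure(list(matrix = matrix(0, 10, 10),
                         sequence = random_aa_seq(10)),
                    class = "contact_map")
  g0 <- threshold_graph(zero)
  expect_equal(g0$n_nodes, 10)
  expect_equal(nrow(g0$edges), 0)

  m <- matrix(0, 8, 8)
  m[2, 5] <- m[5, 2] <- 0.7
  one <- structure(list(matrix = m, sequence = random_aa_seq(8)),
                   class = "contact_map")
  g1 <- threshold_graph(one)
  expect_equal(g1$edges, cbind(2L, 5L), ignore_attr = TRUE)
  expect_equal(g1$edge_weights, 0.7)

  set.seed(3)
  r <- matrix(runif(30 * 30), 30, 30)
  r <- (r + t(r)) / 2
  cm <- structure(list(matrix = r, sequence = random_aa_seq(30)),
                  class = "contact_map")
  g <- threshold_graph(cm)
  expect_equal(nrow(g$edges), sum(r[upper.tri(r)] >= 0.5))
  expect_true(all(g$edge_weights >= 0.5))
  expect_equal(dim(g$node_features), c(30, 33))
})

test_that("raising the threshold never adds edges", {
  set.seed(4)
  r <- matrix(runif(25 * 25), 25, 25)
  r <- (r + t(r)) / 2
  cm <- structure(list(matrix = r, sequence = random_aa_seq(25)),
                  class = "contact_map")
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    nrow(threshold_graph(cm, threshold = th)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contact maps round-trip through the dense TSV format", {
  s <- random_aa_seq(12)
  cm <- splice_contact_map(s, stub_contact_predictor("banded"))
  path <- tempfile(fileext = ".tsv")
  write_contact_map(cm, path)
  back <- read_contact_map(path)
  expect_equal(back$sequence, s)
  expect_equal(back$matrix, cm$matrix, tolerance = 1e-12)
})

test_that("FASTA sequences are read back verbatim", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEFG", ">p2", "MKLVWY"), path)
  got <- read_fasta_sequences(path)
  expect_equal(got, c(p1 = "ACDEFG", p2 = "MKLVWY"))
})
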