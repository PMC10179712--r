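vocab <- feature_vocabulary()

test_that("atom graphs match independently known atom and bond counts", {
  # expected values frozen from an independent SMILES parser (RDKit)
  cases <- list(
    list(smiles = "C", nodes = 1, edges = 0),            # methane
    list(smiles = "c1ccccc1", nodes = 6, edges = 6),     # benzene
    list(smiles = "CC(=O)OC1=CC=CC=C1C(=O)O",            # aspirin
         nodes = 13, edges = 13),
    list(smiles = "CC", nodes = 2, edges = 1),
    list(smiles = "C1CCCCC1", nodes = 6, edges = 6)
  )
  for (cs in cases) {
    g <- build_atom_graph(cs$smiles, vocab)
    expect_equal(g$n_nodes, cs$nodes, info = cs$smiles)
    expect_equal(nrow(g$edges), cs$edges, info = cs$smiles)
    expect_equal(dim(g$node_features), c(cs$nodes, 78))
  }
})

test_that("benzene atoms are aromatic carbons with the expected one-hots", {
  g <- build_atom_graph("c1ccccc1", vocab)
  # aromatic flag is the last column
  expect_equal(g$node_features[, 78], rep(1, 6))
  # symbol one-hot: carbon is slot 1
  expect_equal(g$node_features[, 1], rep(1, 6))
  # degree one-hot at 2 (block offset 44, bins 0..10)
  expect_equal(g$node_features[, 44 + 3], rep(1, 6))
})

test_that("atom feature rows sum to 4 (non-aromatic) or 5 (aromatic)", {
  for (smi in c("C", "CCO", "c1ccccc1", "CC(=O)OC1=CC=CC=C1C(=O)O",
                "C[N+](C)(C)C", "CC(=O)[O-]", "c1cc[nH]c1")) {
    g <- build_atom_graph(smi, vocab)
    sums <- rowSums(g$node_features)
    arom <- g$node_features[, 78]
    expect_equal(sums, 4 + arom, info = smi)
  }
})

test_that("featurize_atom clamps counts and maps unknown symbols", {
  v <- featurize_atom("Xx", degree = 25, n_h = 99, implicit_valence = 12,
                      aromatic = FALSE, vocab)
  expect_length(v, 78)
  expect_equal(v[44], 1)            # unknown slot
  expect_equal(v[44 + 11], 1)       # degree clamped to last bin (10)
  expect_equal(v[44 + 22], 1)       # H count clamped
  expect_equal(v[44 + 33], 1)       # valence clamped
  # methane carbon: one active entry per block, no aromatic flag
  vm <- featurize_atom("C", 0, 4, 4, FALSE, vocab)
  expect_equal(sum(vm), 4)
})

test_that("motif decomposition follows ring / non-ring bond structure", {
  m_benzene <- decompose_motifs("c1ccccc1")
  expect_length(m_benzene, 1)
  expect_equal(m_benzene[[1]]$kind, "ring")
  expect_length(m_benzene[[1]]$atoms, 6)

  m_ethane <- decompose_motifs("CC")
  expect_length(m_ethane, 1)
  expect_equal(m_ethane[[1]]$kind, "bond")
  expect_length(m_ethane[[1]]$atoms, 2)

  m_toluene <- decompose_motifs("Cc1ccccc1")
  expect_equal(sort(vapply(m_toluene, `[[`, character(1), "kind")),
               c("bond", "ring"))
})

test_that("motifs cover every bond exactly once (rings own their fusion bonds)", {
  for (smi in c("Cc1ccccc1", "CC(=O)OC1=CC=CC=C1C(=O)O",
                "c1ccc2ccccc2c1", "CCOC1CCNCC1", "CCC")) {
    mol <- parse_smiles(smi)
    motifs <- decompose_motifs(mol)
    kinds <- vapply(motifs, `[[`, character(1), "kind")
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      in_motif <- vapply(motifs, function(m) {
        if (m$kind == "ring") a %in% m$atoms && b %in% m$atoms
        else setequal(m$atoms, c(a, b))
      }, logical(1))
      # a bond lies in exactly one motif; the only multiplicity allowed
      # is a fusion bond shared by two SSSR rings
      if (sum(in_motif) != 1) {
        expect_true(all(kinds[in_motif] == "ring"),
                    info = paste(smi, "bond", k))
        expect_equal(sum(in_motif), 2, info = paste(smi, "bond", k))
      } else {
        expect_equal(sum(in_motif), 1, info = paste(smi, "bond", k))
      }
    }
    covered <- unique(unlist(lapply(motifs, `[[`, "atoms")))
    expect_setequal(covered, seq_len(nrow(mol$atoms)))
  }
})

test_that("motif graphs of known molecules have the expected topology", {
  g1 <- build_motif_graph("c1ccccc1", vocab)   # one ring, no edges
  expect_equal(g1$n_nodes, 1)
  expect_equal(nrow(g1$edges), 0)

  g2 <- build_motif_graph("Cc1ccccc1", vocab)  # ring + methyl bond unit
  expect_equal(g2$n_nodes, 2)
  expect_equal(nrow(g2$edges), 1)

  g3 <- build_motif_graph("c1ccc2ccccc2c1", vocab)  # fused naphthalene
  expect_equal(g3$n_nodes, 2)
  expect_equal(nrow(g3$edges), 1)
  expect_equal(g3$motif_kind, c("ring", "ring"))
  # fused rings are not "simple" rings (flag at column 91)
  expect_equal(g3$node_features[, 91], c(0, 0))

  expect_equal(dim(g2$node_features), c(2, 92))
})

test_that("motif features encode composition and kind", {
  g <- build_motif_graph("CC", vocab)
  v <- g$node_features[1, ]
  expect_equal(sum(v[1:44]), 1)        # only carbon present
  expect_equal(v[1], 1)
  expect_equal(v[44 + 3], 1)           # atom count 2 (bins 0..10)
  expect_equal(v[91], 0)               # not a simple ring
  expect_equal(v[92], 1)               # bond unit

  gb <- build_motif_graph("c1ccccc1", vocab)
  vb <- gb$node_features[1, ]
  expect_equal(sum(vb[1:44]), 1)
  expect_equal(vb[91], 1)
  expect_equal(vb[92], 0)
})

test_that("acyclic molecules give a motif graph isomorphic to the line graph", {
  skip_if_not_installed("igraph")
  for (smi in c("CCO", "CC(C)CC", "CCOCC", "CC(=O)NC")) {
    mol <- parse_smiles(smi)
    mg <- build_motif_graph(smi, vocab)
    expect_equal(mg$n_nodes, nrow(mol$bonds), info = smi)
    ag <- igraph::graph_from_edgelist(
      as.matrix(mol$bonds[, c("a1", "a2")]), directed = FALSE)
    lg <- igraph::make_line_graph(ag)
    mgi <- igraph::graph_from_edgelist(mg$edges, directed = FALSE)
    mgi <- igraph::add_vertices(mgi, max(0, mg$n_nodes -
                                           igraph::vcount(mgi)))
    expect_true(igraph::isomorphic(lg, mgi), info = smi)
  }
})

test_that("identical SMILES give bit-identical feature matrices", {
  g1 <- build_atom_graph("CC(=O)OC1=CC=CC=C1C(=O)O", vocab)
  g2 <- build_atom_graph("CC(=O)OC1=CC=CC=C1C(=O)O", vocab)
  expect_identical(g1$node_features, g2$node_features)
  m1 <- build_motif_graph("Cc1ccccc1", vocab)
  m2 <- build_motif_graph("Cc1ccccc1", vocab)
  expect_identical(m1$node_features, m2$node_features)
})

test_that("unparseable SMILES fail with an error naming the input", {
  expect_error(build_atom_graph("not-a-smiles(("), "not-a-smiles")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("[H][H]"), "heavy atom")
})

test_that("graphs serialize to JSON with nodes, edges and features", {
  g <- build_atom_graph("CCO", vocab)
  js <- jsonlite::fromJSON(graph_to_json(g))
  expect_equal(js$n_nodes, 3)
  expect_equal(js$type, "atom_graph")
  expect_equal(dim(js$node_features), c(3, 78))
})
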