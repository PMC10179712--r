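# Atom-level and motif-level drug graphs.
#
# The atom graph has one node per heavy atom (78-dim features) and one edge
# per chemical bond. The motif graph coarsens the molecule into perceived
# rings and non-ring bonds (each with its two atoms), 92-dim features; two
# motifs are adjacent when they share an atom or a bond joins their atoms.

#' Featurize one atom (78-dim binary/ordinal vector)
#'
#' Concatenates one-hot(symbol, 44), one-hot(degree, 0..10),
#' one-hot(total hydrogens, 0..10), one-hot(implicit valence, 0..10) and a
#' 0/1 aromatic flag. Out-of-vocabulary symbols map to the "unknown" slot;
#' counts above a block's range clamp to the last bin. Total on all valid
#' atoms; rows always sum to 4 (non-aromatic) or 5 (aromatic).
#'
#' @param symbol element symbol (e.g. `"C"`).
#' @param degree number of heavy-atom neighbours.
#' @param n_h total connected hydrogens (implicit and explicit).
#' @param implicit_valence implicit valence (implicit hydrogen count).
#' @param aromatic logical aromaticity flag.
#' @param vocab a [feature_vocabulary()].
#' @return numeric vector of length 78.
#' @export
featurize_atom <- function(symbol, degree, n_h, implicit_valence, aromatic,
                           vocab = feature_vocabulary()) {
  c(one_hot(symbol, vocab$atom_symbols),
    one_hot_count(degree, vocab$degree_bins),
    one_hot_count(n_h, vocab$h_bins_atom),
    one_hot_count(implicit_valence, vocab$val_bins_atom),
    as.numeric(isTRUE(aromatic)))
}

#' Build the atom-level graph of a drug
#'
#' Nodes are heavy atoms (hydrogens are implicit and contribute only to the
#' hydrogen-count feature block), edges are chemical bonds.
#'
#' @param smiles SMILES string.
#' @param vocab a [feature_vocabulary()].
#' @return object of class `atom_graph`: `n_nodes`, `node_features`
#'   (`n_nodes` x 78 matrix), `edges` (two-column matrix of unordered index
#'   pairs, `[,1] < [,2]`), `smiles`.
#' @export
build_atom_graph <- function(smiles, vocab = feature_vocabulary()) {
  mol <- if (inherits(smiles, "molecule")) smiles else parse_smiles(smiles)
  at <- mol$atoms
  feats <- t(vapply(seq_len(nrow(at)), function(i)
    featurize_atom(at$symbol[i], at$degree[i], at$n_h[i],
                   at$implicit_valence[i], at$aromatic[i], vocab),
    numeric(vocab$atom_dim)))
  structure(list(
    n_nodes = nrow(at),
    node_features = feats,
    edges = cbind(mol$bonds$a1, mol$bonds$a2),
    smiles = mol$smiles
  ), class = "atom_graph")
}

#' Decompose a molecule into motifs
#'
#' Motifs are the building blocks of the motif-level graph: one motif per
#' perceived ring (smallest set of smallest rings; fused systems give one
#' motif per SSSR ring), and one motif per bond whose endpoints are not
#' both members of one ring, covering the bond and its two atoms. Every
#' bond belongs to exactly one motif and every bonded atom to at least one.
#' Heavy atoms with no bonds at all (single-atom molecules, bare counter
#' ions) become singleton motifs of kind `"isolated"` so coverage holds for
#' arbitrary valid input.
#'
#' @param smiles SMILES string or a parsed `molecule`.
#' @return list of motifs, each `list(atoms = <integer indices>,
#'   kind = "ring" | "bond" | "isolated")`.
#' @export
decompose_motifs <- function(smiles) {
  mol <- if (inherits(smiles, "molecule")) smiles else parse_smiles(smiles)
  motifs <- unname(lapply(mol$rings, function(r)
    list(atoms = r, kind = "ring")))
  in_same_ring <- function(a, b) {
    any(vapply(mol$rings, function(r) a %in% r && b %in% r, logical(1)))
  }
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      if (!length(mol$rings) || !in_same_ring(a, b)) {
        motifs[[length(motifs) + 1]] <- list(atoms = c(a, b), kind = "bond")
      }
    }
  }
  covered <- unique(unlist(lapply(motifs, `[[`, "atoms")))
  lone <- setdiff(seq_len(nrow(mol$atoms)), covered)
  for (a in lone) {
    motifs[[length(motifs) + 1]] <- list(atoms = a, kind = "isolated")
  }
  motifs
}

#' Featurize one motif (92-dim vector)
#'
#' Concatenates multi-hot(element symbols present, 44),
#' one-hot(atom count, 0..10), one-hot(inter-motif edge count, 0..10),
#' one-hot(total hydrogens over the motif's atoms, 0..11),
#' one-hot(summed implicit valence, 0..11), a simple-ring flag (a ring that
#' shares no atom with another ring motif) and a bond-unit flag. Counts
#' clamp to the last bin of their block.
#'
#' @param symbols character vector of element symbols present in the motif.
#' @param n_atoms number of atoms in the motif.
#' @param n_edges number of motif-graph edges incident to this motif.
#' @param total_h summed hydrogen count over the motif's atoms.
#' @param total_valence summed implicit valence over the motif's atoms.
#' @param simple_ring logical; motif is a ring not fused to another ring.
#' @param bond_unit logical; motif is a non-ring bond with its two atoms.
#' @param vocab a [feature_vocabulary()].
#' @return numeric vector of length 92.
#' @export
featurize_motif <- function(symbols, n_atoms, n_edges, total_h,
                            total_valence, simple_ring, bond_unit,
                            vocab = feature_vocabulary()) {
  multi <- numeric(length(vocab$atom_symbols))
  idx <- match(unique(symbols), vocab$atom_symbols)
  idx[is.na(idx)] <- length(vocab$atom_symbols)
  multi[unique(idx)] <- 1
  c(multi,
    one_hot_count(n_atoms, vocab$count_bins_motif),
    one_hot_count(n_edges, vocab$edge_bins_motif),
    one_hot_count(total_h, vocab$h_bins_motif),
    one_hot_count(total_valence, vocab$val_bins_motif),
    as.numeric(isTRUE(simple_ring)),
    as.numeric(isTRUE(bond_unit)))
}

#' Build the motif-level graph of a drug
#'
#' Nodes come from [decompose_motifs()]; an edge joins two motifs when
#' they share at least one atom. Because a bond linking two structural
#' units is itself a motif (covering both its endpoint atoms), units
#' connected through a chemical bond are always linked through that bond's
#' motif.
#'
#' @param smiles SMILES string.
#' @param vocab a [feature_vocabulary()].
#' @return object of class `motif_graph`: `n_nodes`, `node_features`
#'   (`n_nodes` x 92), `edges`, `motif_atoms` (list of atom-index vectors),
#'   `motif_kind` (character), `smiles`.
#' @export
build_motif_graph <- function(smiles, vocab = feature_vocabulary()) {
  mol <- if (inherits(smiles, "molecule")) smiles else parse_smiles(smiles)
  motifs <- decompose_motifs(mol)
  m <- length(motifs)
  atoms_of <- lapply(motifs, `[[`, "atoms")
  kind <- vapply(motifs, `[[`, character(1), "kind")

  # two motifs are adjacent when they share an atom; a bond linking two
  # units is itself a motif carrying both its endpoints, so bond-mediated
  # contact always surfaces as shared atoms and the motif graph of an
  # acyclic molecule is exactly the line graph of its atom graph
  edges <- matrix(integer(0), 0, 2)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (length(intersect(atoms_of[[i]], atoms_of[[j]]))) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }

  deg <- integer(m)
  if (nrow(edges)) {
    tab <- table(factor(c(edges[, 1], edges[, 2]), levels = seq_len(m)))
    deg <- as.integer(tab)
  }
  ring_ids <- which(kind == "ring")
  simple <- vapply(seq_len(m), function(i) {
    if (kind[i] != "ring") return(FALSE)
    others <- setdiff(ring_ids, i)
    !any(vapply(others, function(j)
      length(intersect(atoms_of[[i]], atoms_of[[j]])) > 0, logical(1)))
  }, logical(1))

  feats <- t(vapply(seq_len(m), function(i) {
    a <- atoms_of[[i]]
    featurize_motif(
      symbols = mol$atoms$symbol[a],
      n_atoms = length(a),
      n_edges = deg[i],
      total_h = sum(mol$atoms$n_h[a]),
      total_valence = sum(mol$atoms$implicit_valence[a]),
      simple_ring = simple[i],
      bond_unit = kind[i] == "bond",
      vocab = vocab)
  }, numeric(vocab$motif_dim)))

  structure(list(
    n_nodes = m,
    node_features = feats,
    edges = edges,
    motif_atoms = atoms_of,
    motif_kind = kind,
    smiles = mol$smiles
  ), class = "motif_graph")
}

#' @export
print.atom_graph <- function(x, ...) {
  cat("atom_graph '", x$smiles, "': ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.motif_graph <- function(x, ...) {
  cat("motif_graph '", x$smiles, "': ", x$n_nodes, " motifs (",
      sum(x$motif_kind == "ring"), " rings), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Serialize a graph to JSON
#'
#' Writes nodes, edges, features (and edge weights / motif membership where
#' present) in a documented JSON layout for external inspection.
#'
#' @param graph an `atom_graph`, `motif_graph` or `protein_graph`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return invisibly the JSON string.
#' @export
graph_to_json <- function(graph, path = NULL) {
  obj <- list(
    type = class(graph)[1],
    n_nodes = graph$n_nodes,
    node_features = graph$node_features,
    edges = graph$edges
  )
  for (f in c("edge_weights", "motif_atoms", "motif_kind", "smiles",
              "sequence")) {
    if (!is.null(graph[[f]])) obj[[f]] <- graph[[f]]
  }
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
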