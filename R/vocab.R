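#' Default atom-symbol vocabulary
#'
#' The 44-slot element vocabulary used by the atom and motif featurizers:
#' 43 explicit element symbols (common organic elements plus the metals that
#' occur in kinase-inhibitor datasets, following the GraphDTA convention)
#' and a final catch-all "unknown" slot. The ordering is fixed; it is
#' serialized with every trained model so feature layouts are reproducible.
#'
#' @return character vector of length 44, last element `"unknown"`.
#' @export
default_atom_symbols <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
    "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
    "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H",
    "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr",
    "Pt", "Hg", "Pb", "unknown")
}

#' Feature vocabulary for drug graph featurization
#'
#' Fixes the one-hot layouts of the atom (78-dim) and motif (92-dim) node
#' feature vectors:
#' atom rows are `one-hot(symbol, 44) + one-hot(degree, 0..10) +
#' one-hot(total H, 0..10) + one-hot(implicit valence, 0..10) + aromatic flag`
#' (44+11+11+11+1 = 78); motif rows are `multi-hot(symbols, 44) +
#' one-hot(atom count, 0..10) + one-hot(inter-motif edges, 0..10) +
#' one-hot(total H, 0..11) + one-hot(summed implicit valence, 0..11) +
#' simple-ring flag + bond-unit flag` (44+11+11+12+12+1+1 = 92).
#' Counts beyond a block's last bin clamp to that bin; symbols outside the
#' vocabulary map to the final "unknown" slot.
#'
#' @param atom_symbols ordered symbol vocabulary; last entry is the
#'   unknown slot. Must have 44 entries to match the published layout.
#' @return object of class `feature_vocabulary`.
#' @export
feature_vocabulary <- function(atom_symbols = default_atom_symbols()) {
  if (length(atom_symbols) != 44) {
    stop_mgdta("atom symbol vocabulary must have exactly 44 slots, got ",
               length(atom_symbols))
  }
  structure(
    list(
      atom_symbols  = atom_symbols,
      degree_bins   = 0:10,
      h_bins_atom   = 0:10,
      val_bins_atom = 0:10,
      count_bins_motif = 0:10,
      edge_bins_motif  = 0:10,
      h_bins_motif     = 0:11,
      val_bins_motif   = 0:11,
      atom_dim  = 78L,
      motif_dim = 92L
    ),
    class = "feature_vocabulary"
  )
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat("feature_vocabulary: 44 atom symbols (", x$atom_symbols[1], "...",
      x$atom_symbols[44], "), atom dim ", x$atom_dim,
      ", motif dim ", x$motif_dim, "\n", sep = "")
  invisible(x)
}

#' Fingerprint of a feature vocabulary
#'
#' Stable hash of the symbol ordering and bin layout; stored in run
#' manifests and checkpoints so a model is never evaluated against graphs
#' built with a different feature layout.
#'
#' @param vocab a [feature_vocabulary()].
#' @return 8-character hex string.
#' @export
vocab_hash <- function(vocab) {
  string_hash(c(vocab$atom_symbols, vocab$atom_dim, vocab$motif_dim))
}
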