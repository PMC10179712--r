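# Full model: three graph encoders + attention fusion + regression head,
# with ablation switches (use_attention, use_motif, use_skip) and
# checkpointing.

#' Construct a drug-target affinity model
#'
#' Bundles the three branch encoders (drug atom graph, drug motif graph,
#' weighted protein graph), the fusion/head parameters, the feature
#' vocabulary and the configuration. Ablation switches reproduce the
#' published variants: `use_attention = FALSE` concatenates the embeddings
#' with equal implicit weights, `use_motif = FALSE` drops the motif branch
#' (head input 256), `use_skip = FALSE` removes the gated skip-connection.
#'
#' @param vocab a [feature_vocabulary()].
#' @param conv `"gcn"` or `"gat"` for all three branches.
#' @param pooling `"max"` or `"mean"` readout.
#' @param use_attention,use_motif,use_skip ablation switches.
#' @param n_heads GAT attention heads.
#' @param dropout dropout rate (0.2 by default, as published).
#' @param seed optional seed for reproducible initialisation.
#' @return object of class `dta_model`.
#' @export
dta_model <- function(vocab = feature_vocabulary(),
                      conv = c("gcn", "gat"),
                      pooling = c("max", "mean"),
                      use_attention = TRUE, use_motif = TRUE,
                      use_skip = TRUE, n_heads = 1, dropout = 0.2,
                      seed = NULL) {
  conv <- match.arg(conv)
  pooling <- match.arg(pooling)
  if (!is.null(seed)) set.seed(seed)
  mk <- function(dim) encoder_params(dim, conv = conv, pooling = pooling,
                                     use_skip = use_skip,
                                     n_heads = n_heads, dropout = dropout)
  branches <- list(drug = mk(vocab$atom_dim))
  if (use_motif) branches$motif <- mk(vocab$motif_dim)
  branches$protein <- mk(33L)
  structure(list(
    vocab = vocab,
    config = list(conv = conv, pooling = pooling,
                  use_attention = use_attention, use_motif = use_motif,
                  use_skip = use_skip, n_heads = n_heads,
                  dropout = dropout, vocab_hash = vocab_hash(vocab)),
    branches = branches,
    fusion = fusion_params(n_branches = length(branches),
                           use_attention = use_attention,
                           dropout = dropout)
  ), class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  cfg <- x$config
  cat("dta_model: conv=", cfg$conv, ", pooling=", cfg$pooling,
      ", attention=", cfg$use_attention, ", motif=", cfg$use_motif,
      ", skip=", cfg$use_skip, "; ", format(n_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# All learnable arrays of a parameter object, as a flat named list.
.learnable <- function(p) {
  keep <- list()
  fields <- c("W", "a", "U1", "U2", "bg", "Wp1", "bp1", "Wp2", "bp2",
              "W1", "W2", "Wh1", "bh1", "Wh2", "bh2", "Wh3", "bh3")
  for (f in intersect(fields, names(p))) keep[[f]] <- p[[f]]
  keep
}

#' Number of learnable parameters of a model
#' @param model a `dta_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  sum(vapply(model$branches, function(b) count(.learnable(b)), numeric(1))) +
    count(.learnable(model$fusion))
}

#' Build the graph triple for one drug-protein pair
#'
#' @param smiles drug SMILES.
#' @param sequence protein sequence.
#' @param vocab a [feature_vocabulary()].
#' @param predictor contact predictor (see [stub_contact_predictor()]).
#' @param windowsize,max_direct splicing controls
#'   (see [splice_contact_map()]).
#' @param threshold contact retention threshold.
#' @return `list(drug = atom_graph, motif = motif_graph,
#'   protein = protein_graph)`.
#' @export
build_pair_graphs <- function(smiles, sequence,
                              vocab = feature_vocabulary(),
                              predictor = stub_contact_predictor("banded"),
                              windowsize = 500, max_direct = 1000,
                              threshold = 0.5) {
  mol <- parse_smiles(smiles)
  cmap <- splice_contact_map(sequence, predictor, windowsize, max_direct)
  list(drug = build_atom_graph(mol, vocab),
       motif = build_motif_graph(mol, vocab),
       protein = threshold_graph(cmap, threshold))
}

# Forward over prebuilt branch embeddings (training path); returns caches.
.pair_forward <- function(zs, model, training = FALSE) {
  fw <- .fuse_forward(zs, model$fusion)
  hd <- .head_forward(fw$zc, model$fusion, training)
  list(out = hd$out, fuse_cache = fw$cache, head_cache = hd$cache,
       alpha = fw$alpha)
}

#' Forward pass of the full model on prebuilt graphs
#'
#' @param model a `dta_model`.
#' @param graphs list with `drug`, `motif`, `protein` graphs (the motif
#'   entry is ignored by a no-motif model).
#' @param training logical; enables dropout.
#' @return scalar predicted affinity.
#' @export
forward_dta <- function(model, graphs, training = FALSE) {
  for (b in names(model$branches)) {
    if (is.null(graphs[[b]])) {
      stop_mgdta("forward_dta: missing prebuilt graph for branch '", b, "'")
    }
  }
  zs <- lapply(names(model$branches), function(b)
    encode(graphs[[b]], model$branches[[b]], training))
  .pair_forward(zs, model, training)$out
}

#' Predict affinity for one drug-protein pair from raw inputs
#'
#' Builds the graph triple and runs the model in evaluation mode
#' (deterministic; no dropout).
#'
#' @inheritParams build_pair_graphs
#' @param model a `dta_model`.
#' @return scalar predicted affinity.
#' @export
predict_dta <- function(model, smiles, sequence,
                        predictor = stub_contact_predictor("banded"),
                        windowsize = 500, max_direct = 1000,
                        threshold = 0.5) {
  graphs <- build_pair_graphs(smiles, sequence, model$vocab, predictor,
                              windowsize, max_direct, threshold)
  forward_dta(model, graphs, training = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the feature vocabulary and configuration
#' alongside all weights, so a reloaded model reproduces predictions
#' bit-for-bit.
#'
#' @param model a `dta_model`.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the restored `dta_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dta_model")) {
    stop_mgdta("file is not a dta_model checkpoint: ", path)
  }
  model
}
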