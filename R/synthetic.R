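# Seeded synthetic fixtures: fragment-assembled SMILES, random protein
# sequences, deterministic stub contact predictors, and affinity labels
# with a known dependence on graph-visible features so recovery tests have
# ground truth.

#' Synthetic dataset configuration
#'
#' @param n_drugs,n_proteins,n_pairs entity and record counts.
#' @param seq_len_range sequence length range; the default straddles 1000
#'   so the window-splicing path is exercised.
#' @param fragments SMILES fragment vocabulary for molecule assembly; every
#'   fragment is a valid SMILES whose plain concatenation with another
#'   fragment is again valid, and the set contains both ring-bearing and
#'   acyclic fragments.
#' @param max_fragments longest fragment chain per molecule.
#' @param coef_ring,coef_len,coef_shared ground-truth affinity
#'   coefficients (see [gen_affinities()]).
#' @param noise_sd Gaussian label noise standard deviation.
#' @param seed seed fixing all generator randomness.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 16, n_proteins = 8, n_pairs = 64,
                             seq_len_range = c(80, 1200),
                             fragments = default_fragments(),
                             max_fragments = 4,
                             coef_ring = 2.0, coef_len = 2.5,
                             coef_shared = 1.0, noise_sd = 0.1,
                             seed = 1) {
  stopifnot(n_drugs >= 1, n_proteins >= 1, n_pairs >= 1,
            length(seq_len_range) == 2, seq_len_range[1] >= 10,
            diff(seq_len_range) >= 0, noise_sd >= 0)
  structure(list(n_drugs = n_drugs, n_proteins = n_proteins,
                 n_pairs = n_pairs, seq_len_range = seq_len_range,
                 fragments = fragments, max_fragments = max_fragments,
                 coef_ring = coef_ring, coef_len = coef_len,
                 coef_shared = coef_shared, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_config")
}

#' Default SMILES fragment vocabulary
#'
#' Fragments chosen so that any concatenation is itself valid SMILES
#' (each starts on an atom with a free valence and closes its own rings);
#' includes aromatic and aliphatic rings and acyclic units so generated
#' sets always contain both motif kinds.
#' @return character vector of fragments; ring-bearing ones are named
#'   `ring`, acyclic ones `chain`.
#' @export
default_fragments <- function() {
  c(chain = "C", chain = "CC", chain = "N", chain = "O",
    chain = "C(C)C", chain = "CNC", chain = "COC", chain = "C(=O)",
    chain = "CSC", chain = "C=C",
    ring = "c1ccccc1", ring = "C1CCCCC1", ring = "c1ccncc1",
    ring = "C1CCNCC1", ring = "c1ccsc1", ring = "C1CC1")
}

#' Generate fragment-assembled drug SMILES
#'
#' Deterministically (for a fixed seed) assembles `n_drugs` molecules by
#' concatenating 1..`max_fragments` fragments. The first molecule is
#' forced acyclic and the second is forced to contain a ring, so both
#' motif kinds always occur; any assembly that fails to parse is retried
#' with fresh draws.
#'
#' @param cfg a [synthetic_config()].
#' @return character vector of `n_drugs` unique SMILES.
#' @export
gen_molecules <- function(cfg) {
  set.seed(cfg$seed)
  frags <- cfg$fragments
  chain_ids <- which(names(frags) == "chain")
  ring_ids <- which(names(frags) == "ring")
  draw <- function(pool) {
    k <- sample(seq_len(cfg$max_fragments), 1)
    paste(frags[sample(pool, k, replace = TRUE)], collapse = "")
  }
  out <- character(0)
  want <- function(i) {
    if (i == 1) chain_ids
    else if (i == 2) ring_ids
    else seq_along(frags)
  }
  i <- 1
  while (length(out) < cfg$n_drugs) {
    smi <- draw(want(i))
    if (i == 2 && !any(vapply(frags[ring_ids], grepl, logical(1),
                              x = smi, fixed = TRUE))) next
    ok <- !smi %in% out &&
      tryCatch({parse_smiles(smi); TRUE}, error = function(e) FALSE)
    if (ok) {
      out <- c(out, smi)
      i <- i + 1
    }
  }
  out
}

#' Generate random protein sequences
#'
#' Uniform lengths over `seq_len_range`, letters uniform over the 20
#' standard residues. When the range allows lengths above 1000, at least
#' one sequence is forced beyond 1000 so the splicing path is exercised.
#'
#' @param cfg a [synthetic_config()].
#' @return character vector of `n_proteins` sequences.
#' @export
gen_proteins <- function(cfg) {
  set.seed(cfg$seed + 1)
  std <- residue_alphabet()[1:20]
  rng <- cfg$seq_len_range
  lens <- sample(rng[1]:rng[2], cfg$n_proteins, replace = TRUE)
  if (rng[2] > 1000 && !any(lens > 1000)) {
    lens[which.max(lens)] <- sample(1001:rng[2], 1)
  }
  vapply(lens, function(L)
    paste(sample(std, L, replace = TRUE), collapse = ""), character(1))
}

#' Deterministic stub contact predictors
#'
#' Realisations of the contact-predictor contract (sequence chunk ->
#' symmetric probability matrix) for testing without the real model:
#' * `banded` -- probability decays with residue separation
#'   (`pmax(0, base - decay * |i - j|)`), giving a near-diagonal graph
#'   after thresholding;
#' * `hash` -- a position-absolute deterministic value per (i, j) derived
#'   from the residue letters and their positions in the chunk, so window
#'   splicing is non-trivial to reassemble;
#' * `constant` -- every entry equals `value`.
#'
#' @param kind `"banded"`, `"hash"` or `"constant"`.
#' @param value constant value (for `kind = "constant"`).
#' @param base,decay band parameters (for `kind = "banded"`).
#' @return a predictor `function(sequence) -> L x L matrix`.
#' @export
stub_contact_predictor <- function(kind = c("banded", "hash", "constant"),
                                   value = 0.9, base = 0.95,
                                   decay = 0.15) {
  kind <- match.arg(kind)
  switch(kind,
    constant = function(sequence) {
      n <- nchar(sequence)
      matrix(value, n, n)
    },
    banded = function(sequence) {
      n <- nchar(sequence)
      d <- abs(outer(seq_len(n), seq_len(n), `-`))
      pmax(base - decay * d, 0)
    },
    hash = function(sequence) {
      n <- nchar(sequence)
      v <- utf8ToInt(sequence)
      x <- (v * seq_len(n)) %% 97
      m <- (outer(x, x, `+`) %% 89) / 88
      (m + t(m)) / 2
    })
}

# Shared-letter statistic coupling a drug to a protein: the fraction of
# residues whose one-letter code is also an element symbol of the drug.
# Both branches can see it (residue one-hots; atom symbol one-hots).
shared_letter_stat <- function(smiles, sequence) {
  elements <- unique(parse_smiles(smiles)$atoms$symbol)
  letters <- strsplit(sequence, "")[[1]]
  mean(letters %in% elements)
}

#' Generate affinity records with known ground truth
#'
#' Every (drug, protein) pair's affinity is a fixed affine function of
#' graph-visible features plus Gaussian noise:
#' `affinity = 5 + coef_ring * min(rings, 3)/3 + coef_len * norm_length +
#' coef_shared * shared_letter + N(0, noise_sd)`, scaled by construction
#' into the Davis-like 5-10.8 band. The coefficients and per-record
#' feature values are recorded in the attached manifest, so with
#' `noise_sd = 0` labels are exactly reproducible from the manifest
#' formula.
#'
#' @param drugs character vector of SMILES.
#' @param proteins character vector of sequences.
#' @param cfg a [synthetic_config()].
#' @return data.frame of records (columns `drug_id`, `smiles`,
#'   `protein_id`, `sequence`, `affinity`) with a `manifest` attribute.
#' @export
gen_affinities <- function(drugs, proteins, cfg) {
  stopifnot(length(drugs) >= 1, length(proteins) >= 1)
  set.seed(cfg$seed + 2)
  n_cells <- length(drugs) * length(proteins)
  pick <- sample.int(n_cells, min(cfg$n_pairs, n_cells))
  di <- ((pick - 1) %% length(drugs)) + 1
  pi_ <- ((pick - 1) %/% length(drugs)) + 1

  ring_count <- vapply(drugs, function(s)
    sum(vapply(decompose_motifs(s), function(m) m$kind == "ring",
               logical(1))), numeric(1))
  rng <- cfg$seq_len_range
  len_norm <- (nchar(proteins) - rng[1]) / max(1, diff(rng))

  rf <- pmin(ring_count[di], 3) / 3
  ln <- pmin(pmax(len_norm[pi_], 0), 1)
  sh <- vapply(seq_along(di), function(k)
    shared_letter_stat(drugs[di[k]], proteins[pi_[k]]), numeric(1))
  noise <- stats::rnorm(length(di), 0, cfg$noise_sd)
  aff <- 5 + cfg$coef_ring * rf + cfg$coef_len * ln +
    cfg$coef_shared * sh + noise

  rec <- data.frame(
    drug_id = paste0("D", sprintf("%03d", di)),
    smiles = drugs[di],
    protein_id = paste0("P", sprintf("%03d", pi_)),
    sequence = proteins[pi_],
    affinity = aff,
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  attr(rec, "manifest") <- list(
    intercept = 5,
    coef_ring = cfg$coef_ring, coef_len = cfg$coef_len,
    coef_shared = cfg$coef_shared, noise_sd = cfg$noise_sd,
    seed = cfg$seed,
    ring_frac = unname(rf), len_norm = unname(ln), shared = unname(sh))
  rec
}

#' Generate a complete synthetic dataset
#'
#' Molecules, sequences and affinity records in one call.
#'
#' @param cfg a [synthetic_config()].
#' @return `list(records, drugs, proteins, manifest)`.
#' @export
gen_dataset <- function(cfg = synthetic_config()) {
  drugs <- gen_molecules(cfg)
  proteins <- gen_proteins(cfg)
  records <- gen_affinities(drugs, proteins, cfg)
  list(records = records, drugs = drugs, proteins = proteins,
       manifest = attr(records, "manifest"))
}

#' Write a synthetic dataset to disk
#'
#' Long-format TSV of records, FASTA of sequences, and a JSON manifest
#' with the generator configuration and ground-truth coefficients.
#'
#' @param ds result of [gen_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_long_table(ds$records, file.path(dir, "records.tsv"))
  prot <- unique(ds$records[c("protein_id", "sequence")])
  writeLines(paste0(">", prot$protein_id, "\n", prot$sequence),
             file.path(dir, "proteins.fasta"))
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
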