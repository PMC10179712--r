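# Weighted protein graphs from residue-residue contact probabilities.
#
# A pluggable contact predictor maps a sequence chunk (<= the predictor's
# context size) to a symmetric probability matrix. Long sequences are
# handled by predicting overlapping windows and splicing them along the
# diagonal, averaging doubly covered cells. Thresholding the assembled map
# at 0.5 gives the weighted residue graph.

#' The 25-letter amino-acid alphabet
#'
#' Twenty standard residues plus B (Asx), Z (Glx), U (Sec), O (Pyl) and the
#' X wildcard; the ordering fixes the one-hot block of the residue features.
#' @return character vector of length 25.
#' @export
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
    "B", "Z", "U", "O", "X")
}

#' Residue physicochemical property table
#'
#' One row per alphabet letter: class flags (aromatic, aliphatic,
#' polar-neutral, acidic, basic) and scalar properties -- free amino-acid
#' molecular weight (Da), Kyte-Doolittle hydropathy index, and side-chain
#' pKa (0 for non-ionizable side chains). Ambiguity codes carry averaged /
#' nearest-analogue values; X carries neutral means. Scalars are min-max
#' rescaled to \[0,1\] at featurization time.
#'
#' @return data.frame with 25 rows.
#' @export
residue_property_table <- function() {
  code <- residue_alphabet()
  aromatic  <- code %in% c("F", "W", "Y", "H")
  aliphatic <- code %in% c("A", "G", "I", "L", "V")
  polar     <- code %in% c("S", "T", "N", "Q", "C", "Y", "U", "B", "Z")
  acidic    <- code %in% c("D", "E")
  basic     <- code %in% c("K", "R", "H", "O")
  mw <- c(A = 89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
          G = 75.07, H = 155.16, I = 131.17, K = 146.19, L = 131.17,
          M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
          S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19,
          B = 132.61, Z = 146.64, U = 168.06, O = 255.31, X = 136.90)
  hyd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
           G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
           M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
           S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3,
           B = -3.5, Z = -3.5, U = 2.5, O = -3.9, X = 0.0)
  pka <- c(A = 0, C = 8.30, D = 3.65, E = 4.25, F = 0,
           G = 0, H = 6.00, I = 0, K = 10.53, L = 0,
           M = 0, N = 0, P = 0, Q = 0, R = 12.48,
           S = 0, T = 0, V = 0, W = 0, Y = 10.07,
           B = 1.83, Z = 2.13, U = 5.43, O = 9.70, X = 0)
  data.frame(code = code, aromatic = aromatic, aliphatic = aliphatic,
             polar_neutral = polar, acidic = acidic, basic = basic,
             mw = unname(mw[code]), hydropathy = unname(hyd[code]),
             pka = unname(pka[code]), stringsAsFactors = FALSE)
}

.rescale01 <- function(v) (v - min(v)) / (max(v) - min(v))

#' Featurize one residue (33-dim vector)
#'
#' one-hot(residue type, 25) + class flags (aromatic, aliphatic,
#' polar-neutral, acidic, basic) + rescaled scalars (molecular weight,
#' hydropathy, side-chain pKa).
#'
#' @param letter a single amino-acid letter.
#' @param table property table, by default [residue_property_table()].
#' @return numeric vector of length 33.
#' @export
featurize_residue <- function(letter, table = residue_property_table()) {
  idx <- match(letter, table$code)
  if (is.na(idx)) {
    stop_mgdta("unknown amino-acid letter '", letter, "'")
  }
  c(one_hot(letter, table$code),
    as.numeric(table[idx, c("aromatic", "aliphatic", "polar_neutral",
                            "acidic", "basic")]),
    .rescale01(table$mw)[idx],
    .rescale01(table$hydropathy)[idx],
    .rescale01(table$pka)[idx])
}

#' Featurize a whole sequence
#' @param sequence amino-acid string.
#' @param table property table.
#' @return L x 33 numeric matrix.
#' @export
featurize_sequence <- function(sequence, table = residue_property_table()) {
  letters <- validate_sequence(sequence)
  oh <- diag(25)[match(letters, table$code), , drop = FALSE]
  flags <- as.matrix(table[match(letters, table$code),
                           c("aromatic", "aliphatic", "polar_neutral",
                             "acidic", "basic")]) * 1
  sc <- cbind(.rescale01(table$mw), .rescale01(table$hydropathy),
              .rescale01(table$pka))[match(letters, table$code), ,
                                     drop = FALSE]
  m <- cbind(oh, flags, sc)
  dimnames(m) <- NULL
  m
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop_mgdta("'sequence' must be a single string")
  }
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters), residue_alphabet())
  if (length(bad)) {
    stop_mgdta("sequence contains letters outside the 25-letter ",
               "amino-acid alphabet: ", paste(bad, collapse = ", "))
  }
  letters
}

#' Window plan for contact-map splicing
#'
#' For a sequence of `len` residues, the overlapping windows whose
#' predicted contact maps are spliced along the diagonal: width
#' `2 * windowsize`, step `windowsize`, plus a final window anchored at
#' `len - 2 * windowsize` whenever the stepped windows stop short of the
#' end. Every residue pair closer than `windowsize` falls in at least one
#' window.
#'
#' @param len sequence length (> `2 * windowsize`).
#' @param windowsize step size; windows are twice this wide.
#' @return data.frame with 1-based inclusive `start`, `end` columns.
#' @export
splice_windows <- function(len, windowsize = 500) {
  width <- 2L * as.integer(windowsize)
  if (len <= width) return(data.frame(start = 1L, end = as.integer(len)))
  starts <- seq.int(0L, len - width, by = as.integer(windowsize))
  if (max(starts) + width < len) starts <- c(starts, len - width)
  data.frame(start = starts + 1L, end = starts + width)
}

#' Assemble a contact map for a sequence of any length
#'
#' Sequences up to `max_direct` residues go through the predictor in one
#' call. Longer sequences are cut into overlapping windows
#' ([splice_windows()]); each window's predicted map is pasted on the
#' diagonal block it covers and cells covered more than once hold the mean
#' of their predictions. Pairs farther apart than the window width are
#' outside every window and stay 0 -- an inherent limit of the scheme.
#'
#' @param sequence amino-acid string (length >= 2) over the 25-letter
#'   alphabet.
#' @param predictor function `(sequence chunk) -> L x L matrix` of contact
#'   probabilities in \[0,1\]; must be deterministic and symmetric.
#' @param windowsize splicing step (window width is twice this).
#' @param max_direct longest sequence sent to the predictor in one call.
#' @return object of class `contact_map`: `matrix` (L x L), `sequence`.
#' @export
splice_contact_map <- function(sequence, predictor, windowsize = 500,
                               max_direct = 1000) {
  letters <- validate_sequence(sequence)
  len <- length(letters)
  if (len < 2) stop_mgdta("sequence must have at least 2 residues")
  call_predictor <- function(chunk) {
    m <- predictor(chunk)
    n <- nchar(chunk)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      stop_mgdta("contact predictor contract violation: expected ", n, "x",
                 n, " matrix, got ",
                 paste(dim(m), collapse = "x"))
    }
    if (anyNA(m) || min(m) < 0 || max(m) > 1) {
      stop_mgdta("contact predictor contract violation: probabilities ",
                 "outside [0,1]")
    }
    (m + t(m)) / 2
  }
  seq_str <- paste(letters, collapse = "")
  if (len <= max_direct) {
    cm <- call_predictor(seq_str)
  } else {
    acc <- matrix(0, len, len)
    cnt <- matrix(0L, len, len)
    win <- splice_windows(len, windowsize)
    for (k in seq_len(nrow(win))) {
      i <- win$start[k]:win$end[k]
      sub <- substr(seq_str, win$start[k], win$end[k])
      acc[i, i] <- acc[i, i] + call_predictor(sub)
      cnt[i, i] <- cnt[i, i] + 1L
    }
    cm <- acc / pmax(cnt, 1L)
  }
  structure(list(matrix = cm, sequence = seq_str), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map: ", nrow(x$matrix), " residues\n", sep = "")
  invisible(x)
}

#' Threshold a contact map into a weighted protein graph
#'
#' Residues are nodes (33-dim features); an edge joins residues i < j when
#' their contact probability reaches `threshold`, weighted by that
#' probability. Residues with no surviving contact remain as isolated
#' nodes.
#'
#' @param cmap a `contact_map`.
#' @param threshold retention threshold (default 0.5); comparison is `>=`.
#' @param table residue property table.
#' @return object of class `protein_graph`: `n_nodes`, `node_features`
#'   (L x 33), `edges`, `edge_weights`, `sequence`.
#' @export
threshold_graph <- function(cmap, threshold = 0.5,
                            table = residue_property_table()) {
  stopifnot(inherits(cmap, "contact_map"))
  m <- cmap$matrix
  keep <- which(upper.tri(m) & m >= threshold, arr.ind = TRUE)
  structure(list(
    n_nodes = nrow(m),
    node_features = featurize_sequence(cmap$sequence, table),
    edges = unname(keep[order(keep[, 1], keep[, 2]), , drop = FALSE]),
    edge_weights = m[keep[order(keep[, 1], keep[, 2]), , drop = FALSE]],
    sequence = cmap$sequence
  ), class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph: ", x$n_nodes, " residues, ", nrow(x$edges),
      " weighted contacts\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' Write / read a contact map as a dense TSV matrix
#'
#' Plain-text interchange: a square tab-separated matrix, one row per
#' residue, with the sequence stored on a leading `# sequence:` comment.
#' @param cmap a `contact_map`.
#' @param path output file.
#' @export
write_contact_map <- function(cmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sequence: ", cmap$sequence), con)
  utils::write.table(cmap$matrix, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @return a `contact_map`.
#' @export
read_contact_map <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# sequence: ", first)) {
    stop_mgdta("contact map file lacks the '# sequence:' header: ", path)
  }
  seq_str <- sub("^# sequence: ", "", first)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(m) <- NULL
  structure(list(matrix = m, sequence = seq_str), class = "contact_map")
}
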