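# Dataset parsing, the Kd -> pKd transform, and train/test splitting.

#' Convert a dissociation constant (nM) to pKd
#'
#' `pKd = -log10(Kd / 1e9)`: the Kd in nanomolar is expressed in molar
#' units and negated on the log10 scale. The Davis-style affinity label;
#' Kd = 10,000 nM (the assay ceiling) maps to the boundary value 5.0.
#'
#' @param kd dissociation constant(s) in nM; must be positive.
#' @return pKd value(s).
#' @export
kd_to_pkd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop_mgdta("kd must be positive and finite (nM)")
  }
  -log10(kd / 1e9)
}

#' Load a long-format affinity table
#'
#' Reads a TSV/CSV with columns `drug_id`, `smiles`, `protein_id`,
#' `sequence`, `affinity`; validates every row (parseable SMILES, sequence
#' over the 25-letter alphabet, finite affinity, no duplicated
#' drug-protein pair) and reports offending row numbers.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` comma, otherwise tab).
#' @return data.frame of validated records.
#' @export
load_long_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("drug_id", "smiles", "protein_id", "sequence", "affinity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_mgdta("missing column(s) in ", path, ": ",
               paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop_mgdta("empty affinity table: ", path)
  key <- paste(df$drug_id, df$protein_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_mgdta("duplicated drug-protein pair(s): ",
               paste(unique(sprintf("(%s, %s)", df$drug_id[dup],
                                    df$protein_id[dup])), collapse = ", "))
  }
  if (any(!nzchar(df$drug_id)) || any(!nzchar(df$protein_id))) {
    stop_mgdta("empty drug or protein id in ", path)
  }
  if (any(!is.finite(df$affinity))) {
    stop_mgdta("non-finite affinity at row(s): ",
               paste(which(!is.finite(df$affinity)), collapse = ", "))
  }
  for (i in seq_len(nrow(df))[!duplicated(df$smiles)]) {
    ok <- tryCatch({parse_smiles(df$smiles[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      stop_mgdta("invalid SMILES at row ", i, ": '", df$smiles[i], "'")
    }
  }
  for (i in seq_len(nrow(df))[!duplicated(df$sequence)]) {
    ok <- tryCatch({validate_sequence(df$sequence[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      stop_mgdta("invalid protein sequence at row ", i)
    }
  }
  df[need]
}

#' Write a long-format affinity table
#' @param records data.frame of records.
#' @param path output path (TSV).
#' @export
write_long_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split records into equal parts with one held-out test part
#'
#' Seeded shuffle into `n_parts` near-equal parts (sizes differ by at most
#' one); part 1 is the held-out test part and the remaining parts form the
#' training set -- the six-part protocol. With `cv = TRUE` the assignment
#' is interpreted as cross-validation folds instead (each part once as
#' test).
#'
#' @param n_records number of records (or a data.frame of records).
#' @param n_parts number of parts (6 by default; the five-fold protocol is
#'   `n_parts = 5, cv = TRUE`).
#' @param seed RNG seed; fixed seed gives an identical assignment.
#' @param cv logical: mark the split as a cross-validation fold layout.
#' @return object of class `dataset_split`: `part` (integer assignment per
#'   record), `test_part` (1 unless `cv`), `n_parts`, `seed`, `cv`.
#' @export
make_split <- function(n_records, n_parts = 6, seed = 1, cv = FALSE) {
  n <- if (is.data.frame(n_records)) nrow(n_records) else n_records
  if (n < n_parts) {
    stop_mgdta("need at least ", n_parts, " records for a ", n_parts,
               "-part split, got ", n)
  }
  set.seed(seed)
  perm <- sample.int(n)
  part <- integer(n)
  # deal records round-robin over the shuffled order: sizes differ by <= 1
  part[perm] <- rep_len(seq_len(n_parts), n)
  structure(list(part = part, test_part = if (cv) NA_integer_ else 1L,
                 n_parts = n_parts, seed = seed, cv = cv),
            class = "dataset_split")
}

#' Train / test indices of a split
#' @param split a `dataset_split`.
#' @param test_part which part is held out (defaults to the split's own).
#' @return `list(train = <indices>, test = <indices>)`.
#' @export
split_indices <- function(split, test_part = split$test_part) {
  if (is.na(test_part)) test_part <- 1L
  list(train = which(split$part != test_part),
       test = which(split$part == test_part))
}

#' Write a split manifest as JSON
#' @param split a `dataset_split`.
#' @param path output path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE)
  invisible(path)
}
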