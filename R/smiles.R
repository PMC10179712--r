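# SMILES -> heavy-atom molecular description.
#
# OpenBabel (via ChemmineOB) parses the SMILES and emits a kekulized V2000
# molblock; ChemmineR supplies the SDF container and ring perception.
# Molblocks with zero bonds (single heavy atoms, bare ion pairs) are not
# round-tripped correctly by read.SDFset, so a minimal fixed-width reader
# covers that corner.

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1, As = 3, Se = 2)

# Daylight-style implicit hydrogen count: default valence, shifted by formal
# charge (+q for N/P/O/S-group donors, -|q| for carbon-group), minus the sum
# of explicit bond orders. Hypervalent S/P simply bottom out at zero.
implicit_h_count <- function(symbol, charge, order_sum) {
  dv <- DEFAULT_VALENCE[symbol]
  if (is.na(dv)) return(0L)
  adj <- if (symbol %in% c("N", "P", "As", "O", "S", "Se")) charge
         else if (symbol %in% c("C", "Si", "B")) -abs(charge)
         else 0
  max(0L, as.integer(dv + adj - order_sum))
}

parse_charge_lines <- function(lines, natoms) {
  charges <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- tok[1]
    for (k in seq_len(n)) charges[tok[2 * k]] <- tok[2 * k + 1]
  }
  charges
}

#' Parse a SMILES string into a heavy-atom molecular description
#'
#' @param smiles a single SMILES string.
#' @return object of class `molecule`: `atoms` (data.frame with `symbol`,
#'   `charge`, `degree`, `n_h`, `implicit_valence`, `aromatic` per heavy
#'   atom), `bonds` (data.frame `a1`, `a2`, `order`, heavy-atom indices with
#'   `a1 < a2`), `rings` (list of integer vectors, smallest set of smallest
#'   rings), `ring_aromatic` (logical per ring) and the source `smiles`.
#'   Hydrogens are implicit: they never appear as atoms, only in the
#'   per-atom hydrogen counts.
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_mgdta("'smiles' must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tmol\n")),
    error = function(e) "")
  if (!nzchar(txt)) {
    stop_mgdta("cannot parse SMILES string: '", smiles, "'")
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || natoms < 1) {
    stop_mgdta("SMILES '", smiles, "' yields no atoms")
  }

  ring_list <- list()
  ring_arom <- logical(0)
  if (!is.na(nbonds) && nbonds >= 1) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))[[1]]
    labels <- rownames(ChemmineR::atomblock(sdf))
    symbols <- sub("_[0-9]+$", "", labels)
    bb <- ChemmineR::bondblock(sdf)
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    ri <- ChemmineR::rings(sdf, upper = Inf, type = "all",
                           arom = TRUE, inner = TRUE)
    if (length(ri$RINGS)) {
      ring_list <- lapply(ri$RINGS, function(r)
        as.integer(sub(".*_", "", r)))
      ring_arom <- as.logical(ri$AROMATIC)
    }
  } else {
    atom_lines <- lines[5:(4 + natoms)]
    symbols <- trimws(substr(atom_lines, 32, 34))
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  charges <- parse_charge_lines(lines, natoms)

  # Drop explicit hydrogens (they occur only when written as [H] in the
  # input); remember them as explicit H counts on their heavy neighbour.
  heavy <- which(symbols != "H")
  if (!length(heavy)) {
    stop_mgdta("SMILES '", smiles, "' contains no heavy atoms")
  }
  remap <- integer(natoms)
  remap[heavy] <- seq_along(heavy)

  order_sum <- numeric(natoms)
  degree <- integer(natoms)       # heavy-atom neighbours only
  explicit_h <- integer(natoms)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]; o <- bonds$order[k]
    order_sum[a] <- order_sum[a] + o
    order_sum[b] <- order_sum[b] + o
    if (symbols[a] != "H" && symbols[b] != "H") {
      degree[a] <- degree[a] + 1L
      degree[b] <- degree[b] + 1L
    } else {
      if (symbols[b] == "H") explicit_h[a] <- explicit_h[a] + 1L
      if (symbols[a] == "H") explicit_h[b] <- explicit_h[b] + 1L
    }
  }

  imp_h <- vapply(heavy, function(i)
    implicit_h_count(symbols[i], charges[i], order_sum[i]), integer(1))

  aromatic <- logical(length(heavy))
  rings_heavy <- list()
  if (length(ring_list)) {
    rings_heavy <- lapply(ring_list, function(r) sort(remap[r]))
    for (k in seq_along(rings_heavy)) {
      if (ring_arom[k]) aromatic[rings_heavy[[k]]] <- TRUE
    }
  }

  hb <- bonds[symbols[bonds$a1] != "H" & symbols[bonds$a2] != "H", ,
              drop = FALSE]
  if (nrow(hb)) {
    a1 <- remap[hb$a1]; a2 <- remap[hb$a2]
    bonds_heavy <- data.frame(a1 = pmin(a1, a2), a2 = pmax(a1, a2),
                              order = hb$order)
    bonds_heavy <- bonds_heavy[order(bonds_heavy$a1, bonds_heavy$a2), ,
                               drop = FALSE]
    rownames(bonds_heavy) <- NULL
  } else {
    bonds_heavy <- data.frame(a1 = integer(0), a2 = integer(0),
                              order = integer(0))
  }

  structure(list(
    atoms = data.frame(
      symbol = symbols[heavy],
      charge = charges[heavy],
      degree = degree[heavy],
      n_h = imp_h + explicit_h[heavy],
      implicit_valence = imp_h,
      aromatic = aromatic,
      stringsAsFactors = FALSE),
    bonds = bonds_heavy,
    rings = rings_heavy,
    ring_aromatic = if (length(ring_list)) ring_arom else logical(0),
    smiles = smiles
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule '", x$smiles, "': ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", length(x$rings), " rings\n", sep = "")
  invisible(x)
}
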