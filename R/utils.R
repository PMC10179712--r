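# Small numeric helpers shared across modules. Kept internal.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' One-hot encode a value over an ordered vocabulary
#'
#' Values outside the vocabulary map to the final slot (for symbol
#' vocabularies the final slot is the "unknown" symbol; for count bins the
#' final slot absorbs out-of-range counts, i.e. counts clamp).
#'
#' @param value a single value (character symbol or non-negative count).
#' @param levels ordered vector of admissible values.
#' @return numeric 0/1 vector of `length(levels)` with exactly one 1.
#' @keywords internal
one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  if (is.na(idx)) idx <- length(levels)
  v[idx] <- 1
  v
}

# Clamp a count into [0, max(bins)] then one-hot over the bins.
one_hot_count <- function(count, bins) {
  one_hot(min(max(count, min(bins)), max(bins)), bins)
}

# Glorot/Xavier uniform initialisation, n_in x n_out.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Polynomial rolling hash (hex, mod 2^31-1); fingerprints vocabularies in
# manifests and checkpoints without external digest dependencies.
string_hash <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mgdta <- function(...) stop(..., call. = FALSE)
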