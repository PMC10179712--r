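# Evaluation metrics for affinity regression: MSE, concordance index,
# Pearson correlation and the rm2 external-validity index.

.check_pairs <- function(y, p) {
  if (length(y) != length(p)) {
    stop_mgdta("y and p must have equal length")
  }
  if (!length(y)) stop_mgdta("empty input")
  if (anyNA(y) || anyNA(p) || any(!is.finite(c(y, p)))) {
    stop_mgdta("y and p must be finite")
  }
}

#' Mean squared error
#' @param y true affinities.
#' @param p predicted affinities.
#' @return `mean((y - p)^2)`.
#' @export
mse <- function(y, p) {
  .check_pairs(y, p)
  mean((y - p)^2)
}

#' Concordance index
#'
#' Fraction of strictly ordered true pairs (`y_i > y_j`) whose predictions
#' preserve the order: each such pair contributes 1 if `p_i > p_j`, 0.5 if
#' `p_i == p_j`, else 0, normalised by the number of strictly ordered
#' pairs. Ties in y contribute neither to the numerator nor to the
#' normaliser.
#'
#' @param y true affinities (at least one strictly ordered pair).
#' @param p predicted affinities.
#' @return scalar in \[0,1\].
#' @export
concordance_index <- function(y, p) {
  .check_pairs(y, p)
  dy <- outer(y, y, `-`)
  comp <- dy > 0       # (i, j) with y_i > y_j
  z <- sum(comp)
  if (z == 0) {
    stop_mgdta("concordance index undefined: no strictly ordered pair ",
               "of true values")
  }
  dp <- outer(p, p, `-`)
  h <- (dp > 0) + 0.5 * (dp == 0)
  sum(h[comp]) / z
}

#' Pearson correlation coefficient
#'
#' `cov(p, y) / (sd(p) sd(y))`, computed with population moments (the
#' ratio is identical under sample moments).
#'
#' @inheritParams mse
#' @return scalar in \[-1,1\].
#' @export
pearson <- function(y, p) {
  .check_pairs(y, p)
  yc <- y - mean(y)
  pc <- p - mean(p)
  vy <- mean(yc^2)
  vp <- mean(pc^2)
  if (vy == 0 || vp == 0) {
    stop_mgdta("pearson undefined: zero variance input")
  }
  mean(yc * pc) / sqrt(vy * vp)
}

#' rm2 external-validity index
#'
#' `rm2 = r^2 * (1 - sqrt(r^2 - r0^2))`, where `r^2` is the squared
#' Pearson correlation (with intercept) and `r0^2` is the coefficient of
#' determination of the least-squares fit of y on p through the origin
#' (slope `k = sum(y p) / sum(p^2)`,
#' `r0^2 = 1 - sum((y - k p)^2) / sum((y - mean(y))^2)`). A radicand that
#' dips below zero by numerical noise is clamped at 0 with a warning.
#'
#' @inheritParams mse
#' @return scalar.
#' @export
rm2 <- function(y, p) {
  .check_pairs(y, p)
  r2 <- pearson(y, p)^2
  k <- sum(y * p) / sum(p^2)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  rad <- r2 - r02
  if (rad < 0) {
    if (rad < -1e-8) {
      warning("rm2: r^2 < r0^2 (", format(rad), "); radicand clamped at 0")
    }
    rad <- 0
  }
  r2 * (1 - sqrt(rad))
}

#' All four evaluation metrics at once
#'
#' @inheritParams mse
#' @return named list with `mse`, `ci`, `rm2`, `pearson`.
#' @export
evaluate_predictions <- function(y, p) {
  list(mse = mse(y, p),
       ci = concordance_index(y, p),
       rm2 = rm2(y, p),
       pearson = pearson(y, p))
}
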