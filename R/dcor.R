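# Double-centered Euclidean distance matrix of a numeric vector.
dcenter <- function(v) {
  d <- as.matrix(stats::dist(v))
  rm <- rowMeans(d)
  sweep(sweep(d, 1, rm), 2, rm) + mean(d)
}

#' Sample distance correlation
#'
#' Distance correlation is a measure of dependence between two random
#' variables, not necessarily linearly related, whose population value is
#' zero only under independence. The sample version is computed from
#' doubly-centered pairwise Euclidean distance matrices A and B:
#' \eqn{dCov^2 = mean(A B)}, \eqn{dVar_x^2 = mean(A^2)}, and
#' \eqn{dCor = dCov / \sqrt{dVar_x dVar_y}}. When either distance variance is
#' zero (a constant input) the value is 0 by convention.
#'
#' The statistic is symmetric in its arguments and invariant to adding a
#' constant to, or rescaling by a nonzero constant, either vector.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' distance_correlation(1:10, (1:10)^2)
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("distance_correlation: length mismatch")
  if (length(x) < 2L) stop("distance_correlation: need n >= 2")
  A <- dcenter(x)
  B <- dcenter(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(mean(A * B), 0) / sqrt(dvx * dvy))
}

#' Permutation significance test for distance correlation
#'
#' Builds the null distribution of the distance correlation by randomly
#' permuting `y` (the standard independence-test resampling scheme), and
#' returns the add-one permutation p-value
#' \eqn{p = (1 + \#\{dCor_{null} \ge dCor_{obs}\}) / (1 + n_{resamples})},
#' which is never zero. Because double-centering commutes with simultaneous
#' row/column permutation, each resample reuses the centered distance
#' matrices, costing one elementwise product.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_resamples number of permutations (default 300).
#' @param seed RNG seed for the permutations.
#' @return A p-value in (0, 1].
#' @export
dcor_resample_test <- function(x, y, n_resamples = 300L, seed = 1L) {
  if (n_resamples < 1L) stop("dcor_resample_test: n_resamples must be >= 1")
  if (length(x) != length(y)) stop("dcor_resample_test: length mismatch")
  n <- length(x)
  A <- dcenter(x)
  B <- dcenter(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(1)
  denom <- sqrt(dvx * dvy)
  obs <- sqrt(max(mean(A * B), 0) / denom)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_resamples), function(k) {
      p <- sample.int(n)
      sqrt(max(mean(A * B[p, p]), 0) / denom) >= obs
    }, logical(1)))
  })
  (1 + exceed) / (1 + n_resamples)
}
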