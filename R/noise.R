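#' Expression-proportional Gaussian noise
#'
#' Adds mean-zero Gaussian noise with variance proportional to the entry's
#' expression level: `y = max(0, x + eps)`, `eps ~ N(0, c * x)`. Entries with
#' x = 0 have zero noise variance and pass through unchanged; the clamp keeps
#' expression nonnegative (which slightly inflates means at low expression —
#' accepted and documented).
#'
#' @param values nonnegative expression matrix.
#' @param variance_coefficient c >= 0, noise variance per unit expression
#'   (default 0.05).
#' @return Matrix of the same shape. Consumes the R random stream.
#' @export
add_gaussian_noise <- function(values, variance_coefficient = 0.05) {
  if (variance_coefficient < 0) stop("variance_coefficient must be >= 0")
  if (any(values < 0)) stop("values must be nonnegative")
  if (variance_coefficient == 0) return(values)
  eps <- stats::rnorm(length(values), mean = 0,
                      sd = sqrt(variance_coefficient * values))
  out <- pmax(values + eps, 0)
  out[values == 0] <- 0
  out
}

#' Dropout probability as a function of mean expression
#'
#' `p = min(p_max, scale / (1 + mu))`: strictly decreasing in the gene's mean
#' expression for scale > 0, so highly expressed genes are least likely to
#' drop out, capped below 1.
#'
#' @param gene_mean nonnegative mean expression mu (vectorised).
#' @param scale s >= 0.
#' @param p_max probability cap in [0, 1) (default 0.9).
#' @return Probabilities in `[0, p_max]`.
#' @export
dropout_probability <- function(gene_mean, scale, p_max = 0.9) {
  if (any(gene_mean < 0)) stop("gene_mean must be nonnegative")
  if (scale < 0) stop("scale must be >= 0")
  pmin(p_max, scale / (1 + gene_mean))
}

#' Calibrate the dropout scale to a target zero fraction
#'
#' Finds s such that the expected zeroed fraction of the matrix,
#' `mean_g p(mu_g)` weighted by column sizes, equals `target` within `tol`.
#' The expected rate is nondecreasing in s, so bisection applies; the target
#' is unreachable when every gene is already at the `p_max` cap.
#'
#' @param values nonempty expression matrix (genes in columns).
#' @param target desired zero fraction, in (0, p_max) (default 0.175, the
#'   midpoint of the 15-20 percent realistic-sparsity band).
#' @param p_max probability cap.
#' @param tol absolute tolerance on the expected rate (default 1e-4).
#' @return The calibrated scale s.
#' @export
calibrate_dropout_scale <- function(values, target = 0.175, p_max = 0.9,
                                    tol = 1e-4) {
  if (length(values) == 0) stop("values must be nonempty")
  if (target < 0 || target >= p_max)
    stop("target must lie in [0, p_max)")
  if (target == 0) return(0)
  mu <- colMeans(as.matrix(values))
  expected <- function(s) mean(dropout_probability(mu, s, p_max))
  hi <- 1
  while (expected(hi) < target && hi < 1e6) hi <- hi * 2
  if (expected(hi) < target - tol)
    stop("target dropout rate unreachable under the p_max cap")
  lo <- 0
  while (hi - lo > 1e-12 && abs(expected((lo + hi) / 2) - target) > tol / 10) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Apply zero-inflated dropout
#'
#' Each entry of column g is independently set to zero with probability
#' `dropout_probability(mean(column g), scale, p_max)`; a logical mask marks
#' the zeroed entries, all other entries are unchanged.
#'
#' @param values expression matrix (genes in columns).
#' @param scale calibrated (or user-set) dropout scale.
#' @param p_max probability cap.
#' @return List with `values` (matrix after dropout) and `mask` (logical
#'   matrix, TRUE where zeroed). Consumes the R random stream.
#' @export
apply_dropout <- function(values, scale, p_max = 0.9) {
  values <- as.matrix(values)
  p <- dropout_probability(colMeans(values), scale, p_max)
  mask <- matrix(stats::runif(length(values)) <
                   rep(p, each = nrow(values)),
                 nrow = nrow(values), dimnames = dimnames(values))
  out <- values
  out[mask] <- 0
  list(values = out, mask = mask)
}
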