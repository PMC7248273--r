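#' Fisher combination statistic
#'
#' `T = -2 * sum(log p_j)` over the `d` per-trait p-values of one gene.
#' For independent uniform p-values `T ~ chisq(2d)`; the correlated version is
#' handled by [correlated_fisher_pvalue()]. Inputs are clipped at `1e-15`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Scalar `T >= 0`.
#' @export
fisher_statistic <- function(pvals) {
  if (length(pvals) == 0L) abort("no p-values", class = "omga_input_error")
  if (anyNA(pvals)) abort("NA p-values", class = "omga_input_error")
  -2 * sum(log(pmin(pmax(pvals, 1e-15), 1)))
}

#' Pairwise covariance of -2 log p across traits
#'
#' Estimates `delta_jk = cov(-2 log p_j, -2 log p_k)` empirically across the
#' rows of a genes-by-traits p-value matrix, treating genome-wide gene-level
#' p-values as approximately null draws. Entries are clipped to `[-4, 4]`
#' (the variance of `-2 log U` for uniform `U` is 4, bounding the covariance).
#' With fewer than 50 genes the estimate is too noisy; use
#' [delta_from_trait_correlation()] instead.
#'
#' @param pmatrix `G x d` matrix (or data frame) of per-gene, per-trait
#'   p-values, `G >= 50`.
#' @return Symmetric `d x d` covariance matrix of the `-2 log p` transforms
#'   (diagonal = empirical variances; only off-diagonals enter the combined
#'   test).
#' @export
estimate_pairwise_covariance <- function(pmatrix) {
  P <- as.matrix(pmatrix)
  if (nrow(P) < 50) {
    abort(paste0("only ", nrow(P), " genes: too few rows for the empirical ",
                 "covariance estimator; use delta_from_trait_correlation()"),
          class = "omga_input_error")
  }
  if (any(P <= 0 | P >= 1)) P <- pmin(pmax(P, 1e-15), 1 - 1e-15)
  L <- -2 * log(P)
  D <- cov(L)
  D <- (D + t(D)) / 2
  pmin(pmax(D, -4), 4)
}

#' Trait-correlation fallback for delta
#'
#' Polynomial approximation of `cov(-2 log p_j, -2 log p_k)` from the
#' correlation of the underlying traits (Brown's method with the
#' Kost–McDermott polynomial):
#' `delta_jk = 3.263 r + 0.710 r^2 + 0.027 r^3` with `r = |rho_jk|`
#' (signed by `rho_jk`). Used when too few genes are available for the
#' empirical estimator.
#'
#' @param traits `n x d` matrix of traits (or residuals after covariate
#'   adjustment), or a `d x d` correlation matrix.
#' @return Symmetric `d x d` matrix of delta values (diagonal 4).
#' @export
delta_from_trait_correlation <- function(traits) {
  R <- as.matrix(traits)
  if (nrow(R) != ncol(R) || any(abs(diag(R) - 1) > 1e-8)) R <- cor(R)
  a <- abs(R)
  D <- sign(R) * (3.263 * a + 0.710 * a^2 + 0.027 * a^3)
  diag(D) <- 4
  pmin(pmax((D + t(D)) / 2, -4), 4)
}

#' Gamma-approximation p-value for the correlated Fisher statistic
#'
#' Under dependence, `T = -2 sum(log p_j)` has mean `mu = 2d` and variance
#' `sigma2 = 4d + sum_{j != k} delta_jk`. Its null distribution is
#' approximated by a gamma with shape `mu^2 / sigma2` and scale `sigma2 / mu`
#' (equivalently a scaled chi-square), and the p-value is the upper gamma tail
#' at `T`. With all `delta_jk = 0` this is exactly the `chisq(2d)` tail.
#' `sigma2` is floored at 0.5 (with a warning) to keep the gamma proper.
#'
#' @param T Fisher statistic from [fisher_statistic()].
#' @param delta `d x d` matrix of pairwise covariances (diagonal ignored), or
#'   `NULL`/0 for independence.
#' @param d Number of traits.
#' @return An object of class `omga_fisher`: list with `T`, `d`, `mu`,
#'   `sigma2`, `shape`, `scale` and `p_value`.
#' @export
correlated_fisher_pvalue <- function(T, delta = NULL, d) {
  if (!is.finite(T) || T < 0) abort("T must be a non-negative number",
                                    class = "omga_input_error")
  mu <- 2 * d
  off <- 0
  if (!is.null(delta) && !identical(delta, 0)) {
    delta <- as.matrix(delta)
    if (nrow(delta) != d || ncol(delta) != d) {
      abort("delta must be d x d", class = "omga_input_error")
    }
    off <- sum(delta) - sum(diag(delta))
  }
  sigma2 <- 4 * d + off
  if (sigma2 < 0.5) {
    warn("variance of the Fisher statistic floored at 0.5")
    sigma2 <- 0.5
  }
  shape <- mu^2 / sigma2
  scale <- sigma2 / mu
  p <- pgamma(T, shape = shape, scale = scale, lower.tail = FALSE)
  structure(list(T = T, d = d, mu = mu, sigma2 = sigma2, shape = shape,
                 scale = scale, p_value = clip_p(p)),
            class = "omga_fisher")
}

#' @export
print.omga_fisher <- function(x, ...) {
  cat(sprintf("<omga_fisher> d = %d traits, T = %.4g, sigma2 = %.4g, p = %.3g\n",
              x$d, x$T, x$sigma2, x$p_value))
  invisible(x)
}

#' Multi-trait gene test from per-trait p-values
#'
#' Convenience wrapper: Fisher statistic of the `d` per-trait p-values plus
#' the gamma approximation with the supplied dependence matrix.
#'
#' @param pvals Vector of `d` per-trait p-values for one gene.
#' @param delta Optional `d x d` dependence matrix (see
#'   [estimate_pairwise_covariance()]).
#' @return An `omga_fisher` object.
#' @export
multitrait_gene_test <- function(pvals, delta = NULL) {
  correlated_fisher_pvalue(fisher_statistic(pvals), delta, d = length(pvals))
}
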