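#' Kernel U-statistic for one trait and one kernel
#'
#' `T_n = [n(n-1)]^-1 * sum_{i != j} K(X_i, X_j) r_i r_j / sigma2`, where `r`
#' are the null-model residuals and `sigma2` the null residual variance. The
#' diagonal is excluded, making the statistic a degenerate U-statistic with
#' mean approximately zero under no gene effect.
#'
#' @param kernel A normalized `kernel_matrix`.
#' @param fit A [fit_null_model()] result on the same samples.
#' @return Scalar `T_n`.
#' @export
kbt_statistic <- function(kernel, fit) {
  K <- kernel$values
  n <- fit$n
  if (nrow(K) != n) abort("kernel and null fit have different sample sizes",
                          class = "omga_input_error")
  r <- fit$residuals
  quad <- drop(crossprod(r, K %*% r)) - sum(diag(K) * r^2)
  quad / (n * (n - 1) * fit$sigma2)
}

# trace quantities of the doubly centered kernel B = HKH, H = I - J/n,
# computed in O(n^2) without forming H
kernel_traces <- function(K) {
  n <- nrow(K)
  rm_ <- rowMeans(K)
  gm <- mean(rm_)
  B <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  list(trB = sum(diag(B)), trB2 = sum(B * B), sumBii2 = sum(diag(B)^2), n = n)
}

#' Null variance of the kernel U-statistic
#'
#' Returns `V1 = tr(HK)/n` (the scale of the chi-square mixture) and the
#' moment-based estimate of `Var(n T_n)`,
#' \deqn{\hat\sigma^2_{T_n} = n^{-2}\left[(2 - 12/n^2 + 6\hat\Delta/n)\,
#'   \mathrm{tr}(B^2) - (2/n + \hat\Delta/n)\, \mathrm{tr}(B)^2 +
#'   \hat\Delta \sum_i B_{ii}^2\right],}
#' with `B = HKH` and `Delta` the excess kurtosis of the trait. The leading
#' term `2 tr(B^2)/n^2` is the Gaussian quadratic-form variance; the remaining
#' terms are finite-sample and kurtosis corrections. If the estimate is not
#' positive the Gaussian-error form `2 tr(B^2)/n^2` is used with a warning.
#'
#' @param kernel A normalized `kernel_matrix`.
#' @param delta Excess-kurtosis estimate (see [sample_kurtosis()]).
#' @param n Sample size (defaults to the kernel dimension).
#' @return List with `V1` and `sigma2_Tn`.
#' @export
kbt_variance <- function(kernel, delta, n = nrow(kernel$values)) {
  if (n < 3) abort("need n >= 3", class = "omga_input_error")
  tr <- kernel_traces(kernel$values)
  kbt_variance_from_traces(tr, delta)
}

kbt_variance_from_traces <- function(tr, delta) {
  n <- tr$n
  V1 <- tr$trB / n
  if (V1 <= sqrt(.Machine$double.eps)) {
    abort("degenerate kernel: tr(HK) is zero (kernel is constant)",
          class = "omga_degenerate_kernel_error")
  }
  s2 <- ((2 - 12 / n^2 + 6 * delta / n) * tr$trB2 -
           (2 / n + delta / n) * tr$trB^2 +
           delta * tr$sumBii2) / n^2
  if (!is.finite(s2) || s2 <= 0) {
    warn("variance estimate not positive; falling back to the Gaussian-error form")
    s2 <- 2 * tr$trB2 / n^2
  }
  list(V1 = V1, sigma2_Tn = s2)
}

#' Satterthwaite p-value for the kernel U-statistic
#'
#' The null distribution of `n T_n + V1` is approximated by a scaled
#' chi-square `a * chisq(g)` matched on mean and variance:
#' `a = sigma2_Tn / (2 V1)`, `g = V1 / a`. The p-value is the upper tail of
#' `chisq(g)` at `(n T_n + V1) / a`, clipped to `[1e-15, 1]` so downstream
#' log/tan transforms stay finite.
#'
#' @param Tn Observed statistic.
#' @param V1,sigma2_Tn Output of [kbt_variance()].
#' @param n Sample size.
#' @param mean_nTn Null mean of `n * T_n` (default 0). The chi-square-mixture
#'   theory assumes the kernel is centered so that the statistic has null mean
#'   zero; for an uncentered kernel the statistic has the permutation-exact
#'   mean `-(sum(K) - tr(K)) * (n - q - 1) / (n (n-1)^2)` (see
#'   [kbt_null_mean()]), which must be subtracted before the Satterthwaite
#'   mapping.
#' @return p-value in `[1e-15, 1]`.
#' @export
kbt_pvalue <- function(Tn, V1, sigma2_Tn, n, mean_nTn = 0) {
  vals <- c(Tn, V1, sigma2_Tn, n, mean_nTn)
  if (any(!is.finite(vals))) abort("non-finite inputs to kbt_pvalue",
                                   class = "omga_input_error")
  if (V1 <= 0 || sigma2_Tn <= 0) abort("V1 and sigma2_Tn must be positive",
                                       class = "omga_input_error")
  a <- sigma2_Tn / (2 * V1)
  g <- V1 / a
  p <- pchisq((n * Tn - mean_nTn + V1) / a, df = g, lower.tail = FALSE)
  clip_p(p)
}

#' Permutation-exact null mean of the kernel U-statistic
#'
#' Under exchangeable residuals summing to zero,
#' `E[n T_n] = -(sum(K) - tr(K)) * (n - q - 1) / (n (n - 1)^2)`.
#' This is zero for a doubly centered kernel (the setting of the asymptotic
#' theory, whose mixture of chi-squares has mean zero) but of order
#' `-(1 - V1)` for raw similarity kernels such as IBS, whose off-diagonal mass
#' is large; subtracting it aligns the statistic with the Satterthwaite
#' scaled-chi-square reference.
#'
#' @param kernel A normalized `kernel_matrix`.
#' @param n Sample size.
#' @param q Number of covariates in the null fit.
#' @return Scalar null mean of `n * T_n`.
#' @export
kbt_null_mean <- function(kernel, n = nrow(kernel$values), q = 0) {
  K <- kernel$values
  -(sum(K) - sum(diag(K))) * (n - q - 1) / (n * (n - 1)^2)
}

clip_p <- function(p, lower = 1e-15, upper = 1) pmin(pmax(p, lower), upper)

#' Permutation p-value for the kernel U-statistic
#'
#' Small-sample fallback and oracle for the analytic Satterthwaite p-value:
#' residuals are permuted jointly (the kernel stays fixed), the statistic is
#' recomputed for each permutation, and
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams kbt_statistic
#' @param n_perm Number of permutations (default 999, minimum 100).
#' @param seed Optional integer seed for the permutation stream.
#' @return p-value in `(0, 1]`.
#' @export
kbt_permutation_pvalue <- function(kernel, fit, n_perm = 999, seed = NULL) {
  if (n_perm < 100) abort("n_perm must be at least 100", class = "omga_config_error")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  K <- kernel$values
  n <- fit$n
  r <- fit$residuals
  dK <- diag(K)
  denom <- n * (n - 1) * fit$sigma2
  obs <- (drop(crossprod(r, K %*% r)) - sum(dK * r^2)) / denom
  # all permuted residual vectors as one matrix -> BLAS quadratic forms
  R <- vapply(seq_len(n_perm), function(b) r[sample.int(n)], numeric(n))
  quads <- colSums(R * (K %*% R)) - colSums(dK * R^2)
  perm <- quads / denom
  (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
}

#' Single-trait kernel association test for one gene
#'
#' Composes the pipeline for one kernel: resolve the bandwidth, build and
#' normalize the kernel, fit the covariate-only null model, compute the
#' U-statistic, its null variance and the Satterthwaite (or permutation)
#' p-value.
#'
#' @param genotypes A [genotype_matrix()] for the gene's SNPs.
#' @param phenotype Numeric trait vector.
#' @param covariates Optional covariate matrix / data frame.
#' @param spec A [kernel_spec()].
#' @param method `"satterthwaite"` (default) or `"permutation"`.
#' @param n_perm,seed Permutation controls (see [kbt_permutation_pvalue()]).
#' @param kurtosis_center Passed to [sample_kurtosis()].
#' @return An object of class `omga_kbt` with fields `Tn`, `V1`, `sigma2_Tn`,
#'   `delta`, `a`, `g`, `p_value`, `spec`, `n`, `p` (SNP count) and `method`.
#' @export
kbt_test <- function(genotypes, phenotype, covariates = NULL,
                     spec = kernel_spec("linear"),
                     method = c("satterthwaite", "permutation"),
                     n_perm = 999, seed = NULL,
                     kurtosis_center = c("mean", "residual")) {
  method <- match.arg(method)
  fit <- fit_null_model(phenotype, covariates)
  kern <- normalize_kernel(compute_raw_kernel(genotypes, spec))
  delta <- sample_kurtosis(fit, match.arg(kurtosis_center))
  vv <- kbt_variance(kern, delta, fit$n)
  Tn <- kbt_statistic(kern, fit)
  p <- if (method == "satterthwaite") {
    kbt_pvalue(Tn, vv$V1, vv$sigma2_Tn, fit$n,
               mean_nTn = kbt_null_mean(kern, fit$n, fit$q))
  } else {
    kbt_permutation_pvalue(kern, fit, n_perm = n_perm, seed = seed)
  }
  a <- vv$sigma2_Tn / (2 * vv$V1)
  structure(list(Tn = Tn, V1 = vv$V1, sigma2_Tn = vv$sigma2_Tn, delta = delta,
                 a = a, g = vv$V1 / a, p_value = p, spec = kern$spec,
                 n = fit$n, p = ncol(genotypes$values), method = method),
            class = "omga_kbt")
}

#' @export
print.omga_kbt <- function(x, ...) {
  cat(sprintf("<omga_kbt> %s kernel, n = %d, p = %d SNPs\n  Tn = %.4g, V1 = %.4g, p-value = %.3g (%s)\n",
              x$spec$family, x$n, x$p, x$Tn, x$V1, x$p_value, x$method))
  invisible(x)
}
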