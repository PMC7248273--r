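#' Specify a candidate kernel
#'
#' A kernel specification names a similarity family and a bandwidth. The three
#' families are the candidate kernels used throughout the package:
#' \describe{
#'   \item{linear}{`K(x_i, x_j) = x_i' x_j / theta`, the linear (additive
#'     dosage) kernel.}
#'   \item{ibs}{identity-by-state similarity
#'     `K(x_i, x_j) = sum_k (2 - |x_ik - x_jk|) / (2p)`, in \[0, 1\];
#'     bandwidth-free.}
#'   \item{gaussian}{`K(x_i, x_j) = exp(-||x_i - x_j||^2 / theta)`, capturing
#'     smooth nonlinear joint effects.}
#' }
#'
#' @param family One of `"linear"`, `"ibs"`, `"gaussian"`.
#' @param bandwidth Positive scalar, or `"auto"` (the default) to resolve a
#'   data-driven value via [resolve_bandwidth()]: `theta = p` for the linear
#'   kernel and the median pairwise squared Euclidean distance (median
#'   heuristic) for the Gaussian kernel.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "ibs", "gaussian"), bandwidth = "auto") {
  family <- match.arg(family)
  if (!identical(bandwidth, "auto")) {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1L || !is.finite(bandwidth) ||
        bandwidth <= 0) {
      abort("bandwidth must be a positive scalar or \"auto\"", class = "omga_config_error")
    }
  }
  structure(list(family = family, bandwidth = bandwidth), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> family = %s, bandwidth = %s\n", x$family,
              if (identical(x$bandwidth, "auto")) "auto" else format(x$bandwidth)))
  invisible(x)
}

#' Default candidate kernel set
#'
#' The linear, IBS and Gaussian kernels with automatic bandwidths — the
#' candidate set combined by the omnibus test.
#' @return List of three [kernel_spec()] objects.
#' @export
default_kernels <- function() {
  list(kernel_spec("linear"), kernel_spec("ibs"), kernel_spec("gaussian"))
}

#' Resolve an automatic kernel bandwidth
#'
#' Linear kernel: `theta = p` (the SNP count), so entries are average per-SNP
#' products. Gaussian kernel: the median heuristic — the median of pairwise
#' squared Euclidean distances over distinct sample pairs — falling back to `p`
#' (with a warning) when all pairwise distances are zero. The IBS kernel has no
#' bandwidth; 1 is returned.
#'
#' @param genotypes A [genotype_matrix()].
#' @param spec A [kernel_spec()].
#' @return Positive scalar bandwidth.
#' @export
resolve_bandwidth <- function(genotypes, spec) {
  if (!identical(spec$bandwidth, "auto")) return(spec$bandwidth)
  p <- ncol(genotypes$values)
  switch(spec$family,
    linear = p,
    ibs = 1,
    gaussian = {
      d2 <- pairwise_sqdist(genotypes$values)
      med <- median(d2[upper.tri(d2)])
      if (!is.finite(med) || med <= 0) {
        warn("all pairwise genotype distances are zero; falling back to bandwidth = p")
        p
      } else med
    }
  )
}

pairwise_sqdist <- function(X) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' Compute a raw kernel matrix
#'
#' Evaluates the kernel family of `spec` on every pair of samples. Bandwidths
#' given as `"auto"` are resolved first.
#'
#' @inheritParams resolve_bandwidth
#' @return An object of class `kernel_matrix`: list with the `n x n` matrix
#'   `values`, the resolved `spec`, and `is_normalized = FALSE`.
#' @export
compute_raw_kernel <- function(genotypes, spec) {
  X <- genotypes$values
  if (ncol(X) == 0L) abort("empty SNP set", class = "omga_empty_gene_error")
  theta <- resolve_bandwidth(genotypes, spec)
  K <- switch(spec$family,
    linear = tcrossprod(X) / theta,
    ibs = {
      p <- ncol(X)
      M <- as.matrix(stats::dist(X, method = "manhattan"))
      1 - M / (2 * p)
    },
    gaussian = exp(-pairwise_sqdist(X) / theta)
  )
  K <- (K + t(K)) / 2   # enforce exact symmetry against float noise
  dimnames(K) <- NULL
  structure(list(values = K, spec = kernel_spec(spec$family, theta),
                 is_normalized = FALSE),
            class = "kernel_matrix")
}

#' Normalize a kernel matrix
#'
#' Scales a raw kernel so that the mean diagonal entry is 1, the sample
#' estimate of dividing by `E K(X, X)` for identically distributed samples.
#' This keeps the kernel positive semidefinite and puts all candidate kernels
#' on the scale assumed by the test's variance estimator. Idempotent.
#'
#' @param raw A `kernel_matrix` (raw or already normalized).
#' @return A normalized `kernel_matrix`.
#' @export
normalize_kernel <- function(raw) {
  if (isTRUE(raw$is_normalized)) return(raw)
  dbar <- mean(diag(raw$values))
  if (!is.finite(dbar) || dbar <= 0) {
    abort("degenerate kernel: mean diagonal is not positive",
          class = "omga_degenerate_kernel_error")
  }
  structure(list(values = raw$values / dbar, spec = raw$spec, is_normalized = TRUE),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d, family = %s, %s\n", nrow(x$values),
              ncol(x$values), x$spec$family,
              if (isTRUE(x$is_normalized)) "normalized" else "raw"))
  invisible(x)
}
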