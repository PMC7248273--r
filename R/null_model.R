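#' Fit the covariate-only null model for one trait
#'
#' Least-squares fit of `Y = mu + alpha' W + e`. The residuals, fitted values
#' and residual variance of this fit are the ingredients of the kernel
#' U-statistic: the gene effect is tested on the residual scale after
#' adjusting for covariates. An intercept is always prepended; a user-supplied
#' constant column is rejected.
#'
#' @param phenotype Numeric vector of length `n`.
#' @param covariates `n x q` numeric matrix or data frame of covariates, or
#'   `NULL` for an intercept-only fit.
#' @return An object of class `null_model_fit` with elements `fitted`,
#'   `residuals`, `sigma2` (divisor `n - q - 1`), `n`, `q`, `qr` (the QR
#'   factorization of the design) and `y`.
#' @export
fit_null_model <- function(phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (anyNA(y)) abort("phenotype contains NA", class = "omga_input_error")
  W <- prepare_design(covariates, n)
  q <- ncol(W) - 1L
  if (n <= q + 1L) abort("need n > q + 1 for the null fit", class = "omga_input_error")
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1L):ncol(W)]]
    abort(paste0("rank-deficient null design; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "omga_rank_error")
  }
  fitted <- qr.fitted(qrW, y)
  res <- y - fitted
  sigma2 <- sum(res^2) / (n - q - 1L)
  if (sigma2 <= .Machine$double.eps * max(1, mean(y^2))) {
    abort("degenerate phenotype: residual variance is zero",
          class = "omga_degenerate_phenotype_error")
  }
  structure(list(fitted = fitted, residuals = res, sigma2 = sigma2,
                 n = n, q = q, qr = qrW, y = y),
            class = "null_model_fit")
}

prepare_design <- function(covariates, n) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0L)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  W <- as.matrix(as.data.frame(covariates))
  storage.mode(W) <- "double"
  if (nrow(W) != n) abort("covariate rows do not match phenotype length",
                          class = "omga_input_error")
  if (anyNA(W)) abort("covariates contain NA", class = "omga_input_error")
  const <- apply(W, 2, function(col) all(col == col[1]))
  if (any(const)) {
    abort("constant covariate column supplied; the intercept is added automatically",
          class = "omga_input_error")
  }
  cbind(`(Intercept)` = 1, W)
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("<null_model_fit> n = %d, covariates = %d, sigma2 = %.4g\n",
              x$n, x$q, x$sigma2))
  invisible(x)
}

#' Excess kurtosis estimate used by the variance estimator
#'
#' `Delta = mean(((Y_i - Ybar) / sigma_hat)^4) - 3`, with `sigma_hat` the
#' square root of the null fit's residual variance. The default centers by the
#' raw phenotype mean; `center = "residual"` instead standardizes the null-fit
#' residuals, which is the natural choice when covariates explain a
#' non-negligible share of the phenotype variance.
#'
#' @param fit A [fit_null_model()] result.
#' @param center `"mean"` (default) or `"residual"`.
#' @return Scalar excess-kurtosis estimate.
#' @export
sample_kurtosis <- function(fit, center = c("mean", "residual")) {
  center <- match.arg(center)
  s <- sqrt(fit$sigma2)
  z <- switch(center,
              mean = (fit$y - mean(fit$y)) / s,
              residual = fit$residuals / s)
  mean(z^4) - 3
}
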