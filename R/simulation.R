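#' Simulate LD-structured SNP genotypes
#'
#' Generates two haplotypes per sample from a latent Gaussian with AR(1)
#' correlation `ld_decay` across SNPs; each latent value is thresholded at the
#' quantile matching a per-SNP minor allele frequency drawn uniformly from
#' `maf_range`, and the genotype is the haplotype sum in \{0, 1, 2\}. The
#' AR(1) latent structure induces linkage-disequilibrium-like correlation that
#' decays with SNP distance, emulating the local structure of a gene.
#'
#' @param n Sample size.
#' @param p Number of SNPs.
#' @param maf_range Length-2 vector, bounds of the uniform MAF distribution
#'   (default `c(0.05, 0.5)`).
#' @param ld_decay AR(1) correlation of the latent Gaussian in `[0, 1)`
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] with synthetic metadata (chromosome `"1"`,
#'   positions 10 kb apart).
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), ld_decay = 0.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(maf_range[1] > 0, maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
            ld_decay >= 0, ld_decay < 1)
  maf <- runif(p, maf_range[1], maf_range[2])
  thr <- qnorm(maf)
  geno <- matrix(0, n, p)
  for (h in 1:2) {
    Z <- matrix(rnorm(n * p), n, p)
    if (ld_decay > 0 && p > 1) {
      s <- sqrt(1 - ld_decay^2)
      for (k in 2:p) Z[, k] <- ld_decay * Z[, k - 1] + s * Z[, k]
    }
    geno <- geno + (Z < matrix(thr, n, p, byrow = TRUE))
  }
  genotype_matrix(geno,
                  snps = tibble(id = paste0("snp", seq_len(p)), chr = "1",
                                pos = 10000L * seq_len(p)))
}

#' Frozen effect configuration for the polygenic scenarios
#'
#' Draws, once, the 10 main-effect SNPs `S_M`, the 30 interacting SNP pairs
#' `S_N`, and their effect sizes `alpha_k`, `beta_kk'` from `Unif(0, 0.02)`.
#' The default seed freezes the configuration so that all replicates of a
#' simulation share the same effects.
#'
#' @param p Number of SNPs (>= 20 so that main and pair sets fit).
#' @param seed Integer seed (default 20200519).
#' @return List of class `omga_effects`: `S_M` (10 indices), `alpha` (10),
#'   `S_N` (30 x 2 index matrix), `beta` (30).
#' @export
simulate_effects <- function(p, seed = 20200519) {
  if (p < 20) abort("need p >= 20 for the polygenic effect sets", class = "omga_config_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  S_M <- sort(sample.int(p, 10))
  all_pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  S_N <- all_pairs[sample.int(nrow(all_pairs), 30), , drop = FALSE]
  structure(list(S_M = S_M, alpha = runif(10, 0, 0.02),
                 S_N = unname(S_N), beta = runif(30, 0, 0.02)),
            class = "omga_effects")
}

#' Gene-effect mean function for each simulation scenario
#'
#' \describe{
#'   \item{null}{`h(x) = 0` — no gene effect.}
#'   \item{A}{`0.2 (x_1 - x_6) + cos(x_6) exp(-x_6^2 / 4)` — main effects of
#'     opposite sign plus a nonlinear effect of SNP 6.}
#'   \item{B}{`0.3 x_2 + 0.6 x_4 - 0.07 x_8` — purely linear effects.}
#'   \item{C}{`0.02 * sum(alpha_k x_k) + 1.8 * sum(beta_kk' x_k x_k')` — weak
#'     main effects with strong pairwise interactions.}
#'   \item{D}{`3.8 * sum(alpha_k x_k)` — pure polygenic main effects.}
#' }
#'
#' @param genotypes A [genotype_matrix()] (or bare matrix) with `p >= 8`.
#' @param scenario One of `"null"`, `"A"`, `"B"`, `"C"`, `"D"`.
#' @param effects An [simulate_effects()] object (required for C and D).
#' @return Numeric vector `h` of length `n`.
#' @export
scenario_mean <- function(genotypes, scenario = c("null", "A", "B", "C", "D"),
                          effects = NULL) {
  scenario <- match.arg(scenario)
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$values else as.matrix(genotypes)
  X <- unname(X)
  if (scenario == "null") return(rep(0, nrow(X)))
  if (ncol(X) < 8) abort("scenarios need p >= 8", class = "omga_config_error")
  switch(scenario,
    A = 0.2 * (X[, 1] - X[, 6]) + cos(X[, 6]) * exp(-X[, 6]^2 / 4),
    B = 0.3 * X[, 2] + 0.6 * X[, 4] - 0.07 * X[, 8],
    C = {
      check_effects(effects, ncol(X))
      0.02 * drop(X[, effects$S_M, drop = FALSE] %*% effects$alpha) +
        1.8 * drop((X[, effects$S_N[, 1], drop = FALSE] *
                      X[, effects$S_N[, 2], drop = FALSE]) %*% effects$beta)
    },
    D = {
      check_effects(effects, ncol(X))
      3.8 * drop(X[, effects$S_M, drop = FALSE] %*% effects$alpha)
    })
}

check_effects <- function(effects, p) {
  if (is.null(effects)) abort("scenarios C and D need an effects configuration",
                              class = "omga_config_error")
  if (max(effects$S_M, effects$S_N) > p) {
    abort("effect configuration indexes SNPs beyond p", class = "omga_config_error")
  }
  invisible(effects)
}

#' Simulate correlated multi-trait phenotypes
#'
#' `Y_ij = 0.02 Z_i1 + 0.6 Z_i2 + h(X_i) + e_ij`, with covariates
#' `Z1 ~ N(2, 1)` and `Z2 ~ Bernoulli(0.6)`, and errors
#' `e_i ~ MVN(0, Sigma)` with compound-symmetry `Sigma` (unit variances,
#' common correlation `rho`). The scalar gene effect `h(X_i)` enters every
#' trait — the pleiotropy setting the multi-trait test is designed for.
#'
#' @param genotypes A [genotype_matrix()].
#' @param scenario,effects Passed to [scenario_mean()].
#' @param d Number of traits (default 5).
#' @param rho Common trait correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return List with `phenotypes` (`n x d` matrix) and `covariates`
#'   (data frame with `Z1`, `Z2`).
#' @export
simulate_traits <- function(genotypes, scenario = "null", effects = NULL,
                            d = 5, rho = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rho >= 0, rho < 1, d >= 1)
  X <- genotypes$values
  n <- nrow(X)
  h <- scenario_mean(genotypes, scenario, effects)
  Z1 <- rnorm(n, 2, 1)
  Z2 <- rbinom(n, 1, 0.6)
  # compound-symmetry errors: sqrt(rho) * shared + sqrt(1 - rho) * idiosyncratic
  eps <- sqrt(rho) * matrix(rnorm(n), n, d) + sqrt(1 - rho) * matrix(rnorm(n * d), n, d)
  Y <- matrix(0.02 * Z1 + 0.6 * Z2 + h, n, d) + eps
  colnames(Y) <- paste0("trait", seq_len(d))
  list(phenotypes = Y, covariates = data.frame(Z1 = Z1, Z2 = Z2))
}

# per-trait omnibus p-values for one replicate, sharing kernels across traits.
# Y: n x d matrix; W: covariate data frame/matrix. Returns d-vector.
omnibus_pvalues_multi <- function(genotypes, Y, covariates, specs = default_kernels(),
                                  kurtosis_center = "mean") {
  n <- nrow(Y); d <- ncol(Y)
  W <- prepare_design(covariates, n)
  qrW <- qr(W)
  R <- qr.resid(qrW, Y)                        # n x d residual matrix
  dfres <- n - ncol(W)
  sigma2 <- colSums(R^2) / dfres
  s <- sqrt(sigma2)
  delta <- if (kurtosis_center == "mean") {
    Yc <- sweep(Y, 2, colMeans(Y))
    colMeans(sweep(Yc, 2, s, "/")^4) - 3
  } else {
    colMeans(sweep(R, 2, s, "/")^4) - 3
  }
  pk <- matrix(NA_real_, length(specs), d)
  for (i in seq_along(specs)) {
    kern <- normalize_kernel(compute_raw_kernel(genotypes, specs[[i]]))
    K <- kern$values
    tr <- kernel_traces(K)
    mu <- kbt_null_mean(kern, n, ncol(W) - 1L)
    KR <- K %*% R
    quads <- colSums(R * KR) - colSums(diag(K) * R^2)
    Tn <- quads / (n * (n - 1) * sigma2)
    for (j in seq_len(d)) {
      vv <- kbt_variance_from_traces(tr, delta[j])
      pk[i, j] <- kbt_pvalue(Tn[j], vv$V1, vv$sigma2_Tn, n, mean_nTn = mu)
    }
  }
  apply(pk, 2, function(col) cauchy_combination(col)$p_value)
}

#' Empirical rejection rate of the full pipeline under simulation
#'
#' Runs `reps` independent replicates of the generating model (fresh genotypes,
#' covariates and traits per replicate), tests each with either the omnibus
#' multi-trait pipeline (`"omga"`) or the per-SNP MANOVA minimum-p comparator
#' (`"manova_minp"`), and reports the fraction of replicates rejecting at
#' level `alpha`. Under the null scenario this is the empirical type-I error;
#' under scenarios A–D it is the empirical power. For the omga method the
#' `-2 log p` dependence matrix is estimated once, pooled across replicates.
#'
#' @param scenario `"null"`, `"A"`, `"B"`, `"C"` or `"D"`.
#' @param n,p Sample size and SNP count.
#' @param d Number of traits (default 5).
#' @param rho Trait correlation (default 0.3).
#' @param reps Number of replicates (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param method `"omga"` or `"manova_minp"`.
#' @param seed Integer seed for the whole run.
#' @param effects Effect configuration for scenarios C/D; defaults to
#'   [simulate_effects()] with its frozen seed.
#' @param maf_range,ld_decay Passed to [simulate_genotypes()].
#' @param manova_adjust Within-gene adjustment for the comparator
#'   (`"sidak"` or `"none"`).
#' @param force_independent If `TRUE` the Fisher combination ignores trait
#'   dependence (`delta = 0`) — used to demonstrate that the dependence
#'   correction is load-bearing.
#' @return One-row tibble of class `omga_sim`: scenario, n, p, d, rho, method,
#'   reps, `rate`, and Wilson 95% interval (`conf_low`, `conf_high`).
#' @export
empirical_rejection_rate <- function(scenario = "null", n = 100, p = 50, d = 5,
                                     rho = 0.3, reps = 1000, alpha = 0.05,
                                     method = c("omga", "manova_minp"),
                                     seed = NULL, effects = NULL,
                                     maf_range = c(0.05, 0.5), ld_decay = 0.5,
                                     manova_adjust = "sidak",
                                     force_independent = FALSE) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (scenario %in% c("C", "D") && is.null(effects)) effects <- simulate_effects(p)

  if (method == "omga") {
    P <- matrix(NA_real_, reps, d)
    for (b in seq_len(reps)) {
      geno <- simulate_genotypes(n, p, maf_range, ld_decay)
      sim <- simulate_traits(geno, scenario, effects, d = d, rho = rho)
      P[b, ] <- omnibus_pvalues_multi(geno, sim$phenotypes, sim$covariates)
    }
    delta <- if (force_independent || d == 1) NULL else estimate_pairwise_covariance(P)
    pg <- apply(P, 1, function(pr) multitrait_gene_test(pr, delta)$p_value)
  } else {
    pg <- numeric(reps)
    for (b in seq_len(reps)) {
      geno <- simulate_genotypes(n, p, maf_range, ld_decay)
      sim <- simulate_traits(geno, scenario, effects, d = d, rho = rho)
      pg[b] <- manova_minp_gene_test(geno, sim$phenotypes, sim$covariates,
                                     adjust = manova_adjust)
    }
  }
  rate <- mean(pg < alpha)
  ci <- wilson_interval(sum(pg < alpha), reps)
  out <- tibble(scenario = scenario, n = n, p = p, d = d, rho = rho,
                method = method, reps = reps, alpha = alpha, rate = rate,
                conf_low = ci[1], conf_high = ci[2])
  class(out) <- c("omga_sim", class(out))
  out
}

wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- x / n
  den <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Per-SNP MANOVA minimum-p comparator
#'
#' For each SNP, a one-way MANOVA (Pillai trace) of the `d` traits on the SNP
#' dosage adjusted for covariates; the gene-level p-value is the minimum over
#' SNPs, by default with a within-gene Sidak adjustment
#' `1 - (1 - p_min)^p` (the unadjusted minimum is available with
#' `adjust = "none"`). The Pillai trace is computed from the residual
#' cross-products of the multivariate linear model, which is algebraically
#' identical to `stats::manova` with a single-df hypothesis.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes `n x d` trait matrix, `d >= 2`.
#' @param covariates Optional covariates.
#' @param adjust `"sidak"` (default) or `"none"`.
#' @return Gene-level p-value.
#' @export
manova_minp_gene_test <- function(genotypes, phenotypes, covariates = NULL,
                                  adjust = c("sidak", "none")) {
  adjust <- match.arg(adjust)
  Y <- as.matrix(phenotypes)
  d <- ncol(Y)
  if (d < 2) abort("MANOVA comparator needs d >= 2 traits", class = "omga_input_error")
  X <- genotypes$values
  n <- nrow(X)
  W <- prepare_design(covariates, n)
  qrW <- qr(W)
  RY <- qr.resid(qrW, Y)                 # traits residualized on covariates
  S <- crossprod(RY)                     # total (reduced-model) SSCP = H + E
  Sinv <- tryCatch(solve(S), error = function(e)
    abort("singular trait cross-product matrix", class = "omga_input_error"))
  RX <- qr.resid(qrW, X)                 # SNPs residualized on covariates
  ne <- n - ncol(W) - 1L                 # residual df of the full model
  if (ne <= d) abort("too few samples for the MANOVA comparator", class = "omga_input_error")
  xss <- colSums(RX^2)
  usable <- xss > 1e-10 * n
  if (!any(usable)) abort("no usable SNPs (all constant given covariates)",
                          class = "omga_input_error")
  if (any(!usable)) warn(sprintf("skipping %d SNP(s) with no residual variance",
                                 sum(!usable)))
  U <- crossprod(RY, RX[, usable, drop = FALSE])   # d x p' matrix of RY' x
  V <- colSums(U * (Sinv %*% U)) / xss[usable]     # Pillai trace per SNP (s = 1)
  V <- pmin(pmax(V, 0), 1 - 1e-12)
  Fstat <- ((ne - d + 1) / d) * V / (1 - V)
  pv <- pf(Fstat, d, ne - d + 1, lower.tail = FALSE)
  pmin_ <- min(pv)
  if (adjust == "sidak") 1 - (1 - pmin_)^sum(usable) else pmin_
}
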