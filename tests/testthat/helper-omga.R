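# small fixture builders shared across test files

toy_genotypes <- function(values, chr = "1") {
  values <- as.matrix(values)
  genotype_matrix(values,
                  snps = tibble::tibble(id = paste0("s", seq_len(ncol(values))),
                                        chr = chr, pos = 1000L * seq_len(ncol(values))))
}

# wrap an arbitrary symmetric matrix as a kernel_matrix (for algebraic identities)
as_kernel <- function(M, normalized = FALSE, family = "linear") {
  structure(list(values = as.matrix(M), spec = omga::kernel_spec(family, 1),
                 is_normalized = normalized),
            class = "kernel_matrix")
}

# brute-force U-statistic over ordered pairs i != j
brute_force_Tn <- function(K, residuals, sigma2) {
  n <- length(residuals)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s <- s + K[i, j] * residuals[i] * residuals[j]
  }
  s / (n * (n - 1) * sigma2)
}
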