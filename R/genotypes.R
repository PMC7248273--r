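#' Construct a genotype matrix object
#'
#' Bundles an additive-coded (0/1/2 minor-allele count) genotype matrix with
#' per-SNP metadata and sample identifiers. Missing genotypes are mean-imputed
#' per SNP, the standard practice for kernel association tests, so downstream
#' kernels always see a complete matrix.
#'
#' @param values Numeric matrix, samples in rows and SNPs in columns. Entries
#'   must lie in \[0, 2\] (or be `NA` before imputation).
#' @param snps Data frame of per-SNP metadata with columns `id`, `chr`, `pos`
#'   and optionally `a1`, `a2` (allele labels). Defaults are generated when
#'   omitted.
#' @param samples Character vector of sample ids; defaults to the row names of
#'   `values` or `sample1..n`.
#' @param impute Mean-impute missing entries per SNP (default `TRUE`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snps` (tibble) and `samples`.
#' @export
genotype_matrix <- function(values, snps = NULL, samples = NULL, impute = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2L) abort("need at least 2 samples", class = "omga_input_error")
  if (p < 1L) abort("empty SNP set (no genotype columns)", class = "omga_empty_gene_error")

  if (anyNA(values)) {
    if (!impute) abort("missing genotypes present and impute = FALSE", class = "omga_input_error")
    values <- impute_genotypes(values)
  }
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("genotype values must lie in [0, 2] (additive minor-allele counts)",
          class = "omga_input_error")
  }

  if (is.null(samples)) {
    samples <- rownames(values) %||% paste0("sample", seq_len(n))
  }
  if (is.null(snps)) {
    ids <- colnames(values) %||% paste0("snp", seq_len(p))
    snps <- tibble(id = ids, chr = "1", pos = seq_len(p))
  } else {
    snps <- as_tibble(snps)
    stopifnot(all(c("id", "chr", "pos") %in% names(snps)), nrow(snps) == p)
    if (any(snps$pos < 0)) abort("SNP positions must be non-negative", class = "omga_input_error")
  }
  snps$chr <- harmonize_chr(snps$chr)
  dimnames(values) <- list(samples, snps$id)
  structure(list(values = values, snps = snps, samples = samples),
            class = "genotype_matrix")
}

impute_genotypes <- function(values) {
  cm <- colMeans(values, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(values), arr.ind = TRUE)
  values[idx] <- cm[idx[, 2L]]
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, chromosomes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$snps$chr), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# subset SNP columns, keeping metadata aligned
subset_snps <- function(geno, j) {
  genotype_matrix(geno$values[, j, drop = FALSE], snps = geno$snps[j, , drop = FALSE],
                  samples = geno$samples)
}

# "chr1"/"Chr1"/"1" -> "1"; comparisons are case-insensitive
harmonize_chr <- function(x) sub("^chr", "", tolower(as.character(x)))

#' Read a delimited samples-by-SNPs genotype matrix
#'
#' Expects a header of SNP ids and one row per sample; the first column may be
#' a sample id column (detected when it is non-numeric). Entries are additive
#' minor-allele counts 0/1/2, with `NA` allowed (mean-imputed).
#'
#' @param path File path of the delimited table.
#' @param sep Field separator (default tab).
#' @param snps Optional SNP metadata passed on to [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, sep = "\t", snps = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- NULL
  if (ncol(tab) > 1 && !is.numeric(tab[[1]])) {
    samples <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  m <- as.matrix(tab)
  genotype_matrix(m, snps = snps, samples = samples)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Minimal reader for the SNP-major PLINK 1 binary format. The returned dosage
#' counts the A1 allele of the .bim file (PLINK convention: A1 is usually the
#' minor allele); missing calls are mean-imputed per SNP.
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam` must
#'   exist.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(paste0("missing PLINK file: ", f), class = "omga_input_error")
  }
  bim_tab <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam_tab <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_tab); p <- nrow(bim_tab)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)", class = "omga_input_error")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("only SNP-major .bed files are supported", class = "omga_input_error")
  }
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * p) {
    abort(".bed size inconsistent with .bim/.fam dimensions", class = "omga_input_error")
  }
  # 2-bit codes per sample: 00 = 2 copies of A1, 10 = het, 11 = 0 copies, 01 = missing
  bits <- matrix(as.integer(rawToBits(body)), nrow = 2L)
  code <- bits[1L, ] + 2L * bits[2L, ]                  # low bit first
  code <- matrix(code, nrow = 4L * bytes_per_snp)[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  geno <- matrix(lookup[code + 1L], nrow = n, ncol = p)
  genotype_matrix(geno,
                  snps = tibble(id = bim_tab$id, chr = bim_tab$chr, pos = bim_tab$pos,
                                a1 = bim_tab$a1, a2 = bim_tab$a2),
                  samples = as.character(fam_tab[[2]]))
}

# internal writer, used to build round-trip fixtures at test time
write_plink <- function(geno, prefix) {
  X <- geno$values
  n <- nrow(X); p <- ncol(X)
  code <- matrix(3L, nrow = n, ncol = p)   # 11 = 0 copies of A1
  code[X == 1] <- 2L                       # 10 = het
  code[X == 2] <- 0L                       # 00 = 2 copies
  code[is.na(X)] <- 1L                     # 01 = missing
  bytes_per_snp <- ceiling(n / 4)
  pad <- matrix(0L, nrow = 4L * bytes_per_snp - n, ncol = p)
  code <- rbind(code, pad)
  code <- as.integer(code)
  bits <- rbind(code %% 2L, code %/% 2L)   # interleave low/high bit per sample
  body <- packBits(as.logical(bits), type = "raw")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), body), paste0(prefix, ".bed"))
  snps <- geno$snps
  a1 <- if ("a1" %in% names(snps)) snps$a1 else rep("A", p)
  a2 <- if ("a2" %in% names(snps)) snps$a2 else rep("G", p)
  utils::write.table(data.frame(snps$chr, snps$id, 0, snps$pos, a1, a2),
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(geno$samples, geno$samples, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
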