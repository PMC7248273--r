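#' Filter SNPs by minor allele frequency
#'
#' The allele frequency of a SNP is `f = mean(genotype) / 2`; its MAF is
#' `min(f, 1 - f)`. SNPs with MAF strictly below `threshold` are removed
#' (a SNP at exactly the threshold is retained). The number removed is
#' reported via a message.
#'
#' @param genotypes A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.05).
#' @return The filtered [genotype_matrix()].
#' @export
maf_filter <- function(genotypes, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) {
    abort("MAF threshold must lie in [0, 0.5]", class = "omga_config_error")
  }
  f <- colMeans(genotypes$values) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold
  if (!any(keep)) abort("all SNPs removed by the MAF filter",
                        class = "omga_empty_panel_error")
  if (any(!keep)) inform(sprintf("maf_filter: removed %d of %d SNPs (MAF < %g)",
                                 sum(!keep), length(keep), threshold))
  subset_snps(genotypes, which(keep))
}

#' Filter SNPs by a Hardy-Weinberg chi-square test
#'
#' Auxiliary quality-control filter: a 1-df goodness-of-fit chi-square of the
#' observed genotype counts against Hardy-Weinberg proportions, per SNP; SNPs
#' with a p-value below `alpha` are removed. This is the simple asymptotic
#' chi-square, not an exact test, and is meant for coarse pre-filtering; many
#' cohorts apply HWE filtering upstream of association testing.
#'
#' @param genotypes A [genotype_matrix()] (hard 0/1/2 calls; imputed fractional
#'   values are rounded for counting).
#' @param alpha Removal threshold on the HWE p-value (default 1e-6).
#' @return The filtered [genotype_matrix()].
#' @export
hwe_filter <- function(genotypes, alpha = 1e-6) {
  X <- round(genotypes$values)
  n <- nrow(X)
  n2 <- colSums(X == 2); n1 <- colSums(X == 1); n0 <- n - n2 - n1
  f <- (2 * n2 + n1) / (2 * n)
  exp0 <- n * (1 - f)^2; exp1 <- 2 * n * f * (1 - f); exp2 <- n * f^2
  chi <- rep(0, ncol(X))
  ok <- f > 0 & f < 1
  chi[ok] <- (n0[ok] - exp0[ok])^2 / exp0[ok] +
    (n1[ok] - exp1[ok])^2 / exp1[ok] +
    (n2[ok] - exp2[ok])^2 / exp2[ok]
  pv <- pchisq(chi, df = 1, lower.tail = FALSE)
  keep <- pv >= alpha
  if (!any(keep)) abort("all SNPs removed by the HWE filter",
                        class = "omga_empty_panel_error")
  if (any(!keep)) inform(sprintf("hwe_filter: removed %d of %d SNPs (HWE p < %g)",
                                 sum(!keep), length(keep), alpha))
  subset_snps(genotypes, which(keep))
}

#' Read gene annotations from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' closed convention used internally (start + 1). Columns used: chrom, start,
#' end, name (a name `gene1..G` is generated when absent).
#'
#' @param path BED file path (tab-separated, no header).
#' @return Tibble with columns `gene`, `chr`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) abort("BED file needs at least 3 columns", class = "omga_input_error")
  genes <- if (ncol(tab) >= 4) as.character(tab[[4]]) else paste0("gene", seq_len(nrow(tab)))
  tibble(gene = genes, chr = harmonize_chr(tab[[1]]),
         start = as.integer(tab[[2]]) + 1L, end = as.integer(tab[[3]]))
}

#' Map SNPs to genes with a flanking window
#'
#' A SNP belongs to a gene when the chromosome labels match (case-insensitive,
#' `chr` prefix stripped) and its position lies in the closed interval
#' `[start - window, end + window]` (1-based coordinates). A SNP may map to
#' several overlapping genes. Genes with no SNPs are dropped with a message.
#'
#' @param variants Data frame of SNP metadata with columns `id`, `chr`, `pos`
#'   (e.g. the `snps` element of a [genotype_matrix()]).
#' @param annotation Data frame with columns `gene`, `chr`, `start`, `end`
#'   (1-based closed; see [read_gene_bed()] for BED input).
#' @param window Flank size in base pairs added on both sides (>= 0).
#' @return Named list mapping gene name to an integer vector of SNP column
#'   indices into `variants`.
#' @export
map_snps_to_genes <- function(variants, annotation, window = 0) {
  if (window < 0) abort("window must be >= 0", class = "omga_config_error")
  variants <- as_tibble(variants)
  annotation <- as_tibble(annotation)
  stopifnot(all(c("chr", "pos") %in% names(variants)),
            all(c("gene", "chr", "start", "end") %in% names(annotation)))
  if (any(annotation$start > annotation$end)) {
    abort("annotation has start > end", class = "omga_input_error")
  }
  vchr <- harmonize_chr(variants$chr)
  achr <- harmonize_chr(annotation$chr)
  out <- vector("list", nrow(annotation))
  names(out) <- annotation$gene
  for (g in seq_len(nrow(annotation))) {
    on_chr <- which(vchr == achr[g])
    pos <- variants$pos[on_chr]
    hit <- pos >= annotation$start[g] - window & pos <= annotation$end[g] + window
    out[[g]] <- on_chr[hit]
  }
  n_empty <- sum(lengths(out) == 0L)
  if (n_empty == length(out)) {
    abort("no gene overlaps any SNP; check coordinates and chromosome labels",
          class = "omga_empty_scan_error")
  }
  if (n_empty > 0) inform(sprintf("map_snps_to_genes: dropped %d gene(s) with no SNPs",
                                  n_empty))
  out[lengths(out) > 0L]
}

#' Adjust gene-level p-values for multiple testing
#'
#' Bonferroni (with the gene-level significance threshold `alpha / m`) or
#' Benjamini–Hochberg step-up.
#'
#' @param p Vector of p-values.
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha Family-wise / FDR level (default 0.05).
#' @return List with `adjusted` (vector), `threshold` (raw-scale threshold for
#'   Bonferroni, `NA` for BH) and `significant` (logical vector).
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  m <- length(p)
  adj <- p.adjust(p, method = ifelse(method == "bh", "BH", "bonferroni"))
  thr <- if (method == "bonferroni") alpha / m else NA_real_
  list(adjusted = adj, threshold = thr, significant = adj <= alpha)
}

#' Genome-wide gene-based multi-trait scan
#'
#' For every annotated gene: extract its SNPs, run the omnibus kernel test per
#' trait, then combine the per-trait p-values with the correlated Fisher
#' statistic. The dependence matrix of `-2 log p` is estimated empirically
#' across genes when at least `min_genes_for_delta` genes are scanned,
#' otherwise from the trait correlations via the Kost–McDermott polynomial.
#' Genes whose test fails are reported with a reason code, never dropped
#' silently.
#'
#' @param genotypes A [genotype_matrix()] for the full SNP panel (after any
#'   [maf_filter()]).
#' @param phenotypes `n x d` matrix or data frame of quantitative traits.
#' @param covariates Optional covariate matrix / data frame.
#' @param annotation Gene annotation (see [map_snps_to_genes()]).
#' @param window Mapping window in base pairs.
#' @param specs Candidate kernels (default [default_kernels()]).
#' @param adjust Multiple-testing method(s), subset of
#'   `c("bonferroni", "bh")`.
#' @param alpha Significance level for adjustment (default 0.05).
#' @param min_genes_for_delta Minimum scanned genes for the empirical
#'   dependence estimator (default 50; values below 50 have no effect because
#'   the estimator itself refuses fewer genes).
#' @param ... Passed to [omnibus_gene_test()].
#' @return A tibble of class `omga_scan`, one row per gene ordered by
#'   (chromosome, start): `gene`, `chr`, `start`, `end`, `n_snps`, one
#'   `p_<trait>` column per trait, `p_multi`, adjusted columns, and `status`.
#'   The estimated dependence matrix is attached as attribute `delta`.
#' @export
run_genome_scan <- function(genotypes, phenotypes, covariates = NULL, annotation,
                            window = 0, specs = default_kernels(),
                            adjust = c("bonferroni", "bh"), alpha = 0.05,
                            min_genes_for_delta = 50, ...) {
  Y <- as.matrix(phenotypes)
  storage.mode(Y) <- "double"
  if (nrow(Y) != nrow(genotypes$values)) {
    abort("phenotype rows do not match genotype samples", class = "omga_input_error")
  }
  d <- ncol(Y)
  trait_names <- colnames(Y) %||% paste0("trait", seq_len(d))
  annotation <- dplyr::arrange(as_tibble(annotation), .data$chr, .data$start)
  gene_map <- map_snps_to_genes(genotypes$snps, annotation, window)
  annotation <- annotation[annotation$gene %in% names(gene_map), , drop = FALSE]
  G <- nrow(annotation)

  pmat <- matrix(NA_real_, G, d, dimnames = list(annotation$gene, trait_names))
  n_snps <- integer(G)
  status <- rep("ok", G)
  for (g in seq_len(G)) {
    idx <- gene_map[[annotation$gene[g]]]
    n_snps[g] <- length(idx)
    sub <- subset_snps(genotypes, idx)
    for (j in seq_len(d)) {
      res <- tryCatch(omnibus_gene_test(sub, Y[, j], covariates, specs = specs, ...),
                      error = function(e) e)
      if (inherits(res, "error")) {
        status[g] <- paste0("failed: ", conditionMessage(res))
        break
      }
      pmat[g, j] <- res$p_value
    }
  }

  ok <- status == "ok"
  delta <- if (sum(ok) >= max(min_genes_for_delta, 50) && d > 1) {
    estimate_pairwise_covariance(pmat[ok, , drop = FALSE])
  } else if (d > 1) {
    inform("fewer genes than min_genes_for_delta: using the trait-correlation fallback for delta")
    resid <- apply(Y, 2, function(y) fit_null_model(y, covariates)$residuals)
    delta_from_trait_correlation(resid)
  } else {
    matrix(4, 1, 1)
  }

  p_multi <- rep(NA_real_, G)
  for (g in which(ok)) {
    p_multi[g] <- multitrait_gene_test(pmat[g, ], delta)$p_value
  }

  out <- tibble(gene = annotation$gene, chr = annotation$chr,
                start = annotation$start, end = annotation$end, n_snps = n_snps)
  for (j in seq_len(d)) out[[paste0("p_", trait_names[j])]] <- unname(pmat[, j])
  out$p_multi <- p_multi
  for (m in adjust) {
    adj <- adjust_pvalues(p_multi[ok], method = m, alpha = alpha)
    col <- rep(NA_real_, G); col[ok] <- adj$adjusted
    out[[paste0("p_multi_", m)]] <- col
    if (m == "bonferroni") attr(out, "bonferroni_threshold") <- adj$threshold
  }
  out$status <- status
  attr(out, "delta") <- delta
  attr(out, "traits") <- trait_names
  class(out) <- c("omga_scan", class(out))
  out
}

#' Write a scan result with its configuration sidecar
#'
#' Writes the gene table as TSV and a JSON sidecar holding the run
#' configuration and the estimated dependence matrix.
#'
#' @param scan An `omga_scan` tibble.
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @param config Optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, config = list()) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(config = config,
               traits = attr(scan, "traits"),
               bonferroni_threshold = attr(scan, "bonferroni_threshold"),
               delta = attr(scan, "delta"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
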