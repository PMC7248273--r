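test_that("MAF filter computes min(f, 1-f) and keeps the boundary", {
  vals <- cbind(zero = rep(0, 10),                      # f = 0 -> removed
                rare = c(1, rep(0, 9)),                 # f = 0.05 -> kept (>=)
                common = rep(1, 10))                    # f = 0.5 -> kept
  g <- toy_genotypes(vals)
  suppressMessages(out <- maf_filter(g, 0.05))
  expect_equal(out$snps$id, c("s2", "s3"))
  # threshold 0 keeps everything
  expect_equal(dim(maf_filter(g, 0)), dim(g))
  # major-allele coding still measured as minor frequency
  g2 <- toy_genotypes(cbind(rep(2, 10), c(rep(2, 9), 1)))
  suppressMessages(out2 <- maf_filter(g2, 0.05))
  expect_equal(out2$snps$id, "s2")
  expect_error(suppressMessages(maf_filter(toy_genotypes(cbind(rep(0, 6))), 0.05)),
               class = "omga_empty_panel_error")
  expect_error(maf_filter(g, 0.7), class = "omga_config_error")
})

test_that("SNP-to-gene mapping uses closed intervals with a window", {
  variants <- tibble::tibble(id = paste0("s", 1:5), chr = c("1", "1", "1", "chr1", "2"),
                             pos = c(1000L, 2000L, 22000L, 22001L, 1500L))
  ann <- tibble::tibble(gene = c("gA", "gB"), chr = c("chr1", "2"),
                        start = c(1000L, 1L), end = c(2000L, 3000L))
  m0 <- map_snps_to_genes(variants, ann, window = 0)
  expect_equal(m0$gA, c(1L, 2L))          # boundary SNP at start included
  expect_equal(m0$gB, 5L)                 # chromosome harmonization 2 vs 2
  m20 <- map_snps_to_genes(variants, ann, window = 20000)
  expect_true(3L %in% m20$gA)             # 22000 = end + window included
  expect_false(4L %in% m20$gA)            # 22001 just outside

  # overlapping genes share SNPs
  ann2 <- tibble::tibble(gene = c("g1", "g2"), chr = "1",
                         start = c(500L, 1500L), end = c(2500L, 2500L))
  m2 <- map_snps_to_genes(variants, ann2, window = 0)
  expect_true(2L %in% m2$g1 && 2L %in% m2$g2)

  # genes with no SNPs are dropped with a message; all-empty errors
  ann3 <- tibble::tibble(gene = c("hit", "empty"), chr = c("1", "9"),
                         start = c(900L, 1L), end = c(1100L, 10L))
  expect_message(m3 <- map_snps_to_genes(variants, ann3, window = 0), "dropped 1")
  expect_named(m3, "hit")
  ann4 <- tibble::tibble(gene = "none", chr = "22", start = 1L, end = 10L)
  expect_error(map_snps_to_genes(variants, ann4, 0), class = "omga_empty_scan_error")
})

test_that("BED annotations convert 0-based half-open to 1-based closed", {
  d <- withr::local_tempdir()
  path <- file.path(d, "genes.bed")
  writeLines(c("chr1\t999\t2000\tgA", "2\t0\t3000\tgB"), path)
  ann <- read_gene_bed(path)
  expect_equal(ann$start, c(1000L, 1L))
  expect_equal(ann$end, c(2000L, 3000L))
  expect_equal(ann$chr, c("1", "2"))
})

test_that("multiple-testing adjustment matches the genome-wide threshold", {
  adj <- adjust_pvalues(runif(11579), method = "bonferroni", alpha = 0.05)
  expect_equal(signif(adj$threshold, 2), 4.3e-6)
  expect_equal(adjust_pvalues(0.03, "bonferroni")$threshold, 0.05)
  bh <- adjust_pvalues(c(0.01, 0.02, 0.9), method = "bh", alpha = 0.05)
  expect_equal(bh$significant, c(TRUE, TRUE, FALSE))
})

test_that("genome scan: d = 1 reduction, ordering invariance, determinism", {
  set.seed(40)
  n <- 80; p <- 30
  g <- simulate_genotypes(n, p)
  sim <- simulate_traits(g, "null", d = 2, rho = 0.4)
  ann <- tibble::tibble(gene = c("g2", "g1", "g3"), chr = "1",
                        start = c(110000L, 5000L, 150000L),
                        end = c(200000L, 100000L, 290000L))

  # d = 1: multi-trait p equals the per-gene omnibus p
  scan1 <- suppressMessages(run_genome_scan(g, sim$phenotypes[, 1, drop = FALSE],
                                            sim$covariates, ann))
  expect_equal(scan1$p_multi, scan1$p_trait1, tolerance = 1e-12)
  expect_equal(scan1$gene, c("g1", "g2", "g3"))  # ordered by (chr, start)

  # shuffling annotation rows changes nothing
  scan2 <- suppressMessages(run_genome_scan(g, sim$phenotypes[, 1, drop = FALSE],
                                            sim$covariates, ann[c(3, 1, 2), ]))
  expect_equal(scan2$p_multi, scan1$p_multi)

  # full d = 2 scan is deterministic and carries the delta attribute
  s1 <- suppressMessages(run_genome_scan(g, sim$phenotypes, sim$covariates, ann))
  s2 <- suppressMessages(run_genome_scan(g, sim$phenotypes, sim$covariates, ann))
  expect_identical(s1$p_multi, s2$p_multi)
  expect_equal(dim(attr(s1, "delta")), c(2, 2))
  expect_s3_class(s1, "omga_scan")
  expect_true(all(s1$status == "ok"))

  # removing one gene's SNPs drops that gene and changes no other record
  ann_drop <- ann[ann$gene != "g2", ]
  s3 <- suppressMessages(run_genome_scan(g, sim$phenotypes, sim$covariates, ann_drop))
  expect_equal(s3$p_trait1, s1$p_trait1[s1$gene != "g2"], tolerance = 1e-12)

  # tidy/glance/write round trip
  long <- tidy(s1)
  expect_equal(nrow(long), nrow(s1) * 3)   # 2 traits + multi
  expect_equal(glance(s1)$n_genes, 3)
  out <- file.path(withr::local_tempdir(), "scan.tsv")
  write_scan(s1, out, config = list(window = 0))
  expect_true(file.exists(out) && file.exists(paste0(out, ".json")))
  side <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(unname(as.matrix(side$delta)), unname(attr(s1, "delta")),
               tolerance = 1e-12)
})

test_that("null scan of 200 genes with correlated traits is calibrated", {
  set.seed(41)
  n <- 150; n_genes <- 200; snps_per_gene <- 8
  g <- simulate_genotypes(n, n_genes * snps_per_gene)
  sim <- simulate_traits(g, "null", d = 3, rho = 0.5)
  ann <- tibble::tibble(gene = sprintf("g%03d", seq_len(n_genes)), chr = "1",
                        start = (seq_len(n_genes) - 1L) * snps_per_gene * 10000L + 1L,
                        end = seq_len(n_genes) * snps_per_gene * 10000L)
  scan <- suppressMessages(run_genome_scan(g, sim$phenotypes, sim$covariates, ann))
  expect_equal(nrow(scan), n_genes)
  frac <- mean(scan$p_multi < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("a failing gene is reported with a reason, not dropped", {
  set.seed(42)
  n <- 40
  g <- simulate_genotypes(n, 10)
  g$values[, 10] <- 1   # constant SNP: gene of only this SNP is degenerate
  sim <- simulate_traits(g, "null", d = 2, rho = 0)
  ann <- tibble::tibble(gene = c("ok", "bad"), chr = "1",
                        start = c(1L, 95001L), end = c(90000L, 100000L))
  scan <- suppressWarnings(suppressMessages(
    run_genome_scan(g, sim$phenotypes, sim$covariates, ann, min_genes_for_delta = 1e6)))
  expect_equal(scan$status[scan$gene == "ok"], "ok")
  expect_match(scan$status[scan$gene == "bad"], "failed")
  expect_true(is.na(scan$p_multi[scan$gene == "bad"]))
})

test_that("HWE chi-square filter removes gross departures only", {
  set.seed(43)
  n <- 500
  f <- 0.3
  hw <- rbinom(n, 1, f) + rbinom(n, 1, f)        # Hardy-Weinberg SNP
  het_only <- rep(1, n); het_only[1:2] <- c(0, 2) # everyone heterozygous
  g <- toy_genotypes(cbind(hw = hw, bad = het_only))
  suppressMessages(out <- hwe_filter(g, alpha = 1e-6))
  expect_equal(out$snps$id, "s1")
  # chi-square matches a direct oracle computation on the kept SNP
  counts <- tabulate(hw + 1L, 3L)
  fhat <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - fhat)^2, 2 * fhat * (1 - fhat), fhat^2)
  chi <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(chi, 1, lower.tail = FALSE), 1e-6)
})
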