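#' Tidy a single-kernel test result
#'
#' @param x An `omga_kbt` object.
#' @param ... Unused.
#' @return One-row tibble with the kernel family, bandwidth, statistic,
#'   variance components and p-value.
#' @export
tidy.omga_kbt <- function(x, ...) {
  tibble(family = x$spec$family, bandwidth = x$spec$bandwidth, Tn = x$Tn,
         V1 = x$V1, sigma2_Tn = x$sigma2_Tn, delta = x$delta, df = x$g,
         p_value = x$p_value, method = x$method)
}

#' @export
glance.omga_kbt <- function(x, ...) {
  tibble(n = x$n, n_snps = x$p, p_value = x$p_value, method = x$method)
}

#' Tidy an omnibus combination
#'
#' @param x An `omga_omnibus` object.
#' @param ... Unused.
#' @return Per-kernel tibble when available, otherwise the combined row.
#' @export
tidy.omga_omnibus <- function(x, ...) {
  if (!is.null(x$kernels)) x$kernels
  else tibble(p_value = x$p_values)
}

#' @export
glance.omga_omnibus <- function(x, ...) {
  tibble(n_kernels = length(x$p_values), T_O = x$T_O, p_value = x$p_value)
}

#' Tidy a correlated Fisher combination
#'
#' @param x An `omga_fisher` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, gamma parameters and p-value.
#' @export
tidy.omga_fisher <- function(x, ...) {
  tibble(statistic = x$T, d = x$d, mu = x$mu, sigma2 = x$sigma2,
         shape = x$shape, scale = x$scale, p_value = x$p_value)
}

#' @export
glance.omga_fisher <- function(x, ...) tidy.omga_fisher(x)

#' Tidy a genome scan into long format
#'
#' @param x An `omga_scan` tibble.
#' @param ... Unused.
#' @return Long tibble with one row per gene x trait (trait `"multi"` for the
#'   combined test).
#' @export
tidy.omga_scan <- function(x, ...) {
  traits <- attr(x, "traits")
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "gene", "chr", "start", "n_snps",
                  dplyr::all_of(paste0("p_", traits)), "p_multi"),
    cols = c(dplyr::all_of(paste0("p_", traits)), "p_multi"),
    names_to = "trait", values_to = "p_value")
  long$trait <- sub("^p_", "", long$trait)
  long$trait[long$trait == "multi"] <- "multi"
  long
}

#' @export
glance.omga_scan <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_tested = sum(x$status == "ok"),
         n_traits = length(attr(x, "traits")),
         bonferroni_threshold = attr(x, "bonferroni_threshold") %||% NA_real_,
         min_p_multi = suppressWarnings(min(x$p_multi, na.rm = TRUE)))
}
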