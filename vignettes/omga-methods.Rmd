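---
title: "Gene-based multi-trait association testing with omnibus kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based multi-trait association testing with omnibus kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omga)
```

## The problem

Single-variant GWAS tests are underpowered when a trait is driven by several
variants acting jointly within a gene, possibly nonlinearly or through
interactions; and analysing one phenotype at a time wastes the information
carried by correlated traits that share genetic causes (pleiotropy). `omga`
tests the joint effect of all SNPs mapped to a gene on a set of correlated
quantitative traits, in three layers:

1. **Kernel U-statistic per trait and kernel.** For trait $Y$ with covariates
   $W$, the semiparametric model is
   $Y_i = \mu + \alpha^\top W_i + h(x_i) + \varepsilon_i$, where $x_i$ is the
   gene's SNP vector and $h(\cdot)$ an unknown joint-effect function. The null
   $H_0: h \equiv 0$ is tested with the degenerate U-statistic
   $$T_n = \frac{1}{n(n-1)} \sum_{i \neq j} K(x_i, x_j)\,
     (Y_i - \hat Y_i)(Y_j - \hat Y_j) / \hat\sigma^2,$$
   where $\hat Y$ and $\hat\sigma^2$ come from the covariate-only least-squares
   fit (residual-variance divisor $n - q - 1$) and $K$ is a normalized kernel.
   No normality of $\varepsilon$ is assumed; only the excess kurtosis enters
   the variance estimate.
2. **Cauchy omnibus over candidate kernels.** Because the best kernel depends
   on the unknown form of $h$, the per-kernel p-values $p_1,\dots,p_L$
   (default: linear, IBS, Gaussian) are combined by
   $T_O = L^{-1} \sum_j \tan\{(0.5 - p_j)\pi\}$ with
   $p = 0.5 - \arctan(T_O)/\pi$ — analytic, fast, and valid under the strong
   dependence between kernels on the same data.
3. **Correlated Fisher combination across traits.** The $d$ per-trait omnibus
   p-values give $T = -2\sum_j \log p_j$, whose null distribution under
   dependence is approximated by a gamma with mean $\mu = 2d$ and variance
   $\sigma^2 = 4d + \sum_{j \neq k} \delta_{jk}$,
   $\delta_{jk} = \mathrm{cov}(-2\log p_j, -2\log p_k)$: shape
   $\mu^2/\sigma^2$, scale $\sigma^2/\mu$. With independent traits this is
   exactly $\chi^2_{2d}$.

## Kernels and normalization

The candidate kernels are the linear kernel $x_i^\top x_j/\theta$, the
identity-by-state kernel $\sum_k (2 - |x_{ik} - x_{jk}|)/2p \in [0, 1]$, and
the Gaussian kernel $\exp(-\lVert x_i - x_j\rVert^2/\theta)$, all on raw
0/1/2 minor-allele dosage (no standardization or MAF weights). Bandwidths
default to $\theta = p$ for the linear kernel and the median pairwise squared
distance (median heuristic) for the Gaussian kernel; the omnibus layer makes
results robust to this choice. Each raw kernel is divided by the mean of its
diagonal, the empirical estimate of $E\,K_\theta(X, X)$ for identically
distributed samples, so every candidate enters the test with mean diagonal 1.
Normalizing by this single scalar (rather than a product of two expectations)
preserves positive semidefiniteness and is idempotent.

## Satterthwaite approximation and the null mean

Under $H_0$, $nT_n$ converges to a centered mixture of chi-squares; its
distribution is approximated by a scaled chi-square $a\chi^2_g$ matched on
mean and variance with $V_1 = \mathrm{tr}(HK)/n$
($H = I - n^{-1}J$), $a = \hat\sigma^2_{T_n}/2V_1$ and $g = V_1/a$. The
variance estimate is, with $B = HKH$ and excess kurtosis $\hat\Delta$ of the
trait,
$$\hat\sigma^2_{T_n} = n^{-2}\Big[(2 - 12/n^2 + 6\hat\Delta/n)\,
  \mathrm{tr}(B^2) - (2/n + \hat\Delta/n)\,\mathrm{tr}(B)^2 +
  \hat\Delta \textstyle\sum_i B_{ii}^2\Big].$$
Its leading term $2\,\mathrm{tr}(B^2)/n^2$ is the classical quadratic-form
variance for Gaussian errors; the kurtosis term matches
$\mathrm{Var}(e^\top B e) = 2\,\mathrm{tr}(B^2) + \Delta\sum_i B_{ii}^2$ for
i.i.d. errors. The estimate is validated in the test suite against the
permutation variance of $nT_n$ (agreement within 15% at $n = 50, 100$); a
non-positive estimate falls back to the Gaussian form with a warning.

One correction the package applies deliberately: the chi-square-mixture limit
presumes a *centered* kernel (the first-order projection of the U-statistic
must vanish), under which $E[nT_n] = 0$. The raw similarity kernels used here
are not centered — the IBS kernel in particular has large positive
off-diagonal mass — and the statistic then has null mean $-(1 - V_1)$, which
is far from 0 on the scale of its standard deviation. We subtract the
permutation-exact null mean
$$E[nT_n] = -\frac{(\mathbf 1^\top K \mathbf 1 - \mathrm{tr}\,K)(n - q - 1)}
  {n(n-1)^2},$$
exact under exchangeable residuals that sum to zero, before the chi-square
mapping (`kbt_null_mean()`). For a doubly centered kernel the correction
vanishes and the mapping reduces to the uncorrected rule. Without this
correction the IBS and Gaussian tests reject essentially never; with it,
p-values for all three kernels are uniform under the null (verified by
Kolmogorov–Smirnov tests at $n = 200$, $p = 50$, 2,000 replicates) and the
analytic p-value tracks a 999-permutation p-value instance by instance.

p-values are clipped to $[10^{-15}, 1]$ so that the downstream
$\log$ and $\tan$ transforms stay finite; the Cauchy combination additionally
clips inputs at $1 - 10^{-15}$ and switches to the tail identity
$p \approx 1/(\pi T_O)$ for $T_O > 10^{15}$ to avoid cancellation near 0.5.
A seeded residual-permutation p-value (`method = "permutation"`, default 999
permutations) is available as a small-sample fallback and serves as the
oracle in the test suite.

## Estimating the trait dependence $\delta_{jk}$

The covariance of the $-2\log p$ terms is estimated empirically across genes:
genome-wide gene-level p-values are treated as approximately null draws and
$\hat\delta_{jk}$ is the sample covariance of the transformed columns,
clipped to $[-4, 4]$ (the variance of $-2\log U$ for uniform $U$ is 4). This
estimator needs many genes; below 50 genes the package refuses and uses the
documented fallback instead: Brown's approximation with the Kost–McDermott
polynomial $\delta_{jk} \approx 3.263\rho + 0.710\rho^2 + 0.027\rho^3$ on the
empirical trait (residual) correlation $\rho_{jk}$. In simulation harnesses,
where each replicate contributes one gene, $\hat\delta$ is pooled across
replicates — valid because replicates are i.i.d. draws. $\sigma^2$ is floored
at 0.5 (with a warning) to keep the gamma proper. The dependence correction
is load-bearing: at trait correlation 0.8 forcing $\delta = 0$ inflates the
empirical type-I error above the acceptance band, while the corrected
combiner stays inside — this directional property is asserted in the test
suite.

## Genome scan conventions

- Coordinates are 1-based closed internally; BED input (0-based half-open) is
  converted on read, matching the PLINK `.bim` convention.
- A SNP maps to a gene when chromosomes match (case-insensitive, `chr`
  prefix stripped) and its position lies in $[\text{start} - w,
  \text{end} + w]$ for window $w$; SNPs may map to several genes. The window
  has no silent default in the command-line wrapper — it must be given.
- MAF filtering removes SNPs with $\min(f, 1-f)$ strictly below the
  threshold; a SNP exactly at the threshold is retained. An auxiliary
  Hardy–Weinberg filter (`hwe_filter()`, asymptotic 1-df chi-square, not an
  exact test) is available for coarse quality control.
- Genes are ordered by (chromosome, start); failing genes carry a reason code
  in `status` rather than being dropped.
- The scan output is a tibble with `tidy()`/`glance()` methods and a Q–Q
  `autoplot()`; `write_scan()` adds a JSON sidecar with the configuration and
  $\hat\delta$.

## The simulator and what it does (not) emulate

`simulate_genotypes()` draws two haplotypes per sample from a latent Gaussian
with AR(1) correlation (`ld_decay`, default 0.5) across SNPs, thresholded at
per-SNP MAFs drawn from Unif(0.05, 0.5), and sums them — producing
0/1/2 dosage with LD that decays along the gene. This is a deliberate,
documented stand-in for a haplotype-block simulator trained on real data: it
reproduces allele-frequency spectra and local LD decay, but not block
structure, recombination hotspots, or rare-variant site-frequency spectra.
Calibration claims (type-I error) transfer to real data much more readily
than power magnitudes, which depend on where causal variants sit in the LD
and MAF landscape; the test suite therefore asserts calibration bands and
qualitative power orderings, never power values.

Traits follow $Y_{ij} = 0.02\,Z_{i1} + 0.6\,Z_{i2} + h(X_i) +
\epsilon_{ij}$ with $Z_1 \sim N(2,1)$, $Z_2 \sim \mathrm{Ber}(0.6)$,
$\epsilon_i \sim \mathrm{MVN}(0, \Sigma)$, $\Sigma$ compound-symmetric with
unit variances and correlation $\rho \in \{0.3, 0.8\}$, $d = 5$ traits. The
scalar gene effect $h(X_i)$ is added to every trait — the fully pleiotropic
reading, which is the setting a multi-trait test targets. $Z_1, Z_2$ are
included as covariates in every null fit. Four effect scenarios are provided:
a nonlinear two-SNP effect (A), a sparse linear effect (B), weak polygenic
main effects with strong pairwise interactions (C: $c_M = 0.02$,
$c_N = 1.8$), and pure polygenic main effects (D: $c_M = 3.8$, $c_N = 0$);
for C and D the 10 main-effect SNPs, 30 interacting pairs and their
Unif(0, 0.02) effect sizes are drawn once under a frozen seed
(`simulate_effects()`) and shared by all replicates.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bandwidth` | `"auto"` | $p$ (linear) or median heuristic (Gaussian) |
| `specs` | linear, IBS, Gaussian | candidate kernel set for the omnibus |
| `kurtosis_center` | `"mean"` | center trait by its raw mean before the 4th moment; `"residual"` standardizes null-fit residuals instead |
| `n_perm` | 999 | permutations for the fallback p-value (seeded) |
| `window` | none (CLI), 0 (API) | SNP-to-gene flank, base pairs |
| `maf threshold` | 0.05 | strict-`<` removal rule |
| `min_genes_for_delta` | 50 | empirical vs polynomial $\delta$ estimator |
| `ld_decay`, `maf_range` | 0.5, (0.05, 0.5) | genotype generator |

The kurtosis default centers by the raw trait mean with the regression
residual scale, exactly as the estimator is defined; with covariates that
explain much variance the `"residual"` option is the natural alternative.
Under the simulation design the covariate contribution is small and the two
choices give indistinguishable calibration, so the definitional form stays
the default.

## The MANOVA comparator

The benchmark method tests each SNP with a one-way MANOVA (Pillai trace) of
the $d$ traits on dosage plus covariates and takes the smallest p-value in
the gene. The Pillai trace is computed from residual cross-products of the
multivariate linear model (algebraically identical to `stats::manova` with a
single-df hypothesis, verified to $10^{-15}$ in the tests, and fast enough
for replicated simulation). An unadjusted within-gene minimum cannot control
gene-level type-I error, so the default applies a Šidák correction
$1 - (1 - p_{\min})^p$; the unadjusted variant remains available. Whether the
original benchmark adjusted within genes is not documented; both variants are
therefore provided.

## Problem sizes used in validation

The packaged tests run the full null grid ($n \in \{100, 200, 400\}$,
$p \in \{50, 100\}$, $\rho \in \{0.3, 0.8\}$) at 1,000 replicates per cell;
uniformity checks use 2,000 single-trait replicates; power properties use 500
replicates per point on the $p = 50$ grid; oracle agreement uses 200
instances at 999 permutations. These sizes put the Monte-Carlo standard error
of a rejection rate near 0.007, small enough for the binomial acceptance band
$[0.035, 0.065]$ around the nominal 0.05.

## Known limitations and honest failures

- **Power in near-linear single-SNP scenarios.** Under this generator,
  scenario A's mean function is almost exactly linear in dosage at
  $x \in \{0,1,2\}$ (per-allele decrements $-0.78, -0.77$ for the nonlinear
  SNP), so the per-SNP MANOVA comparator saturates at power $\approx 1$ at
  $n = 400$ and the omnibus test — which spreads its evidence over all 50
  SNPs — cannot exceed it. The interaction scenario C shows the expected
  ordering clearly (omnibus several-fold more powerful). Orderings in
  strong-single-SNP scenarios depend on the genotype distribution and are not
  portable across generators.
- Quantitative traits only; no binary phenotypes or GLMs.
- No exact mixture-of-chi-square inversion (Davies/Imhof); the Satterthwaite
  approximation with the permutation fallback is the intended operating
  point. The two-moment match has a visible shape limit: a chi-square with
  fitted degrees of freedom $\hat g$ has skewness $\sqrt{8/\hat g}$, so for
  kernels that fit a large $\hat g$ (typically the Gaussian kernel) the
  reference is less skewed than the statistic's resampling distribution, and
  analytic and permutation p-values can differ by a few hundredths in the
  middle of the distribution even though the variance estimate is validated
  within 15% of the permutation variance and the tails — hence type-I error
  and KS-uniformity — are calibrated. Where instance-level agreement with a
  resampling reference matters, use `method = "permutation"`.
- No weighted or learned kernels; the candidate set is fixed by the user.
- The empirical $\delta$ estimator assumes most genes are null; in a panel
  saturated with signal it overestimates dependence and becomes
  conservative.
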