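---
title: "Variance-component TWAS: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component TWAS: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a gene's expression is associated with a phenotype.
A reference cohort with both genotypes and expression provides per-SNP
cis-eQTL effect-size estimates $\hat w_j$ (the "weights"); a test cohort
(or a published GWAS) provides the association data. The classical
two-stage ("burden") approach imputes genetically regulated expression
$\widehat{GReX} = G_{new}\hat w$ and regresses the phenotype on it:

$$E[g(Y \mid G_{new})] = \beta\, \widehat{GReX} + \alpha' Z,$$

testing $H_0\!: \beta = 0$. This assumes each SNP's phenotype effect is
the *same linear multiple* of its eQTL effect. When effect directions or
magnitudes in the test cohort deviate from the reference weights — ancestry
differences, context-specific regulation, or genuinely non-linear
architectures — the burden statistic loses power because oppositely signed
contributions cancel inside the weighted sum.

## The variance-component test

The variance-component formulation instead treats the per-SNP phenotype
effects $\beta_j$ as random with $\beta_j \sim N(0, w_j^2 \tau)$ and tests
$H_0\!: \tau = 0$ with the score statistic

$$Q = (Y - \hat\mu)' K (Y - \hat\mu), \qquad K = G W G',
  \qquad W = \mathrm{diag}(w_j^2),$$

where $\hat\mu$ is the fitted phenotype mean under the covariate-only null
model (linear for quantitative traits, logistic for case/control). Only
the squared weights enter, so the test is invariant to weight signs and to
a common rescaling — the robustness property that distinguishes it from
the burden test. Under $H_0$, $Q$ is distributed as a weighted sum of
independent 1-df chi-squares $\sum_k \lambda_k \chi^2_{1,k}$, with
$\lambda_k$ the eigenvalues of the covariate-projected weighted kernel:
$\hat\sigma^2\, W^{1/2} G'(I - H) G\, W^{1/2}$ for Gaussian traits ($H$
the covariate hat matrix) and
$W^{1/2} G'(V - VZ(Z'VZ)^{-1}Z'V) G\, W^{1/2}$, $V =
\mathrm{diag}(\hat\mu(1-\hat\mu))$, for binomial traits. `Q` is evaluated
in the $O(nm)$ score form $\sum_j w_j^2 (G_j'r)^2$; the explicit kernel
form is retained only for testing.

### Summary statistics

When only marginal GWAS results $(\hat\beta_j, \hat\sigma_j, n)$ are
available, the phenotype is assumed covariate-adjusted ($\hat\mu = 0$) and
the statistic simplifies to $Q = \sum_j w_j^2 s_j^2$ with single-variant
scores $s_j = G_j'Y / \hat\sigma_Y^2$ reconstructed from a reference LD
covariance matrix $\Sigma$:

$$G_j'Y = (n-1)\hat\beta_j \Sigma_{jj}, \qquad
  \hat\sigma^2_Y = \mathrm{median}_j\!\left(\Sigma_{jj}\hat\sigma_j^2(n-1)
  + \Sigma_{jj}\hat\beta_j^2\right),$$

the median taken over the gene's own SNPs (the formula is gene-local as
written; whether a genome-wide variance would be preferable is not
determinable from the method's description, and the gene-local choice
keeps the test self-contained). Under the null
$\mathrm{Cov}(s) = ((n-1)/\hat\sigma_Y^2)\,\Sigma$, so the mixture weights
are the eigenvalues of $((n-1)/\hat\sigma_Y^2)\, W^{1/2}\Sigma W^{1/2}$.
With per-SNP sample sizes (meta-analyzed GWAS) the median $n$ enters the
eigenvalue formula, matching the median strategy of the variance
estimator.

## Computing the mixture tail

No quadratic-form distribution package is assumed: tail probabilities
$P(\sum_k \lambda_k \chi^2_{1,k} > q)$ are computed by numerical inversion
of the characteristic function (Imhof's integral, the quantity Davies'
exact method evaluates), with two exact shortcuts where the oscillatory
integral converges slowest — a single eigenvalue (scaled 1-df chi-square)
and exactly two eigenvalues (one-dimensional conditioning integral). Deep
tails (below ~1e-8, where quadrature error dominates) switch to the
Kuonen saddlepoint approximation; the Liu moment-matching approximation
is the last-resort fallback and is flagged in the result. P-values are
clipped to $(10^{-300}, 1]$. Eigenvalues below $10^{-8}\lambda_{max}$ are
truncated; tiny negative eigenvalues from finite-precision
eigendecomposition are clamped to zero and flagged when their magnitude
exceeds $10^{-6}\lambda_{max}$.

## Finite-sample dispersion handling (a deliberate design choice)

For Gaussian traits the classical ("plug-in") construction multiplies the
kernel eigenvalues by the estimated residual variance $\hat\sigma^2$ and
treats them as fixed. But $Q$ and $\hat\sigma^2$ are computed from the
*same residuals* and are positively dependent; the dependence is
negligible when the number of weighted SNP directions is small relative
to the sample size (the regime of real, strongly structured cis-LD), but
with a diffuse kernel spectrum — as produced by this package's synthetic
AR(1) panels with dense weights, where ~1,200 comparable eigendirections
meet $n \approx 1{,}230$ — the plug-in test becomes severely conservative
(empirical type-I error ~2e-3 at nominal 1e-2).

The package therefore defaults to the *exact* finite-sample null of the
ratio $t = Q/\hat\sigma^2$: writing the residual as $N = n - q$
independent normal directions of which $d$ carry the kernel eigenvalues
$\lambda^0_k$,

$$P(t > t_{obs}) \;=\; P\!\Big(\textstyle\sum_k
  (\lambda^0_k - t_{obs}/N)\, z_k^2 \;-\; (t_{obs}/N)\,\chi^2_{N-d}
  \;>\; 0\Big),$$

a *signed* chi-square mixture evaluated by the same inversion integral
(valid for signed weights) with a signed saddlepoint for deep tails. The
construction is free of $\sigma^2$, exact at any $n$, converges to the
plug-in mixture as $n \to \infty$, and for a single SNP reduces the test
to the familiar Wald $t$-test. The summary-level test receives the
identical treatment (treating $\hat\sigma^2_Y$ as a chi-square variance
estimator with $n-1$ degrees of freedom), so individual-level and
summary-level p-values agree on shared data in all regimes. The plug-in
composition remains available as `dispersion = "plugin"`, under which the
single-SNP test is algebraically the 1-df score test. Binomial traits
have no estimated dispersion and are unaffected.

## Weight training

* **Elastic net** (`fit_elastic_net_weights`): `glmnet` with mixing
  parameter 0.5 (the sparse-trainer convention), penalty chosen by seeded
  5-fold cross-validation minimizing MSE. Genotypes and expression are
  centered but *not* scaled, so coefficients apply directly to dosages.
  `cv_r2` is $1 - \mathrm{CV\,MSE}/\mathrm{Var}(y)$ from held-out
  predictions and may be negative. At weak, polygenic expression signal
  the cross-validated penalty can select the empty model — a legitimate
  outcome; such genes fail the `cv_r2 > 0.005` inclusion rule.
* **Dense ridge stand-in** (`fit_ridge_standin_weights`): an SVD-based
  ridge regression with CV-selected penalty over a log-spaced grid. It
  emulates the qualitative behavior of nonparametric Bayesian eQTL
  estimators — a finite, generally nonzero weight for every SNP, most of
  them small — whose actual weight files the package consumes via
  `read_weight_file` (tag `dpr_external`); the estimator itself is out of
  scope. The ridge solution is deliberately simple so its closed forms
  (univariate case, orthogonal designs) are testable.
* **Median filtering** (`filter_weights`): dense weight sets are thinned
  by keeping SNPs with $|w_j|$ strictly above the gene's median absolute
  weight (about half the SNPs), or above a fixed magnitude threshold such
  as 1e-4. Magnitudes are used rather than signed values because dense
  weights are signed and a signed-median rule would discard all negative
  eQTL. The unfiltered median is stored in the weight set so the filter
  is idempotent. Retained weights are never altered.

## The synthetic world

`simulate_genotypes` draws two latent standard-normal haplotypes per
sample with AR(1) correlation $\rho^{|i-j|}$ ($\rho = 0.5$) inside blocks
of 100 SNPs, thresholded at population MAFs drawn uniformly from
$(0.05, 0.5)$ — Hardy-Weinberg genotype frequencies and the MAF > 5%
screen hold by construction. Defaults mirror the reference design: 499
training samples, 1,232 test samples, 2,799 cis-SNPs. Expression is
$E = Gw + \varepsilon_E$ with a causal set of size $\lceil p_{causal}
\cdot m\rceil$ (the ceiling guarantees at least one causal eQTL at
$p_{causal} = 0.001$), effects rescaled so the *realized* genetic variance
equals $h_e^2$ and $\varepsilon_E \sim N(0, 1-h_e^2)$. Phenotypes follow
Model I ($Y = r E_g + \varepsilon_Y$, the burden-friendly architecture)
or Model II ($Y = G\beta + \varepsilon_Y$, $\beta_i \sim N(0, r w_i^2)$,
variance- but not sign-linked to the weights), each calibrated to a
realized genetic share $h_p^2$. Calibration uses realized (empirical)
variances per replicate rather than asymptotic formulas.

What the stand-in does **not** reproduce: real cis-LD (long-range, highly
heterogeneous block structure), allele-frequency/LD coupling, and real
eQTL effect-size distributions. Consequently absolute power values are
properties of the synthetic world, not of any real gene; only
calibration (type-I error), method orderings (variance-component vs
burden under Model II/Model I), sample-size monotonicity, and the
summary/individual and filtered/complete equivalences are meaningful, and
those are what the acceptance suite asserts. A green power test
establishes the orderings, not the published power curves.

The power harness refreshes training expression (and hence weights) every
`reps_per_fit = 25` replicates and re-simulates phenotypes every
replicate — a compute compromise documented here; `reps_per_fit = 1`
reproduces the fully nested design. The type-I harness exploits the fact
that with an intercept-only Gaussian null, `p < alpha` is *exactly*
`Q/\hat\sigma^2 > t_alpha`, so the eigendecomposition and one critical
value per weight set replace 1e5 tail evaluations; a dedicated test
verifies that the fast path reproduces the per-gene code path's decision,
replicate by replicate.

## Meta-analysis and reporting

Per-cohort p-values combine by Fisher's method ($-2\sum\ln p_i$ against
$\chi^2_{2k}$); zero p-values are clipped at 1e-300 and flagged. FDR
control across genes uses Benjamini-Hochberg (the reporting threshold
convention is FDR < 0.05; the procedure itself is unnamed in the source
method description, and BH is the field default). Results tables use the
fixed schema `GENE_ID CHROM START END N_SNPS Q PVALUE FDR FLAGS` and
round-trip through text at full precision.

## Numerical and policy choices collected

* Cis window: gene start − 1 Mb to gene end + 1 Mb, configurable flank.
* Missing dosages: per-SNP mean imputation (preserves allele frequency).
* HWE: chi-square goodness-of-fit on hard calls only; dosage-only input
  skips the test.
* LD covariance: divisor $n-1$; default ridge $10^{-6} \times$ mean
  diagonal guarantees PSD.
* Dosages are never standardized: weights are trained on, and applied
  to, the dosage scale.
* All joins are by sample id or by chromosome-position with allele
  harmonization (swap flips the weight/effect sign; strand-ambiguous
  A/T and C/G mismatches are dropped).
* All randomness flows from named substreams of a single base seed;
  identical configurations are bit-reproducible.

## Known limitations

* The synthetic LD stand-in bounds what the simulation studies can claim
  (above); real-genotype power curves are out of scope.
* Binomial traits use the unadjusted score construction (no small-sample
  moment correction) and the summary-level test treats case/control GWAS
  through the linear-score approximation.
* No LD-proxy imputation for summary statistics: SNPs missing from the
  weight set or LD reference are dropped and counted.
* The nonparametric Bayesian and genome-wide (cis+trans) weight trainers
  are consumed from files, never fitted here.
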