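---
title: "Estimating genomic heritabilities and correlations for milk fatty acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genomic heritabilities and correlations for milk fatty acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Milk fat composition — the weight proportions of individual fatty acids —
is a breeding target: saturated fatty acids (SFA) are nutritionally less
desirable than unsaturated ones (UFA), and selection can only act on traits
with genetic variance. The classical route to heritability estimates is a
pedigree-based animal model, but a sampling design built around *many sires
with very few daughters each* (good for association mapping, poor for
pedigree-based variance components) makes dense SNP markers the more
informative source of relatedness. `snpherit` estimates genomic
heritabilities and genomic/environmental correlations directly from SNP
markers with a Bayesian random-regression SNP-BLUP model, and verifies them
with REML on a genomic relationship matrix (GBLUP).

## The model

For one trait on $n$ cows with $m$ SNPs,

$$ y = \mu + X_1\beta_1 + X_2\beta_2 + Zu + e $$

where $X_1, X_2$ are herd and parity incidence matrices, $Z$ is the matrix
of *centered* SNP covariates (allele counts $0/1/2$ minus $2\hat p_j$), $u$
holds per-SNP allele-substitution effects with $u \sim N(0, I\sigma_u^2)$,
and $e \sim N(0, I\sigma_e^2)$. Both variances carry flat (uniform) priors
on the variance scale. The quantity of interest is not $\sigma_u^2$ itself
but the *SNP-explained* (genomic) variance, evaluated in every saved MCMC
cycle as the empirical variance over individuals of the genomic values,

$$ \sigma_a^2 = \mathrm{Var}(Zu), \qquad
   h^2 = \frac{\sigma_a^2}{\sigma_a^2 + \sigma_e^2}, $$

and, in the two-trait model with per-SNP effect 2-vectors
$u_j \sim N(0, \Sigma_u)$ and residual pairs $\sim N(0, \Sigma_e)$,

$$ r = \frac{\mathrm{Cov}(Zu_1, Zu_2)}
            {\sqrt{\mathrm{Var}(Zu_1)\,\mathrm{Var}(Zu_2)}} . $$

Posterior means and posterior standard deviations (psd) of the per-cycle
$h^2$ and $r$ draws are the reported estimates and uncertainties.

### Sampling scheme

The reference sampler is exact single-site Gibbs: fixed effects and each
$u_j$ from their normal full conditionals, $\sigma_e^2$ and $\sigma_u^2$
from scaled inverse-chi-square full conditionals (degrees of freedom $n-2$
and $m-2$ under the flat prior), and in the bivariate model $\Sigma_e$ and
$\Sigma_u$ from inverse-Wishart full conditionals (degrees of freedom $n-3$
and $m-3$). The default schedule is 100&nbsp;000 iterations, 10&nbsp;000
burn-in, saving every 100th cycle — 900 saved draws.

An optional Metropolis–Hastings mode replaces the single-site SNP-effect
updates with blocked random-walk proposals whose per-SNP scale tracks the
conditional posterior SD $\sqrt{\sigma_e^2/(z_j'z_j + \sigma_e^2/\sigma_u^2)}$,
with a global step multiplier adapted toward ~25% acceptance during burn-in
only (so the post-burn-in chain is a valid fixed-kernel MH). Gibbs is the
correctness reference; the MH mode is validated against it and against the
closed-form ridge posterior, not an independent authority.

### Numerical conventions, frozen

Choices the model description leaves open are frozen and exposed as
arguments rather than silently varied:

* $\mathrm{Var}(Zu)$ uses the population ($n$) denominator each cycle;
  posterior summaries use the sample ($n-1$) SD over saved draws.
* The first herd and parity levels are absorbed into the intercept, keeping
  the fixed-effect design full rank.
* Missing genotype calls are imputed to the per-SNP mean $2\hat p_j$ before
  centering, so imputed entries contribute exactly zero to $Zu$.
* Flat variance priors may be truncated at `variance_upper_bound`
  (rejection sampling, pinned at the bound after repeated rejection);
  the default is untruncated.
* Rows with a missing phenotype (either trait, bivariate) are dropped with
  a logged count; the sampler never imputes phenotypes.

## Quality control and the genomic relationship matrix

`apply_qc()` filters in a fixed order — individuals below 80% call rate,
then loci below 95% call rate (recomputed on retained individuals), then
loci with MAF < 1% (which removes monomorphic loci) — because the
conventional thresholds do not by themselves determine an order and the
order affects which call rates are measured. MAF and the centering
frequencies are computed on the same non-missing calls, after individual
filtering, so the design matrix and the filter agree. A per-call quality
score matrix (e.g. array GenCall scores) can be supplied to mask low-quality
calls, but is off by default: simulated data carry no intensities.

`compute_grm()` implements the first VanRaden construction: $M$ coded
$-1/0/1$, $P$ with columns $2(p_j - 0.5)$, $Z = M - P$ and
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with observed sample allele frequencies
(no base-population frequencies are available). This is algebraically
identical to the centered-0/1/2 construction used by the sampler, and the
package tests that identity to $10^{-10}$. G can be assembled per
chromosome; the combination rule is the denominator-weighted average
$G = \sum_c d_c G_c / \sum_c d_c$, chosen because it reproduces the
whole-genome matrix exactly.

## REML verification path

The same traits are re-analysed with an animal model
$y = \mu + \mathrm{herd} + \mathrm{parity} + g + e$, $g \sim N(0, G\sigma_a^2)$,
fitted by average-information (AI) REML. Implementation choices:

* $G$ is eigendecomposed once; in the rotated basis the phenotypic
  covariance is block-diagonal with $t \times t$ blocks
  $d_i \Sigma_g + \Sigma_e$, making every AI iteration $O(n p^2)$. This is
  the package's own choice of algorithm — the published analyses used
  general-purpose REML software whose internals are not reproduced here.
* AI updates are step-halved when they would decrease the restricted
  likelihood and replaced by an EM step (guaranteed ascent) when they leave
  the parameter space, so the likelihood trace is non-decreasing.
* Convergence: relative parameter change < 1e-8 and scaled gradient norm
  < 1e-6; maximum 200 iterations, non-convergence flagged, never silent.
* Variances are bounded below at $10^{-8}$ of the phenotypic variance and
  correlations at $|r| \le 0.9999$; a fit is `boundary_flag`ged when
  $|r| > 0.999$ or a variance sits at its floor. Weakly identified
  bivariate problems (small $n$, weak signal) routinely collapse to
  $\hat r = \pm 1$; the flag reproduces that diagnostic behaviour, and
  flagged fits are excluded from the Bayes–REML agreement statistic while
  remaining in the comparison table.
* Standard errors come from the inverse AI matrix (delta method for $h^2$
  and $r$); they are auxiliary diagnostics, not published quantities.

With $G = I$ the genomic and residual variances are not separable and the
model errors out rather than returning an arbitrary split.

## Fatty-acid traits

`derive_fa_traits()` computes, per cow, group sums (SFA, UFA, MUFA, PUFA,
even-chain C6–C14) of the 17 measured fatty-acid proportions and the four
delta-9-desaturase indices product/(product+substrate):
C14:1c9/C14:0, C16:1c9/C16:0, C18:1c9/C18:0 and CLAc9t11/C18:1t11.
The even-chain C6–C14 group deliberately excludes C13:0 and C15:0: only the
even-chain membership reproduces the published group mean (22.18) from the
published member means — including C13:0 would give 22.28. Groups are
computed per cow and then summarized; means commute with the grouping
(linearity) but SDs and CVs do not, so the per-cow order matters.
`table1_summary()` ships the published per-trait summary table used by the
composition-identity checks.

## What the synthetic data emulate — and what they do not

The generator reproduces the *sampling design* the estimators face:
371 cows sired by 200 bulls (paternal half-sib families, mostly of size
1–3), 19 herds of 3–24 cows, parities 1–3, a genome-wide panel scaled down
to a few thousand SNPs in contiguous chromosome blocks, QC fodder
(monomorphic, low-MAF, missing calls), and traits with target
heritabilities spanning 0.07–0.35 and genomic correlations spanning
−0.60 to 0.91. One published inconsistency (19 herds in the animals
description, 20 herd levels in the model description) is resolved in favour
of 19 in the preset; the fitting code accepts any level count.

Genotypes are gene-dropped from sire and unrelated-dam gametes under a
uniform(0.05, 0.95) base allele-frequency law, so *relatedness* is real but
*linkage disequilibrium beyond family structure is absent*: chromosome
labels exist to exercise per-chromosome GRM assembly, not to model linkage.
Consequently the simulations cannot probe LD-dependent phenomena (e.g.
incomplete tagging of causal variants, the main suspected source of
downward bias in real genomic heritabilities), and passing recovery tests
demonstrate correctness of the estimators under their own assumptions, not
robustness to real LD. There is also no genotyping-error model, no
repeated-measures/lactation structure, and missingness is completely at
random.

Per-SNP effects are drawn jointly across traits with covariance scaled as
$\sigma_a^2 / \sum_j 2p_j(1-p_j)$ so the *expected* Var($Zu$) hits its
target; the *realized* Var($Zu$), residual variances and correlations are
recorded as the truth against which recovery is judged, which keeps tests
sharp at small marker counts. Herd sizes are drawn by constrained
multinomial rejection (exact total, every size within range). Monomorphic
markers receive zero effects — they cannot carry genomic variance.

## Problem sizes used by the tests and the acceptance script

Simulation-based checks run at deliberately reduced scale, chosen as the
smallest sizes at which the statistical claims are sharp: heritability
recovery uses replicated datasets of n = 500 cows x 2000 SNPs with
short "smoke" chains (15 000 iterations, 3 000 burn-in, thin 10) rather
than the full production schedule, the closed-form sampler oracle uses
n = 8 x m = 3 where the posterior is computable exactly, and the
Bayes-vs-REML agreement uses a five-trait dataset (ten pairs) of
n = 400 x 1000 SNPs with strong family structure (40 sires), since
method agreement is only a meaningful comparison where the genomic
correlation is identified at all. The full production schedule (100k
iterations) is exercised on a small dataset to pin the bookkeeping.

## Known limitations

* No LD simulation and no variable-selection priors (BayesB/C/R-style);
  effects are dense Gaussian by construction and by model.
* At the study's own scale (a few hundred cows, tiny half-sib families),
  bivariate genomic correlations are weakly identified: posterior standard
  deviations of 0.15–0.3 and frequent REML boundary collapses are the
  honest behaviour, not a defect.
* The MH mode mixes more slowly than Gibbs per iteration and exists for
  comparability, not speed, at the panel sizes used here.
* Models with more than two traits, pedigree-based relationship matrices
  and dominance/epistatic GRMs are out of scope.
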