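---
title: "Partition-based permutation tests for rare-variant regions: models, choices, and limitations"
author: "spaRV maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based permutation tests for rare-variant regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaRV)
```

## The problem

Single-marker association tests collapse for rare variants: with minor
allele frequencies (MAF) below 1%, a region of K SNPs yields a handful of
carriers per site, far too few for per-site inference. Region-based tests
therefore aggregate evidence across the K sites of a gene or pathway
region. Most aggregate only *marginal* signal; this package implements the
summation-of-partition family of influence scores, which additionally
captures gene–gene (G×G) and gene–environment (G×E) structure while
remaining model-free: no genetic model is fit, and all inference is by
permutation.

## The statistics

All scores are partition-retention (PR) influence measures. Given any
partition of the N subjects into cells, the influence of the partition on
a trait Y is

$$I = \sum_{\text{cells } c} n_c^2\, (\bar Y_c - \bar Y)^2,$$

the count-weighted squared deviation of cell means from the grand mean.
For a case-control trait, cell means are case fractions and
$\bar Y = \bar\pi = N_A/N$. `influencePR()` computes this reference form
for an arbitrary non-overlapping partition; its normalized version is
asymptotically a weighted sum of one-degree $\chi^2$ variables under the
null, but none of the package's inference relies on asymptotics.

Rare variants make the joint $3^K$-cell partition useless (nearly all
cells are empty), so the region scores build *overlapping* per-SNP cells
and sum them:

* **I1 (marginal, `computeI1`)** — per SNP i, the allele-level partition:
  $n_i$ is the total minor-allele count at SNP i and $\hat\pi_i$ the
  fraction of those alleles found in cases;
  $I_1 = \sum_i n_i^2 (\hat\pi_i - \bar\pi)^2$. For continuous traits the
  cell mean is the average trait among carriers and the weight stays the
  allele count. Because every term is a squared deviation, risk and
  protective variants both contribute — no directional collapsing is
  assumed.
* **I2 (pairwise G×G, `computeI2`)** — per SNP pair, the carrier cells
  mM (minor allele at i only), Mm (at j only), mm (at both); the MM cell
  (no minor allele at either) is excluded. Each pair contributes its
  three-cell PR sum divided by the pair's carrier-union size
  $n_{union} = |mM| + |Mm| + |mm|$. The division matters: without it the
  K−1 copies of each SNP's single-carrier cell dominate the sum and the
  score degenerates into a rescaled marginal statistic (see *Numerical
  and design choices*). `normalize = FALSE` gives the plain sum.
* **p\* (adaptive, `adaptivePStar`)** — $\min\{p(I_1), p(I_2)\}$, for the
  common situation where one does not know whether interactions are
  present.
* **I1E (G×E, `computeI1E`)** — crosses the per-SNP allele cells with the
  J strata of a categorical environmental factor:
  $I_1^E = \sum_j \sum_i n_{ij}^2 (\hat\pi_{ij} - \bar\pi)^2$, with
  deviations always taken from the *global* case fraction. Measured this
  way the score retains the environmental marginal signal, which is what
  makes the two permutation strategies below test different nulls.

## Permutation inference

Significance is always by phenotype permutation (`spaTest`):

* **global** — permute the trait among all subjects; tests "no
  association at all" (no G, E, or G×E effect).
* **local** — permute independently within each environmental stratum;
  the stratum case counts are preserved, so the environmental marginal
  effect is *part of the null* and only genetic and G×E signal can
  reject.

P-values use the add-one estimator $p = (1 + \#\{T_b \ge T_{obs}\})/(1+B)$:
never zero, valid for any B, ties counted against rejection. For p\* a
single shared ensemble serves both arms (Westfall–Young min-p): each
permuted statistic is converted to a p-value by its leave-one-out add-one
rank within its own null ensemble, per-permutation minima form the null of
p\*. This costs B statistic evaluations instead of the $B^2$ of nested
permutation, at equivalent validity. Evaluation is vectorized — one matrix
product per ensemble, using the exact identity
$n_c^2(S_c/n_c - \bar Y)^2 = (S_c - n_c \bar Y)^2$ — and equals
per-permutation evaluation to machine precision (this is tested).

## The synthetic-data generator

`spaScenario()` + `simulateScenario()` emulate the validation conditions
the statistics were studied under:

* a region of 20 independent rare SNPs (no linkage disequilibrium),
  genotypes Binomial(2, MAF) per subject (Hardy–Weinberg equilibrium),
  MAF drawn per replicate either fixed at 0.01 or uniform on
  (0.0001, 0.01);
* binary traits from a logistic model — baseline prevalence 0.01 —
  sampled retrospectively to an exact number of cases and controls;
  continuous traits from a linear model with unit residual SD and no
  sampling step;
* named scenario shapes: the complete null (`null1`), an
  environment-only model (`null2`), marginal-effect models (`s1`–`s3`:
  constant effects, MAF-inverse effects, mixed risk/protective),
  pure-interaction and mixed models (`s4`–`s6`, both-carrier indicator
  terms, MAF fixed at 0.01), and G×E models (`s7`–`s8`, binary
  environment).

Coefficient defaults are this package's documented choices, since the
source material's exact simulation coefficients are not published:
constant marginal effects default to log-odds log 3 (a typical rare-variant
odds ratio), MAF-inverse effects to $0.4\,|\log_{10} m_i|$ (≈ OR 3 at MAF
0.001), interaction terms to log-odds 3 on the both-carrier indicator, and
the `null2` environmental main effect to log-odds log 3 — chosen once as a
strong, unambiguous exposure effect, since any nonzero value exercises the
local-permutation null. Calibration (type-I error) results do not depend
on any of these; only power magnitudes do.

Two exact shortcuts keep binary simulation cheap: under the complete null,
case status is independent of everything, so genotypes are drawn for the
retained sample directly; when only the environment enters the model,
(env, status) pairs are drawn prospectively and genotypes attached
afterwards. Both are distributionally identical to full
prospective-then-retrospective sampling, which is used whenever any
genetic coefficient is nonzero (with a stall guard at $10^7$ draws).

What the generator does **not** emulate: linkage disequilibrium,
population structure, genotyping error, covariates beyond one categorical
factor, and real site-frequency spectra. Passing calibration tests on
these data therefore shows the permutation machinery is exact under
exchangeability — it does not certify behavior under confounding, which
permutation tests do not address.

## Experiments and reproducibility

`runExperiment()` estimates rejection rates over R independent replicates;
replicate r runs under `replicateSeed(seed, r)` (a Lehmer-style mix modulo
$2^{31}-1$), so partial runs and re-runs reproduce exactly and identical
master seeds give byte-identical summary tables. Statistics sharing a
permutation strategy share one ensemble per replicate. Desk-scale defaults
are R = 1000 replicates with B = 1000 permutations (R = 500 for the
heavier I2 runs); exact binomial 95% confidence intervals are always
reported alongside the rates so that reduced-scale calibration checks
remain honest. The calibration checks shipped in the test suite use
n = 1000 and n = 600 subjects; uniformity checks use n = 500 with B = 499;
power-ordering checks use n = 1000 with B = 499.

## Numerical and design choices

* **Formula normalization.** Monotone rescalings of any statistic leave
  permutation p-values untouched, so global constants (e.g. the
  $N \mathrm{Var}(Y)$ normalization of the PR measure) are dropped.
* **The I2 n_union division** is the one reconstruction choice with
  statistical consequences, so it deserves its rationale. For independent
  rare SNPs, each SNP's single-carrier cell reappears in K−1 pairs; in
  the unnormalized sum these near-duplicates dominate both signal and
  null noise, and the resulting test is empirically power-equivalent to a
  carrier-level marginal test in every scenario we examined — the
  interaction cells never get weight. Dividing each pair by its carrier
  union tempers the large cells and restores the intended contrast
  between I1 (marginal-sensitive) and I2 (less powerful than I1 under
  purely marginal architectures). The unnormalized form remains available
  as `normalize = FALSE`.
* **A limitation worth stating plainly:** under retrospective case-control
  sampling of *independent* rare variants, a pure both-carrier interaction
  induces per-SNP marginal enrichment whose expected magnitude equals the
  both-carrier cell's own signal ($n_{mm} = n_i P(\text{carrier at } j)$).
  The marginal route has lower sampling variance, so in such scenarios
  I2's power advantage over I1 is structurally limited — in our
  experiments I2 does not overtake I1 even at large interaction effects.
  I2's value lies in localizing signal to pairs and in architectures with
  co-carrier enrichment (e.g. haplotype effects) rather than in raw power
  under this generator.
* **Counting conventions.** Binary I1/I1E count alleles (a homozygous
  carrier contributes 2); I2 cells and continuous-trait cell means use
  carrier status (dosage ≥ 1); continuous I1 keeps the allele-count
  weight. SNPs and cells with no observations contribute 0 rather than
  erroring — low-MAF regions produce them routinely.
* **Missing genotypes** are recoded to 0 minor alleles (conservative for
  rare variants) and counted in a message.
* **Minor-allele orientation.** VCF ingestion re-orients each column so
  dosage counts the *sample-minor* allele (ties go to ALT); the
  rare-variant MAF filter (default cutoff 0.05 for real data) then always
  refers to the minor allele.
* **Degenerate inputs.** Single-SNP regions make I2 zero (warning) and p\*
  degenerate to p(I1); binary phenotypes must contain both classes;
  every environmental level must be occupied.
* **Ties.** The add-one estimator counts ties against rejection, which is
  what keeps heavily discrete null ensembles (sparse regions, small B)
  conservative rather than anti-conservative.

## Worked example

```{r example}
spec <- spaScenario("s1", nCases = 200, nControls = 200,
                    effectSize = log(3))
ds <- simulateScenario(spec, seed = 7)
ds
spaTest(ds, statistic = "I1", B = 999, seed = 7)
spaTest(ds, statistic = "pstar", B = 999, seed = 7)
```

A small calibration run (scaled far below the defaults to keep the
vignette light):

```{r calibration}
null1 <- spaScenario("null1", nCases = 100, nControls = 100)
ex <- runExperiment(null1, c("I1", "pstar"), B = 199, R = 100, seed = 1)
summarizeExperiments(ex)
```

## Limitations

Beyond the generator gaps above: no asymptotic p-values are provided (by
design); higher-order (≥ 3-way) interaction scores and
environment×SNP×SNP extensions are not implemented; population
stratification is not corrected; multi-region batch analysis applies no
multiple-testing correction by default. The continuous-trait G×E score is
not defined here (the case-control form is the one the method specifies).
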