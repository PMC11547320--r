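---
title: "Two-sample Mendelian randomization with mrpipe: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y from two independent GWAS. For each genetic
instrument j we observe the SNP-exposure association $\hat\gamma_j$ (SE
$\sigma_{Xj}$) and the SNP-outcome association $\hat\Gamma_j$ (SE
$\sigma_{Yj}$). Under the instrumental-variable assumptions each SNP
identifies the same causal effect $\beta$ through its Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$, and the estimators in this
package differ only in how they pool the ratios and which assumption
violations (horizontal pleiotropy, weak instruments, outliers) they
tolerate. Quantitative traits are assumed standardized (effects per SD);
binary traits are analyzed on the log-odds scale and reported as odds
ratios per SD of exposure.

## Instrument quality control

* **Selection.** Candidates need association $p$ strictly below `pThreshold`
  (default $5\times 10^{-8}$). Greedy LD clumping then repeatedly keeps the
  smallest-$p$ remaining candidate and discards candidates with
  $r^2 >$ `r2Threshold` (default $10^{-3}$) to any retained index SNP. Ties
  in $p$ break by (chromosome, position, rsid) so the result cannot depend
  on input row order. LD is an explicit matrix input: clumping services
  differ by reference panel, so reproducibility requires the $r^2$ values
  to travel with the analysis. SNPs absent from the matrix are treated as
  unlinked and reported loudly.
* **Strength.** Per-SNP $F = (\hat\gamma/\sigma_X)^2$, with $F < 10$ flagged
  weak. Variance explained uses $2p(1-p)\hat\gamma^2$, which assumes the
  unit-variance exposure; missing allele frequencies exclude a SNP from the
  $r^2$ total with a warning rather than failing.
* **Confounder screen.** An offline annotation table (rsid, trait, p)
  replaces live phenome-scan queries. Screening only *flags* instruments;
  removal is a sensitivity-analysis decision (below), because a flagged
  association may be vertical (downstream of the exposure) rather than
  confounding.

## Harmonization

Outcome records are aligned to the exposure's effect allele: swapped
alleles negate the outcome beta and flip the frequency; strand complements
are complemented first. Palindromic pairs (A/T, C/G) are always dropped —
never frequency-inferred — because their strand is ambiguous and a
nine-ish-SNP instrument cannot afford a silent sign error. Duplicate rsids
keep the smallest-$p$ record. Retained plus dropped SNPs always partition
the instrument list, and the drop log (reason per rsid) is part of the
output contract.

## The estimator suite

| method | assumption it relaxes | key tunables |
|---|---|---|
| `mrIvw` | none (all instruments valid) | — |
| `mrPivw` | weak instruments, balanced pleiotropy | `lambda` (1) |
| `mrEgger` | directional pleiotropy (InSIDE) | — |
| `mrWeightedMedian` | up to 50% invalid weight | `bootReps` (1000), `seed` |
| `mrWeightedMode` | plurality-valid instruments | `bandwidthFactor` (1) |
| `mrPresso` | outlier pleiotropy | `nSim` (1000), `outlierP` (0.05) |

Numerical choices, and why:

* **First-order Wald SEs** ($\sigma_Y/|\hat\gamma|$): the standard default;
  the Monte-Carlo test bounds the approximation error at ~2% when
  instruments are strong. All p-values are two-sided normal (summary-data
  MR convention), not t.
* **Multiplicative random effects, floored at 1.** IVW's SE is scaled by
  $\sqrt{\max(1, Q/(k-1))}$, MR-Egger's by $\max(1, \hat\sigma)$:
  over-dispersion widens intervals, under-dispersion is never allowed to
  shrink them. This is conservative and matches common practice.
* **pIVW.** The debiased denominator
  $\hat\mu = \sum_j (\hat\gamma_j^2 - \sigma_{Xj}^2)/\sigma_{Yj}^2$ removes
  the exposure measurement-error term that attenuates plain IVW; the
  penalty $\hat\mu_\lambda = (\hat\mu + \sqrt{\hat\mu^2 + 4\lambda\hat
  v})/2$ bounds it away from zero (degenerating gracefully to the plain
  ratio of sums when $\sigma_X = 0$). The variance estimator carries a
  method-of-moments balanced-pleiotropy component $\tau^2$; `extras$kappa`
  ($\hat\mu/\sqrt{\hat v}$) reports effective instrument strength.
* **Weighted median.** Ratios sorted, cumulative percentiles
  $p_j = \sum_{i\le j} w_i - w_j/2$, linear interpolation at 0.5; SE from a
  parametric bootstrap that redraws both association vectors. Bootstrap
  seeds are explicit arguments and are recorded in the estimate's extras;
  there is no hidden global-RNG dependence, and the caller's RNG state is
  restored afterwards.
* **Weighted mode.** Weighted normal-kernel density over a 1024-point grid;
  bandwidth is `bandwidthFactor` times a MAD-based robust spread shrunk by
  $k^{-1/5}$. A zero MAD falls back to the SD, and a fully degenerate
  ratio vector returns that common value outright.
* **MR-PRESSO.** The global test compares the leave-one-out residual sum of
  squares against `nSim` parametric simulations under the fitted
  no-pleiotropy model. The per-SNP outlier search runs only when the
  global test is significant at 0.05 — outlier removal in data that show
  no global distortion signal is exactly the over-pruning the method is
  criticized for. Per-SNP p-values are Bonferroni-adjusted; the distortion
  test is reported but never auto-applied. Empirical p-values use the
  $(1 + \#\{\text{exceedances}\})/(n_{sim}+1)$ convention, so a reported p
  is never exactly zero.

## Colocalization

A single-causal-variant Bayesian screen adjudicates whether a flagged
instrument shares its causal variant with an outcome. Per-SNP
Wakefield-style log approximate Bayes factors
($\tfrac12[\log(1-r) + r z^2]$, $r = W^2/(W^2+V)$) are combined by
log-sum-exp into the five hypothesis likelihoods; everything stays in log
space because regional $|z|$ can exceed 30. Defaults: priors $p_1 = p_2 =
10^{-4}$, $p_{12} = 10^{-5}$, prior effect SD $W = 0.2$ (per-SD traits) or
0.15 (log odds) — the conventional values for this class of screen. The
pipeline's retention rule treats PP$_{H4} \ge 0.8$ as evidence of a shared
variant (vertical pleiotropy: keep the SNP); the threshold is
configuration, not code. The region width around an index SNP is the
caller's choice; ±500 kb is a sensible default and nothing in the math
depends on it.

## Sensitivity sets, meta-analysis, sex differences, power

* The **main** instrument set is never pruned by the confounder screen. A
  per-outcome **sensitivity** set drops flagged SNPs unless colocalization
  supports a shared variant for that outcome, recording every exclusion
  and its reason. This reproduces, as a rule rather than a hard-coded
  list, the practice of removing a flagged SNP for some outcomes but
  keeping it where PP$_{H4}$ is high.
* Outcomes observed in two GWAS are pooled by **fixed-effect**
  inverse-variance meta-analysis. With $k = 2$ a random-effects variance
  is essentially unestimable, so the fixed-effect model is the honest
  choice; $I^2 = \max(0,(Q-df)/Q)\times 100$ is still reported and must be
  read cautiously at such small $k$.
* The **sex-difference test** $z = (b_m - b_w)/\sqrt{se_m^2 + se_w^2}$ is
  algebraically the two-group Cochran Q test; the test suite asserts the
  equivalence to $10^{-12}$. When sex-stratified exposure associations are
  unavailable, the overall instrument-exposure associations are reused —
  a documented approximation, configurable when stratified data exist.
* **Power.** The SE of the causal log OR is approximately
  $1/\sqrt{n\,r^2\,cf(1-cf)}$ — outcome sample size discounted by the
  instrument $r^2$, with the Bernoulli variance term for binary outcomes —
  giving the minimum detectable effect
  $(z_{1-\alpha/2}+z_{power})\times se$. The empirical check simulates MR
  analyses at exactly that effect size and recovers 75–85% rejection; the
  check uses the fixed-effect z statistic because that is the sampling
  model the formula describes (the multiplicative over-dispersion floor
  would otherwise eat ~5 points of power).
* **Multiple testing.** `classifySignificance` applies
  threshold $= \alpha/n_{tests}$; with the default family of 15 outcomes
  that is $0.05/15 \approx 0.003$. P-values in $[\alpha/n_{tests}, \alpha)$
  are "suggestive", the standard reporting convention for this design.

## The synthetic world

`generateMrDataset` states its world rather than sampling an arbitrary
one: nine instruments for a standardized metabolite-like exposure measured
in 121,577 samples, a binary outcome GWAS of 547,261 participants (case
fraction 0.224, the scale of a large coronary-disease consortium), causal
OR 0.62 per SD, and instruments explaining `r2Total = 0.005` of exposure
variance. One default deserves explanation: a nine-SNP instrument
explaining only 0.05% of variance at $n \approx 121{,}577$ would have mean
$F \approx n\,r^2/k \approx 6.8$ — *weak* instruments — which is
incompatible with requiring all nine to clear $F > 10$. Since the
generator's contract is "strong instruments by default", it defaults to
0.5% explained variance (mean $F \approx 68$, every SNP strong with high
probability); analyses of genuinely weaker instruments set `weakFraction`
or lower `r2Total` explicitly. True SNP effects are drawn with magnitudes
$\mathcal N(1, 0.15^2)$ times a random sign and rescaled to the target
$r^2$ — heterogeneous enough to be realistic, bounded away from zero so
"strong" means every instrument, not just the average.

Sampling noise is added at exactly the asymptotic SEs
($1/\sqrt{2p(1-p)n}$, with the case-fraction variance factor for binary
traits); a property test confirms there is no hidden extra noise.
Pleiotropy regimes: `balanced` ($\alpha \sim \mathcal N(0, sd^2)$),
`directional` (nonzero mean), `inside_violating`
($\alpha = c\,\gamma + \varepsilon$, correlating instrument strength with
the direct effect), each applicable to a `pleiotropyFraction` of
instruments. Outliers shift an outcome beta by a stated number of its SEs.
Harmonization stress is injected last (palindromic pairs, swapped-allele
records).

What the generator does **not** emulate — so a green test does not
establish robustness to it: sample overlap between the exposure and
outcome GWAS (no correlated errors are simulated), LD between instruments
(instruments are independent by construction; LD lives only in the
colocalization region generator's AR(1) model $R_{ij} = \rho^{|i-j|}$),
allele-frequency misreporting, and population stratification.

## Known limitations

* First-order ratio SEs understate uncertainty when instruments are weak;
  `mrPivw` is the intended tool there, and the weak-instrument simulations
  quantify the IVW attenuation it removes.
* MR-Egger's slope suffers regression dilution when the true SNP-exposure
  effects are nearly homogeneous relative to their SEs; the agreement test
  documents the instrument-strength regime where this is negligible.
* The colocalization model assumes at most one causal variant per trait
  per region; multi-causal regions can misallocate posterior mass.
* No proxy-SNP lookup, GWAS-VCF parsing, liftover, Steiger filtering,
  multivariable MR, or random-effects meta-analysis: out of scope by
  design.
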