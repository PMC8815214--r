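---
title: "Mixed-model stratification correction under extreme phenotype sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model stratification correction under extreme phenotype sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Extreme phenotype sampling (EPS) genotypes only the individuals in the two
tails of a quantitative phenotype and analyses tail membership as a binary
trait (1 = upper tail, 0 = lower tail). The design is cost-efficient, but
when the cohort contains subpopulations that differ both in allele
frequency and in phenotype mean, the two tails end up with different
ancestry composition, and any variant whose frequency differs between the
subpopulations shows a spurious association with tail membership. This
package provides the simulators and from-scratch method implementations
needed to measure how well the standard correction strategies — linear and
logistic mixed models, a liability-threshold method, and
principal-component (PC) adjusted logistic regression — control the type I
error under EPS, and at what power.

## Simulated study conditions

The defaults encode the study conditions throughout:

* **Background panel.** 5000 bi-allelic SNPs under the Balding–Nichols
  model: per SNP an ancestral frequency $p \sim U(0.1, 0.9)$, and each of
  two subpopulations draws its frequency from
  $\mathrm{Beta}\!\big(p(1-F_{st})/F_{st},\,(1-p)(1-F_{st})/F_{st}\big)$
  with $F_{st} = 0.01$; genotypes are Hardy–Weinberg within subpopulation.
  The realized Weir–Cockerham $\hat F_{st}$ of a panel is checked in the
  tests.
* **Candidate SNP.** Simulated separately with subpopulation frequencies
  $(p_1, p_2)$, by default the worst-case $(0.25, 0.85)$; a no-effect,
  equal-frequency candidate with $p_1 = p_2$ serves as the unconfounded
  control, and a sweep over $p_2 \in [0.5, 0.9]$ traces the trend.
* **Phenotype.** $y_j \sim N(\mu_{s(j)} + \beta G_j, 1)$ with
  subpopulation means $\pm 0.07$; $\beta = 0$ under the null, 0.15 or 0.25
  in power runs (causal allele frequency 0.2, equal across
  subpopulations). EPS keeps the $\lfloor 0.1 N \rfloor$ largest and
  smallest values (0.2 N genotyped in total).
* **Rare-variant region.** A 30 kb region simulated under a two-deme
  island-model structured coalescent: per-deme pairwise coalescence at
  rate 1 on the $2N_e$-generation time scale, per-lineage migration
  $M/2$ with $M = 4 N_e m = 10$ (matching $F_{st} \approx 0.01$),
  infinite-sites mutations at total rate $\theta/2$,
  $\theta = 4 N_e \mu L = 120$ ($N_e = 10^5$, $\mu = 10^{-8}$); 10,000
  haplotypes paired into diploids uniformly at random within deme.

Two demes of size $N_e$ each approach, as $M \to \infty$, a panmictic
population of size $2N_e$; the tests verify this against a single-deme run
with $N_e$ doubled, and verify Watterson's $E[S] = \theta \sum_{i<n} 1/i$
in single-deme mode.

### What the generator does not emulate

Real cohorts have linkage disequilibrium in the background panel,
admixture rather than two discrete demes, genotyping error and
missingness, and highly differentiated outlier SNPs beyond what the
Balding–Nichols Beta model produces. Passing tests therefore demonstrate
correct behaviour under idealized two-population structure, not
performance on any particular real cohort.

### Recombination

The coalescent region uses a single genealogy (no intra-region
recombination). At 30 kb with these rates the expected number of
recombination events is small relative to the mutation count, and its main
effect — decorrelating variant genealogies across the region — is
secondary for region-level set tests. The `n_subloci` knob splits the
region into independent genealogies (each carrying $\theta/k$) as a cheap
approximation when decorrelation matters; the default is 1.

## The methods implemented

All methods see only the EPS sample: genotypes exist only for selected
individuals, so the standardized genetic relationship matrix (GRM)
$G = \tfrac1p \sum_s w_s w_s^{\mathsf T}$,
$w_s = (x_s - 2\hat p_s)/\sqrt{2\hat p_s(1-\hat p_s)}$, and its principal
components are recomputed per replicate within the sample, candidate
excluded.

* **LMM** (`fit_lmm_null()`, `lmm_score_test()`): the 0/1 label is treated
  as a continuous trait, $y \sim N(X\beta,\ \sigma_a^2 G + \sigma_e^2 I)$.
  Restricted likelihood is maximized over the ratio
  $\lambda = \sigma_a^2/\sigma_e^2$ in the GRM eigenbasis (each evaluation
  is O(n)), on a 100-point log grid over $[10^{-5}, 10^5]$ with Brent
  refinement; $\sigma_e^2$ is profiled in closed form. Candidates get a
  Wald test under GLS at the null $\hat\lambda$ (a score-type variant is
  available through the same machinery); the t reference with $n - p$
  degrees of freedom is the default.
* **Logistic mixed model** (`fit_glmm_null()`, `glmm_score_test()`):
  $\operatorname{logit} p_i = x_i^{\mathsf T}\alpha + b_i$,
  $b \sim N(0, \tau G)$, fitted by penalized quasi-likelihood with
  average-information REML updates of $\tau$ (working response
  $\tilde y = \eta + W^{-1}(y - \mu)$, $\Sigma = W^{-1} + \tau G$), to
  joint relative convergence $10^{-6}$, at most 100 iterations, $\tau$
  floored at 0. One null fit serves all variants: the score test uses
  $T = g^{\mathsf T}(y - \hat\mu)$ with variance $g^{\mathsf T} P g$,
  $P = \Sigma^{-1} - \Sigma^{-1}X(X^{\mathsf T}\Sigma^{-1}X)^{-1}
  X^{\mathsf T}\Sigma^{-1}$.
* **Rare-variant set tests** (`smmat_tests()`): with weighted dosages
  $G_w$ (weights default to the Beta(1, 25) density at the sample minor
  allele frequency; flat weights available) and score vector
  $U = G_w^{\mathsf T}(y-\hat\mu)$ with covariance
  $V = G_w^{\mathsf T} P G_w$: the burden test collapses to
  $1^{\mathsf T}U / \sqrt{1^{\mathsf T}V1}$; SKAT refers
  $Q = U^{\mathsf T}U$ to its $\sum_k \lambda_k \chi^2_1$ null with
  $\lambda_k$ the eigenvalues of $V$; SKAT-O takes the minimum p over the
  kernel-mixing grid $\rho \in \{0, 0.1^2, \dots, 0.5^2, 0.5, 1\}$ with
  the usual one-dimensional integration for the minimum's null
  distribution; and the efficient hybrid combines the burden p-value with
  the SKAT p-value of $U$ orthogonalized against the burden direction via
  Fisher's method ($\chi^2_4$), the two components being asymptotically
  independent.
* **Liability-threshold method** (`estimate_liabilities()`,
  `liability_assoc()`): a ridge-regularized probit MAP fit of the binary
  label on all standardized background SNPs; the estimated liability is
  the genetic component $\hat z_i = x_i^{\mathsf T}\hat\beta_g$, which is
  then analysed as a quantitative trait with the LMM. The ascent runs in
  the dual (eigenbasis of $XX^{\mathsf T}$, proportional to the GRM), so
  5000 SNPs cost no more than the sample size per Newton step.
* **Baselines** (`pca_logistic_test()`, `uncorrected_logistic_test()`):
  logistic regression of the label on the dosage with and without the top
  5 PCs.

### Numerical choices

Quadratic-form tail probabilities default to Liu-type moment matching.
Because only the first four spectral moments enter, wide variant sets are
handled by trace algebra on the sample-space Gram matrix
($Z Z^{\mathsf T}$ with $Z = CG_w$, $P = C^{\mathsf T}C$ from a pivoted
Cholesky), avoiding per-kernel eigendecompositions; an exact
characteristic-function inversion (`method = "exact"`) is available and is
cross-checked against Monte-Carlo mixtures in the tests. GRM eigenvalues
in $[-10^{-8}, 0)$ are clamped to zero, larger negative values are an
error. PC signs follow a largest-loading-positive convention. EPS ties are
broken by lowest index (probability zero for continuous phenotypes).
Monomorphic variants are excluded from the GRM, the liability fit and all
tests; monomorphic candidates report a missing p-value rather than 1.
Degenerate inputs (identity GRM, flat REML profiles) are flagged via a
`boundary` warning rather than silently returned.

## Ancestry covariates in the mixed-model null fits

A design point that matters more under EPS than in random-sampling
simulations: the harness includes the top 5 PCs as *fixed covariates* in
the LMM, GLMM and liability-scale null fits for the common-variant
scenarios (`n_covariate_pcs = 5`), alongside the GRM random effect — the
standard single-variant mixed-model GWAS pipeline, in which the leading
ancestry axes are modelled as fixed effects and the random effect absorbs
residual and cryptic structure.

The reason is quantitative, and the package makes it easy to reproduce:
the worst-case candidate ($p_1 = 0.25$, $p_2 = 0.85$) carries a raw
confounding z-score near $-3$ at $n = 1000$, while REML under a pure
mean-shift phenotype estimates a small variance ratio
($\hat\lambda \approx 0.1$, top GRM eigenvalue $d_1 \approx 1 + nF_{st}$),
so the random effect alone attenuates the ancestry axis only by
$1/(1 + \hat\lambda d_1) \approx 0.4$ — a partial correction that leaves
several-fold inflation (empirical sizes of 0.25–0.5 at nominal 0.05). With
the PC covariates the same fits are near-nominal, slightly conservative at
small samples. Setting `n_covariate_pcs = 0` reproduces the
shrinkage-only behaviour for study.

The rare-variant scenario instead defaults to a covariate-free GLMM null
(`n_covariate_pcs = 0`), matching the default workflow of rare-variant set
testing software; its residual inflation under EPS is precisely the
phenomenon the experiments quantify. Region variants are differentiated
only as far as the island-model demography implies, so no worst-case
single-variant outlier is involved.

## The experiment harness

`run_experiment()` drives replicated scenarios (`null`, `power`,
`rare_null`): per replicate it simulates subpopulation labels and
phenotypes for the cohort, ascertains the extremes, simulates genotypes
*for the selected individuals only*, computes the GRM and PCs within the
sample, runs every requested method, and records one p-value each. Type I
error and power are rejection proportions at $\alpha = 0.05$ with
Monte-Carlo standard errors $\sqrt{r(1-r)/m}$; `freq_sweep()` repeats the
null scenario over a $p_2$ grid; `qq_data()` and `autoplot()` produce
QQ-plot data with midpoint plotting positions.

Simulating genotypes only for the ascertained individuals is a
distributional identity, not an approximation: under the null, genotypes
are independent of the phenotype given subpopulation membership, and in
power runs the causal candidate is simulated cohort-wide before selection.
For the coalescent region the identity is the sampling consistency of the
coalescent — the genealogy of the selected individuals' haplotypes is
itself a structured coalescent — so the region is simulated directly for
the $2 n_1 + 2 n_2$ selected haplotypes.

Reproducibility: a root seed spawns per-replicate streams through an
integer hash, so results are bit-identical across runs and replicates are
individually re-runnable.

### Problem sizes in the shipped checks

The packaged test suite runs each scenario at reduced replication chosen
to keep the whole suite at desk scale: the common-variant null at
$N = 5000$ with $m = 100$, the frequency sweep at $m = 25$ per grid
point, the rare-variant null at $m = 100$, and the power comparison at
$m = 15$ per effect size; all comparisons carry the three-combined-SE
tolerance that this replication implies. `scripts/acceptance.R`
recomputes the rare-variant rates at $m = 500$. Full-replication runs
(m = 3000) are a matter of increasing `m_reps`.

### Power saturates quickly under this design

A caution for interpreting power runs: extreme sampling concentrates
information, so the two-tail dosage contrast for a causal candidate has
noncentrality
$\approx 2\beta\,\mathrm{var}(G)\,\phi(z_{0.9})/0.1 \big/
\sqrt{2\,\mathrm{var}(G)/n_\text{tail}}$ — about 11 at $\beta = 0.25$,
causal frequency 0.2 and $n = 2000$. At these defaults every method's
power is essentially 1 and the comparison is uninformative; method
differences only become visible at effect sizes several-fold smaller (or
samples much smaller). The harness reports whatever the configuration
implies rather than rescaling anything silently.

## Known limitations

* Two subpopulations only; admixture, more demes, and unequal deme sizes
  beyond the `pop_fractions` knob are out of scope.
* The LMM Wald test fixes $\lambda$ at the null estimate rather than
  re-optimizing per variant; at these sample sizes the difference is well
  inside Monte-Carlo error.
* The liability method's ridge strength defaults to
  $\lambda_r = p(1-h^2)/h^2$ with $h^2 = 0.5$ (a Gaussian prior with
  per-SNP variance $h^2/p$); the reference implementations do not document
  an equivalent constant, and moderate changes move results within
  Monte-Carlo error.
* Saddlepoint corrections for unbalanced case-control ratios are not
  implemented; EPS samples are balanced by construction.
* No genotype QC (missingness, sex checks) for user-supplied VCFs beyond
  GT parsing with missing-genotype handling.
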