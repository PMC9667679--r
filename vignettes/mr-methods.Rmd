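---
title: "Methods: two-sample Mendelian randomization across exposure panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization across exposure panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpanel)
```

## The model

mrpanel estimates the causal effect of an exposure (here, a standardized
gut-bacterial genus abundance) on a binary outcome (a disease phenotype on
the log-odds scale) from two independent GWAS. For each instrument SNP $j$
we observe the exposure association $\hat\gamma_j$ with standard error
$\sigma_{xj}$ and the outcome association $\hat\Gamma_j$ with standard
error $\sigma_{yj}$. The structural model is

$$\Gamma_j = \theta\,\gamma_j + r_j,$$

where $\theta$ is the causal log-odds effect per SD of exposure and $r_j$
is the direct (horizontally pleiotropic) effect of SNP $j$ on the outcome.
A SNP is a valid instrument when $r_j = 0$; the estimators differ in what
they assume about the invalid ones:

* **Wald ratio / IVW** — all instruments valid. The per-SNP ratio is
  $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order standard
  error $\sigma_{yj}/|\hat\gamma_j|$, and IVW is the precision-weighted
  mean with weights $w_j = \hat\gamma_j^2/\sigma_{yj}^2$ — identically, a
  weighted zero-intercept regression of $\hat\Gamma$ on $\hat\gamma$.
* **Maximum likelihood** — same validity assumption but the exposure-side
  noise enters the likelihood: the joint Gaussian likelihood over
  $(\theta, \gamma_1..\gamma_J)$ is profiled to
  $\sum_j (\hat\Gamma_j-\theta\hat\gamma_j)^2 / \{2(\sigma_{yj}^2 +
  \theta^2\sigma_{xj}^2)\}$ and minimized in one dimension.
* **MR-Egger** — allows directional pleiotropy satisfying the InSIDE
  assumption (instrument strength independent of direct effects): weighted
  regression with a free intercept, the intercept estimating the mean
  direct effect.
* **Weighted median** — consistent when at least half the total weight
  comes from valid instruments.
* **Weighted mode** — consistent when the largest homogeneous cluster of
  ratios is the valid one (no majority needed).
* **MR-PRESSO** — detects instruments whose residual
  $\hat\Gamma_j - \hat\theta_{-j}\hat\gamma_j$ is extreme relative to a
  parametric null, removes them, and tests whether removal distorts the
  estimate.
* **cML-MA-BIC** — constrained maximum likelihood that treats an explicit
  subset of instruments as invalid (their $r_j$ free), fit for every
  subset size $K = 0..J-2$ and combined by BIC model averaging. It does
  not require InSIDE, so it also handles correlated pleiotropy.

All estimates are reported as log-odds `beta`, `or = exp(beta)`, and a
95% interval `exp(beta ± 1.96 se)`. P-values are two-sided normal except
MR-Egger, which uses a t distribution with $J-2$ degrees of freedom (the
usual small-J convention for Egger inference).

## Instrument selection and harmonization

Candidate instruments are SNPs with exposure $p < 10^{-5}$ (the locus-wide
threshold used for mbQTL-scale exposures, where genome-wide hits are
scarce) and minor allele frequency strictly above 0.01 (records with
MAF ≤ 0.01 are removed; missing frequencies are kept but flagged). Greedy
LD clumping then keeps, within every ±10,000 kb window, only the
lowest-p SNP among those with pairwise $r^2 \ge 0.001$; ties on p-value
break lexicographically by SNP id so the output is deterministic. LD is
consumed as a precomputed $r^2$ table (symmetric lookup, absent pair = 0)
rather than computed from genotypes — clumping needs nothing more.

Harmonization expresses both studies' effects on the exposure's effect
allele: swapped alleles negate the outcome beta and mirror its frequency;
complementary-strand records are re-complemented first; palindromic SNPs
(A/T, C/G) cannot be resolved from allele labels, so the strand is
inferred from allele frequencies. Frequencies inside the ambiguity window
[0.42, 0.58] (a symmetric convention; the window is configurable) or
missing lead to the SNP being dropped; otherwise frequencies on the same
side of 0.5 mean same strand, opposite sides mean flip. Instruments
absent from the outcome GWAS are dropped without proxy search. Every
decision is recorded in an audit table. Harmonizing already-harmonized
data is a no-op, and jointly flipping an outcome record's alleles, beta
sign, and frequency leaves the harmonized pairs unchanged.

Instrument strength uses $R^2 = \sum_j 2 p_j (1-p_j)\hat\gamma_j^2$ (the
standardized-exposure convention; a $t^2/(t^2+N-2)$ fallback serves SNPs
without frequencies) and $F = R^2 (N-1-K) / \{(1-R^2) K\}$. Power for a
binary outcome uses the standard normal approximation
$\Phi(|\theta|\sqrt{N r^2 v(1-v)} - z_{1-\alpha/2})$ with case fraction
$v$.

## Panel orchestration and FDR

`run_mr_panel()` runs selection → clumping → harmonization → the estimator
ensemble per exposure, skipping exposures with no analyzable instruments
(logged) and restricting exposures with one or two instruments to
Wald/IVW (flagged; Egger, median, and mode need at least three).
Q-values are computed per method across exposures — e.g. the family of
119 IVW p-values — never pooled across methods, and each row is
classified as **significant** (p < 0.05 and q < 0.1), **suggestive**
(p < 0.05, q ≥ 0.1), or **null**. The Storey estimate
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/\{m(1-\lambda)\}$ is evaluated on
$\lambda = 0.05..0.95$, smoothed by a 3-df cubic spline, read off at
$\lambda = 0.95$, and clamped to (0, 1]; with $\hat\pi_0$ forced to 1 the
q-values equal Benjamini–Hochberg adjusted p-values exactly (a tested
identity). Reverse analyses re-run the identical pipeline with the
outcome GWAS as the exposure against every forward hit of the primary
method (IVW by default).

## The synthetic generator

`simulate_instrument_panel()` draws, per SNP: MAF uniform on [0.05, 0.5]
(common variants; mbQTL panels rarely contribute rare instruments), a true
effect $\gamma_j$, a direct effect $r_j$ per the pleiotropy mode, and
observed summary statistics around the truth with the standard GWAS
standard errors $\sigma_x = (2p(1-p)N_x)^{-1/2}$ and
$\sigma_y = (2p(1-p)N_y v(1-v))^{-1/2}$. Defaults mirror the targeted
study shape: $N_x = 13{,}266$, $N_y = 166{,}401$, $v = 5731/166{,}401$.

Two conventions deserve explanation:

* **Effect-allele orientation.** Each SNP's effect allele is taken to be
  the exposure-increasing allele, so true instrument effects are
  half-normal magnitudes $|\mathcal N(0, \texttt{gamma\_sd}^2)|$. This is
  how "directional" pleiotropy is meaningful at the summary level: with
  sign-symmetric instrument effects, orienting pairs for Egger regression
  would flip half the direct effects and cancel the intercept, and no
  mean-shift pleiotropy could bias IVW. The estimators themselves are
  orientation-invariant, so this convention costs no generality.
* **`gamma_sd` is a calibration knob, not an estimate.** No effect-size
  distribution for mbQTLs is available at this scale; the default 0.1
  gives instruments with median $|z| \approx 5$ at $N_x = 13{,}266$, so
  most survive the $p<10^{-5}$ screen and estimator unit tests are not
  distorted by selection. Tests that need essentially complete
  post-selection panels use 0.15.

Pleiotropy modes: `none`; `balanced` ($r_j \sim \mathcal N(0,\sigma_r^2)$
on the invalid subset); `directional` ($\mathcal N(\mu_r,\sigma_r^2)$);
`correlated` ($r_j = \phi\gamma_j + \mathcal N(0,\sigma_r^2)$, violating
InSIDE). The invalid subset has exactly
`round(pleio_fraction * n_snps)` members. `simulate_ld_blocks()` adds
block-diagonal LD with a shared causal signal per block (members' true
effects differ by noise of SD `gamma_sd/10`), and `simulate_study()`
builds disjoint panels for many exposures against one pooled outcome
table, with per-exposure sub-seeds derived from one master seed.

What the generator does **not** emulate: winner's curse beyond simple
thresholding, sample overlap between the two GWAS, population
stratification, LD beyond equicorrelated blocks, rare variants, and
binary-trait non-collapsibility (outcome effects are generated directly on
the log-odds scale). Passing tests therefore demonstrate correctness of
the estimators and pipeline under the stated model, not robustness to
every artefact of real consortium data.

## Numerical choices

* **IVW standard error** defaults to multiplicative random effects with a
  fixed-effect floor: $\mathrm{SE} \times \max(1, \sqrt{Q/(J-1)})$. This
  is the dominant convention in two-sample MR tooling; it never rejects
  more than the fixed-effect version and is conservative when
  heterogeneity is low. Both modes are exposed.
* **ML and cML slope searches** are 1-D optimizations of exactly profiled
  objectives (tolerance 1e-10), initialized at IVW; standard errors come
  from the numerical curvature of the profile at the optimum (central
  differences, step $10^{-4}\max(1,|\hat\theta|)$).
* **cML descent** alternates an exact invalid-set selection (the $K$
  largest standardized residuals) with an exact minimization given the
  selection; every step is a full minimization, so the objective is
  monotone non-increasing and the selection can change only finitely
  often. Ten restarts (IVW ± seeded perturbations of SD half the IVW SE)
  guard the non-convex selection; BIC uses
  $n_\mathrm{eff} = \min(N_x, N_y)$ by default.
* **Weighted median** interpolates ratios at standardized cumulative
  weight 0.5; its SE is the SD over seeded parametric resamples of the
  summary statistics (1000 by default).
* **Weighted mode** uses a normal kernel with bandwidth
  $0.9\,\phi\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$ on a 512-point grid
  spanning the ratios ±3 bandwidths. Its SE is the **MAD** of the
  bootstrap estimates: the bootstrap distribution of a mode is multimodal,
  and occasional jumps between density peaks inflate its SD severalfold
  relative to the estimator's true sampling spread (measured 0.26 vs 0.06
  at J = 30 in the package's own calibration checks), while the MAD tracks
  it closely. If all ratios coincide the estimate is the common ratio.
* **MR-PRESSO** standardizes residuals by $1/\sigma_{yj}^2$, uses the
  $(1+\#)/(n_\mathrm{sim}+1)$ p-value convention so p-values are never
  zero, Bonferroni-corrects the per-SNP outlier test at
  $\mathrm{sig}/J$, and assesses distortion by comparing the
  raw-minus-corrected shift against shifts from removing random subsets of
  the same size.
* **Degenerate inputs**: a single instrument reduces IVW/ML to the Wald
  ratio; a null instrument ($\hat\gamma_j = 0$) is an error for ratio-based
  estimators and a zero-weight observation for IVW sums; p-values from the
  generator are clamped above zero at the smallest positive double.
* **Seeds.** Every stochastic component (bootstraps, PRESSO simulations,
  cML restarts, the generator) takes its own sub-seed derived from one
  master seed by an integer mixing function, and restores the caller's RNG
  state afterwards; identical configuration and seed reproduce reports
  bit-for-bit. Simulation studies in the package's tests also draw
  replicate seeds through this mixing step — consecutive literal seeds
  produce a slightly shrunken empirical null under R's RNG seeding.

## Validation design and problem sizes

The test suite validates each layer against independent oracles: IVW
against a weighted regression fit, clumping against a literal re-application
of the rule on r² matrices for panels up to 12 SNPs, ML against grid
search, q-values against Benjamini–Hochberg, and hand-computed
two-instrument arithmetic. Statistical behavior is checked by simulation
at sizes chosen to balance resolution against runtime, stated here as the
package's own validation design: type-I error over 400 replicates at
J = 30 (median/mode bootstraps at 200 resamples), MR-PRESSO and cML null
behavior over 200 replicates, CI coverage over 500 replicates at J = 50,
robustness under 30% directional pleiotropy over 200 replicates
(`pleio_mean = 0.1`, i.e. direct effects of roughly five outcome-side
standard errors, a regime where pleiotropy dominates sampling noise), and
panel-level FDR over 100 replicates of 100-exposure all-null screens.

## Limitations

Single-outcome panels only; no multivariable MR, no Steiger
directionality filtering, no proxy-SNP substitution, no correlated-
instrument (LD-aware) likelihoods, and no simple/penalized median or mode
variants beyond the weighted forms above. The cML data-perturbation
variant is not implemented — model averaging is BIC-only. Figure
generation is out of scope by design: `render_report()` exports per-SNP
scatter and leave-one-out tables for external plotting, and `plot()` on a
fit draws a basic base-graphics scatter for interactive inspection only.
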