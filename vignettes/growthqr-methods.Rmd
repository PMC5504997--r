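---
title: "Quantile-specific genomic growth curves with growthqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-specific genomic growth curves with growthqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthqr)
```

## The problem

Pig growth is usually summarized by fitting a nonlinear curve to each
animal's weight-age records and interpreting the curve parameters: mature
weight, the age at the inflection point, and a growth-scale parameter.
Classical genomic analyses then regress those parameters on SNP genotypes
at the conditional *mean*, so a genomic growth curve exists only for the
population average. `growthqr` instead estimates marker effects at chosen
*quantiles* of the trait distribution with regularized quantile regression
(RQR), which yields quantile-specific marker rankings and quantile-specific
genomic growth curves — a picture of how the genome shapes the trajectories
of slow, average, and fast-growing animals, not just the mean animal.

## The model, step by step

**Step one — individual growth curves.** For animal $i$ with weight
$w_{ij}$ at age $t_j$ we fit the three-parameter logistic

$$ w_{ij} = \frac{\alpha_{1i}}{1 + \exp[(\alpha_{2i} - t_j)/\alpha_{3i}]} + e_{ij}, $$

where, for $\alpha_{3i} > 0$, $\alpha_{1i}$ is the mature weight (kg;
horizontal asymptote), $\alpha_{2i}$ the inflection age (days; the age at
which the response is $\alpha_{1i}/2$), and $\alpha_{3i}$ a growth scale
(days): the distance on the age axis from the inflection to the age where
the response is $\alpha_{1i}/(1+e^{-1}) \approx 0.73\,\alpha_{1i}$. The
scale form is the only parameterization stored anywhere in the package;
$\alpha_3$ is the reciprocal of the rate parameter of the rate-form
logistic, and we never mix the two.

The per-animal estimates are then corrected for the fixed effects sex, lot,
and halothane genotype by ordinary least squares (main effects, treatment
coding); the corrected trait is the OLS residual plus the grand mean, so
each corrected trait retains the mean of the raw estimates by construction.

**Step two — regularized quantile regression.** Each corrected trait
$y_i \in \{\hat\alpha^*_{1i}, \hat\alpha^*_{2i}, \hat\alpha^*_{3i}\}$ is
regressed on the SNP genotypes $x_{ik} \in \{0, 1, 2\}$ (copies of one
allele; raw, uncentered — the explicit intercept $\mu$ absorbs location):

$$ \hat\beta(\tau) = \arg\min_{\mu,\beta}\;
   \sum_i \rho_\tau\!\Big(y_i - \mu - \sum_k x_{ik}\beta_k\Big)
   + \lambda \sum_k |\beta_k|, \qquad
   \rho_\tau(u) = \begin{cases} \tau u & u > 0 \\ -(1-\tau)\,u & u \le 0,
   \end{cases} $$

with the intercept unpenalized. The default quantiles are
$\tau = 0.2, 0.5, 0.8$ — low, average, and high levels of each trait.

**Predictions.** Genomic estimated breeding values are
$\hat u_i(\tau) = \sum_k x_{ik}\hat\beta_k(\tau)$ per trait, and the
quantile-specific genomic growth curve evaluates the logistic at
GEBV-shifted parameters,

$$ \hat y_i(t) = \frac{\hat\mu_{\alpha_1} + \hat u_{\alpha_1 i}}
   {1 + \exp[((\hat\mu_{\alpha_2} + \hat u_{\alpha_2 i}) - t)/
   (\hat\mu_{\alpha_3} + \hat u_{\alpha_3 i})]}, $$

averaged over animals, where the $\hat\mu$s are the grand means of the
corrected traits. A rate-form variant of this expression (multiplying the
third parameter by $t$) circulates in the literature, but it is
dimensionally inconsistent with the scale-form model whose parameters the
step-two traits *are*; `growthqr` deliberately keeps the scale form
throughout.

## Solving the RQR problem exactly

The penalized check-loss objective is a linear program. `solve_rqr()`
folds the penalty into the loss by the standard augmentation — for each
coefficient two pseudo-observations of zero with design entries
$\pm\lambda$, whose pooled check loss is exactly $\lambda|\beta_k|$ for any
$\tau$ — and solves the resulting plain quantile-regression LP with a
primal-dual interior-point method (Mehrotra predictor-corrector on the
bounded-dual formulation). The implementation maintains exact primal and
dual feasibility, so the duality gap directly bounds the suboptimality of
the returned coefficients; iteration stops at a relative gap of $10^{-9}$.
Each Newton step solves a $(p{+}1)\times(p{+}1)$ normal-equations system by
Cholesky, with a $10^{-10}$-scaled ridge fallback for rank-deficient
designs (e.g. $p \ge n$ at $\lambda = 0$).

Correctness is anchored by an independent brute-force oracle used in the
tests: every vertex of the LP — each intersection of $p{+}1$ independent
hyperplanes from $\{r_i = 0\}$ and $\{\beta_k = 0\}$ — is enumerated on
tiny instances and the minimum objective compared with the solver's to
$10^{-6}$. Because optima of piecewise-linear programs can be non-unique
(a face, not a point), tests compare objective values, never coefficient
vectors, and the interior-point solution may legitimately be any point of
the optimal face. Diagnostics that depend on residual *signs* (the
quantile-bracketing property $\#\{r_i < 0\} \le n\tau \le \#\{r_i \le 0\}$)
therefore count residuals within a $10^{-6}$-relative band of zero as zero.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `quantiles` | 0.2, 0.5, 0.8 | trait levels at which effects are estimated |
| `lambda_grid` | 0 to 50 by 0.5 | candidate L1 penalties (trait units) |
| `bootstrap_reps` | 200 | case-resampling replicates for SEs and bands |
| `top_fraction` | 0.025 | fraction of markers reported as most relevant |
| `age_grid` | 0–150 by 5 d | evaluation ages for genomic curves |
| `tol` (solver) | 1e-9 | relative duality-gap stopping rule |

The penalty is chosen per (trait, $\tau$) as the grid value maximizing
*predictive capacity* — the Pearson correlation between fitted and observed
trait values, computed in-sample by default. In-sample selection is the
package's default because the capacity criterion is defined on the data the
model was fit to; a k-fold cross-validated variant
(`select_lambda(method = "cv")`) is available for users who prefer
out-of-sample selection. Capacity ties are broken toward the *largest*
penalty, preferring the sparser model. Penalties so large that the fit
collapses to a constant have undefined capacity and are rejected. Goodness
of fit is reported as the Koenker–Machado pseudo-$R^1$,
$1 - V_{\mathrm{full}}/V_{\mathrm{null}}$, the check-loss analogue of
$R^2$ with the sample $\tau$-quantile as the null model.

Bootstrap inference uses case (paired row) resampling with 200 replicates
by default; per-marker standard errors are bootstrap standard deviations
and p-values use the normal approximation $2(1 - \Phi(|\hat\beta_k|/se_k))$
— only standard errors, not percentile intervals, are needed for the marker
tables, which is why the normal form was chosen. A marker excluded by the
penalty in every replicate reports $se = 0$ and $p = 1$. Confidence bands
for the mean genomic curve are percentile intervals across the replicate
mean curves (95% by default); band-versus-band overlap across quantiles is
a reported visual, not a formal test.

The "most relevant" marker lists keep the top
$\lceil \mathrm{fraction} \times p \rceil$ markers by $|\hat\beta|$ —
with the default 2.5% of a 237-SNP panel, six markers per (trait, $\tau$)
block — with ties at the cutoff resolved toward the lower marker index.

## The synthetic F2 generator

No individual-level dataset of the motivating design is publicly deposited,
so the package ships a simulator whose **defaults are the study
conditions**: 345 F2 animals, 237 SNPs on six chromosomes (56, 54, 59, 31,
25, 12 markers; the X treated as autosomal since no sex-linked model is
specified), weights at 0, 21, 42, 63, 77, 105, 150 days, population-mean
parameters (89.43 kg, 113.18 d, 32.03 d) taken from the corrected-trait
means of the motivating population, and a weight-noise SD rising from
0.25 kg at birth to 3.25 kg at 150 d — the fan shape real weight-age data
show. Chromosome lengths (160, 130, 150, 120, 70, 100 cM) are realistic
pig map lengths chosen once.

Founder lines are fixed for alternate alleles, F1s are uniformly
heterozygous, and each F2 genotype sums two F1 gametes generated by a
Markov walk with Haldane (no-interference) recombination fractions
$r = (1 - e^{-2d/100})/2$ — the simplest defensible LD-generating
mechanism for an F2, chosen because the motivating analysis does not model
recombination at all. Per-animal true parameters are base values plus
additive marker effects plus categorical covariate shifts (modest sex, lot,
and halothane effects by default). Optionally, an animal-level trait noise
whose SD scales with the mean genotype at that trait's effect markers
(`het_scale`) produces *quantile-heterogeneous* marker effects — upper
trait quantiles see larger effective effects than lower ones — which is the
mechanism used to demonstrate separating genomic curves; the default is
homogeneous effects with heterogeneous age noise only.

What the simulator does **not** emulate: the real population's LD structure
(the actual chip targeted previously mapped QTL), genotyping error, sex
linkage on the X, selection, or pedigree structure beyond F0–F1–F2.
Passing recovery tests on simulated data therefore demonstrate that the
estimator works when its assumptions hold, not that any particular real QTL
would be found.

## Numerical choices and degenerate inputs

* Logistic fits use Levenberg-damped Gauss–Newton (via `minpack.lm`) with a
  self-start: $\alpha_1^0 = 1.05\max_j w_j$, $\alpha_2^0$ the interpolated
  age at half that asymptote, $\alpha_3^0$ from the slope of
  $\mathrm{logit}(w/\alpha_1^0)$ on age; relative tolerance $10^{-8}$, at
  most 200 iterations. A fit whose asymptote leaves the sanity band
  $[\max w,\, 10 \max w]$, or whose scale is non-positive, is flagged
  non-converged rather than reported. Non-converged animals are dropped
  from step two with a logged count. Curvature-free series (constant
  weights) return a flagged non-fit, never an error; fewer than four
  observations is an error, since three parameters would be unidentified.
* Missing genotype calls are a hard error by default — the genomic model
  needs complete $x_{ik}$ — with opt-in per-marker mode imputation (ties to
  the smallest call).
* A confounded fixed-effect design triggers a warning and proceeds with the
  least-squares solution with aliased levels absorbed; single-level factors
  are dropped from the model formula.
* Bootstrap coefficient replicates are snapped to zero below a
  $10^{-8}$-relative threshold so that penalty-excluded markers report
  exactly $se = 0$, $p = 1$ instead of interior-point dust.
* All randomized operations (simulation, bootstrap, CV folds) take explicit
  integer seeds and are bit-reproducible.

## Problem sizes used in the shipped checks

The test suite exercises the solver-versus-oracle battery on 200 random
instances with $n \le 8$, $p \le 2$ (the regime where vertex enumeration is
exact and fast); monotone-shrinkage on a simulated $n = 200$, $p = 50$
instance over the full default penalty grid, on a standardized trait with
moderate planted QTL (2 and $-1.5$ kg) so that the grid top lies beyond the
zero-coefficient threshold — with unit response scale the subgradient bound
puts that threshold near 30–40, inside the grid; and a 20-seed end-to-end
recovery study at $n = 300$, $p = 100$ with five planted mature-weight QTL.
For the recovery study the weight-noise schedule is reduced to 0.1–0.4 kg
so that the mature-weight estimation SD is about 1.8 kg and the planted
per-allele effects (9–11 kg) are at least five times that spread — under
the default fan schedule the asymptote's estimation SD is ~20 kg, and no
admissible effect size (the model requires $\alpha_1 > 0$ for every
genotype combination) could be "strong" in that sense. The recovery
criterion asks that all five true markers appear in the union over
$\tau \in \{0.2, 0.5, 0.8\}$ of the per-$\tau$ six-marker top lists for the
mature-weight trait; six is the block size the 2.5% convention yields on a
237-marker panel, and is used as the fixed "top set" size here because
2.5% of 100 markers (three) could never contain five true effects. The
recovery battery selects its penalty over the reduced grid
$\{0, 0.5, 2, 8\}$; penalty *selection* behaviour over the full grid is
covered by the dedicated shrinkage and selection tests.

## Known limitations

* Quantile crossing is not corrected: curves fitted at different $\tau$ can
  cross, especially in sparse-data regions.
* Predictive capacity is an in-sample criterion by default and will favour
  weak penalties when $p$ approaches $n$; use the CV mode there.
* The bootstrap normal-approximation p-values ignore the selection event
  induced by the penalty; they are descriptive, as in the marker tables
  they accompany.
* The multi-trait pedigree REML analysis that often accompanies this kind
  of study (heritabilities, genetic correlations) is out of scope: it
  requires pedigree data and standard mixed-model software, not this
  package's estimator.
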