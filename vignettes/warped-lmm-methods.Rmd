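---
title: "Warped linear mixed models: model, estimation and design notes"
author: "warplmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warped linear mixed models: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warplmm)
```

## The problem

Linear mixed models (LMMs) are the workhorse of quantitative genetics:
heritability estimation, genomic prediction and mixed-model association
scans all assume the phenotype is Gaussian *after* removing fixed and
polygenic random effects. Measured traits rarely satisfy this on their
raw scale, and the usual remedy — picking a log, square-root or Box-Cox
transform by eye or by marginal normality — conflates two different
goals: the residuals, not the phenotype itself, should be Gaussian under
the fitted *genetic* model. A transform chosen against the null model can
therefore be the wrong one, and the choice feeds through to biased
heritability estimates and lost association power.

`warplmm` treats the transformation as part of the model. The observed
phenotype $y_n$ of individual $n$ is modelled as a monotone,
parametric, invertible map of a latent Gaussian trait,

$$ z_n = f(y_n; \psi), \qquad
   \mathbf z \sim \mathcal N\!\left(X\beta,\;
   \sigma_g^2 K + \textstyle\sum_j \sigma_j^2 \mathbf g_j \mathbf g_j^\top
   + \sigma_e^2 I\right), $$

where $K = GG^\top/S$ is the realized-relationship (kinship) matrix of
the $N \times S$ column-standardized genotype matrix $G$, the optional
rank-one terms carry forward-selected large-effect loci, and $\psi$ are
the warp parameters. All parameters are estimated together.

## The extended likelihood

Maximizing the Gaussian likelihood of $\mathbf z$ alone would reward
warps that simply shrink the data. The correct objective is the density
of the *observed* data, which adds the Jacobian of the transformation:

$$ -\log L(\psi, \beta, \sigma^2)
   = \tfrac12\log|2\pi\Sigma|
   + \tfrac12 (\mathbf z - X\beta)^\top \Sigma^{-1} (\mathbf z - X\beta)
   - \sum_n \log f'(y_n; \psi). $$

The Jacobian term penalizes flattening: a warp can only improve the fit
by making the residual distribution more Gaussian, not by making it
smaller. `extended_nll()` evaluates this quantity at a given state;
`wlmm_fit()` minimizes it.

One exact symmetry deserves note: post-composing $f$ with any affine map
leaves the objective unchanged (the variance components, intercept and
Jacobian absorb it exactly). The latent scale and origin are therefore
pure gauge freedoms. Heritability, association p-values and
back-transformed predictions are all invariant to them, but an optimizer
left free to move along the flat directions can drift the numerical
representation of $\mathbf z$ into degenerate territory — a collapsed
scale, or (when a saturated step carries a huge constant, which is how
the tanh family legitimately emulates exponential shapes) a mean many
orders of magnitude larger than the spread, either of which destroys the
downstream linear algebra by cancellation. We pin both gauges: the
linear slope is fixed at 1 during optimization, and the fitted warp is
shifted so the phenotype median maps to 0 (the `shift` field of
`warp_params`). Neither costs any generality.

## Warping families

The default family is a linear term plus $I$ tanh step functions,

$$ f(y) = d\,u + \sum_{i=1}^{I} a_i \tanh\!\big(b_i (u + c_i)\big),
   \qquad u = \frac{y - \mathrm{med}(y)}{\mathrm{MAD}(y)}, $$

with step size $a_i \ge 0$, steepness $b_i \ge 0$ and location $-c_i$.
Monotonicity is guaranteed by construction for $d > 0$, $a_i, b_i \ge 0$;
the optimizer works with $\log a_i$ and $\log b_i$ so the constraint can
never be violated. The median/MAD pre-scaling (recorded inside the
stored `warp_params`, so serialized warps always act on the original
measurement scale) makes the default step locations — the quartiles of
$u$ — and step widths unit-free. We use $I = 3$ steps by default; this
follows the family's original recommendation and was robust across all
our simulations. A one-parameter Box-Cox family
($f(y) = (y^\lambda - 1)/\lambda$, $\log y$ at $\lambda = 0$, positive
phenotypes only) plus fixed `log` and `identity` warps are also
available; with `family = "identity"` the fit reduces exactly to
standard LMM maximum likelihood, which is tested.

The tanh family can only represent bounded deviations from a straight
line: far outside the data range it reverts to linear growth. For a
fully log-like target this means the recovered transform matches the log
over the data mass but not in the extreme tails. We assess recovery with
bulk statistics (median deviation from the best affine fit, $R^2$)
rather than sup-norms on tails where no data constrain the fit. A second
consequence of unpenalized maximum likelihood is that the fitted warp may
place an occasional very steep step that absorbs a local quirk of the
empirical distribution; this is a real feature of the likelihood surface,
is harmless for the downstream estimates (the affected mass is tiny), and
is why "near-linearity on linear data" is also asserted for the bulk.

Inversion (`invert_warp()`, used for predictions on the original scale)
runs Newton–Raphson from the linear part with a bisection fallback on a
bracket that always exists by monotonicity; round-trips are exact to
1e-8 by test.

## Estimation

For fixed variance *ratios* $\delta_g = \sigma_g^2/\sigma_e^2$ (and
$\delta_j$ for selected loci), $\beta$ and $\sigma_e^2$ have closed-form
profiles on the basis that diagonalizes $K$. We eigendecompose $K$ once
per data set; every objective evaluation then costs $O(N^2)$ (one
rotation of $\mathbf z$) instead of $O(N^3)$. Rank-one components enter
through a Woodbury update of the diagonal, so up to tens of selected
loci add negligible cost. The remaining parameters — warp parameters and
log variance ratios — are optimized by L-BFGS-B with fully analytic
gradients (envelope theorem across the profiled $\beta, \sigma_e^2$);
the gradients are verified against central finite differences to 1e-5
in the test suite. Convergence uses the optimizer's relative-change
rule (`factr = 1e7`, i.e. ~1e-9 relative); because the objective is
multi-modal in $\psi$, the best of 5 seeded restarts (near-identity
warp plus jitter) is returned, and fits are deterministic given the
seed.

Two numerical corners are handled explicitly. First, with
column-centred genotypes the vector of ones is a null vector of $K$; if
the design contains an intercept and $S \ge N$, the profiled *ML*
criterion decreases without bound (slowly, $-\tfrac12\log\delta$) as
$\delta \to \infty$. Variance-ratio searches therefore scan a coarse
log-spaced grid first and refine the interior optimum, flagging
boundary solutions. Second, final variance components are re-estimated
by REML on the fitted $\mathbf z$ (with $K$ only), which does not share
the ML degeneracy and is the conventional estimator for reported
heritabilities; the joint warp fit itself uses ML because the Jacobian
term belongs to a full likelihood.

## Forward selection of large-effect loci

A kinship built from all SNPs under-represents sparse architectures.
After each joint fit, every SNP is tested as a fixed effect against the
current transformed phenotype under the current covariance
(likelihood-ratio test, 1 df, with the variance ratio re-profiled per
SNP on a dense log grid around the exact null optimum — the grid always
contains the null optimum, so statistics are non-negative; a
fixed-covariance mode is exact GLS and is verified against a dense
oracle to 1e-8). If the smallest Storey q-value is at most 0.05, that
SNP enters the model as a *random* effect (a rank-one variance
component, never a fixed effect), and the model is refit from the
previous optimum; the loop stops when nothing is significant or after
20 iterations (a safety cap). Ties are broken by genomic position, then
identifier. New components start at the variance their scan statistic
implies (the log-scale gradient vanishes at zero variance, so a tiny
start would leave them inert); if the refit lands in a worse local
valley, a second start from the previous optimum with the component
switched off guarantees the extended NLL is non-increasing across
iterations (tested).

Selected components exist to improve the reconstruction of the
transformation. They are excluded from reported heritability and from
prediction, and a regression test asserts that adding components changes
neither output. For small numbers of tests ($S < 100$) the Storey
smoother for $\pi_0$ is unstable and we fall back to $\pi_0 = 1$, which
makes the q-values equal to Benjamini–Hochberg adjusted p-values.

## Applications

**Heritability.** `estimate_h2()` reports
$\hat h^2 = \hat\sigma_g^2 / (\hat\sigma_g^2 + \hat\sigma_e^2)$ from a
REML re-fit on $\mathbf z$ with $K$ only. An optional bootstrap (10
resamples of 90% of the samples) gives an empirical SD.

**Prediction.** `predict()` computes the BLUP
$\hat z_* = x_*\hat\beta + \hat\sigma_g^2 \mathbf k_*
(\hat\sigma_g^2 K + \hat\sigma_e^2 I)^{-1} (\mathbf z - X\hat\beta)$
for new samples (with $\mathbf k_*$ from `kinship_cross()`, which
standardizes test genotypes with the *training* per-SNP centre and
scale), then maps back to the measurement scale through the inverse
warp. This matches a dense conditional-Gaussian oracle to 1e-8 by test.

**GWAS.** `gwas_scan()` transforms the phenotype through a warp learned
with forward selection (so large-effect loci do not distort the
transformation), then scans every SNP on $\mathbf z$ under
$\hat\sigma_g^2 K + \hat\sigma_e^2 I$, reporting p-values, Storey
q-values, the genome-wide threshold $5\times 10^{-8}$ and the
genomic-control inflation factor $\lambda$. No leave-one-chromosome-out
kinship is used by default; the scan's calibration under a polygenic
null is a tested property ($\lambda$ within $1.00 \pm 0.05$).

## The simulator

`sim_config()` / `simulate_dataset()` generate the study conditions the
estimators are validated under: biallelic dosages
$\mathrm{Bin}(2, \mathrm{maf}_s)$ with $\mathrm{maf}_s \sim
U(0.05, 0.5)$ and *no linkage disequilibrium*; Gaussian causal effects
on standardized dosages; an optional covariate; and Gaussian noise. The
genetic, covariate and noise pieces are orthogonalized in sample and
rescaled so the realized variance fractions equal the configuration
*exactly* — heritability bias can then be measured against a constant
rather than a random variable. The observed phenotype blends the latent
trait with a nonlinear transform,

$$ y_{\mathrm{obs}} = t\,y + (1 - t)\, f_{\mathrm{sim}}(y), \qquad
   f_{\mathrm{sim}}(y) = \exp\!\big((y - \bar y)/s_y\big), $$

so $t = 1$ is the untransformed (linear) limit and $t = 0$ the fully
nonlinear one, where the ideal recovery transformation is the log. The
exponential acts on the standardized latent trait to avoid overflow; its
centre and scale are recorded in the truth record.

What the simulator does *not* emulate: linkage disequilibrium (the bias
estimand — variance fractions — does not depend on it for unlinked
causal variants, and `run_bias_experiment()` accepts user genotypes when
realism matters), minor-allele-frequency/effect-size coupling,
non-Gaussian effect-size distributions, and heteroscedastic noise on the
latent scale (a stated model assumption: the warp assumes constant noise
after transformation, so count-like or binary traits are better served
by generalized LMMs).

`run_bias_experiment()` ties it together: for each grid cell and
estimator (`warpedlmm`, `lmm_raw`, `lmm_log` with a positivity shift
when needed, `lmm_boxcox` via the classical marginal Box-Cox fit) it
simulates replicates, estimates $h^2$ and tabulates the bias. Identical
seeds give bit-identical tables.

## Problem sizes and what the tests show

The default validation cell is $n = 1000$ samples, $S = 2000$ SNPs,
$h^2 = 0.4$, 100 causal variants, 50 replicates — large enough that the
estimator's own sampling noise, not the warp recovery, dominates the
spread of $\hat h^2$ (the per-replicate SD of a kinship-REML estimate
here is $\approx \sqrt{2S/N^2} \approx 0.06$, so a 50-replicate mean
carries a standard error near 0.009, i.e. roughly 2% relative at
$h^2 = 0.4$). The robustness-at-linear-truth comparison runs at
$n = 600$, $S = 1200$; the selection and power experiments at
$n = 500$–$800$ with $S = 600$–$1000$. The association-power comparison
(warped vs raw scan at a planted 1%-variance locus) uses a 2-sigma
exponential distortion; this intensity was chosen by requiring that an
*oracle* scan on the true latent trait separates clearly from the
raw-scale scan at this effect size — under a milder 1-sigma exponential
even the oracle beats the raw scan in only ~70% of seeds, so no method
could demonstrate a power gain there. The warped scan is then held to
the oracle's standard. These sizes are the package's
choice of a desk-scale design whose Monte-Carlo error is small relative
to the effects being demonstrated. Passing tests show that the estimator
chain is correct and calibrated *under the simulator's assumptions*;
they do not by themselves certify behaviour under strong LD, ascertained
sampling or non-Gaussian effect sizes.

## Known limitations

- Constant latent-scale noise is assumed; the model is not a substitute
  for generalized LMMs on counts or binary traits.
- The tanh family reverts to linear outside the data range, so
  extrapolated inverse predictions far beyond the training phenotype
  range inherit that shape.
- The heritability reported is the latent-scale chip heritability; it is
  not comparable across different fitted warps except through the model.
- Maximum likelihood over a flexible warp can mildly overfit at small
  $n$; the Jacobian term controls but does not eliminate this.
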