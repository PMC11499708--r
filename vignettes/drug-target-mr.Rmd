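---
title: "Drug-target Mendelian randomization with correlated instruments: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The design

Two-sample drug-target MR estimates the effect of pharmacologically
modulating a protein target on a disease outcome, using only GWAS summary
statistics. Instruments are variants in or near the gene encoding the target
(a cis window of ±500 kb by default) that associate with a biomarker of the
drug's action — in the motivating application, HbA1c variants near *ABCC8*
proxying sulfonylurea-receptor inhibition, with primary open-angle glaucoma
as outcome and intraocular pressure (IOP) as candidate mediator. Because a
cis region rarely contains many independent signals, instruments are pruned
only to *weak* LD (r² < 0.30) to preserve variance explained, and the
residual correlation is carried into estimation rather than assumed away.

Identification rests on the usual instrumental-variable assumptions:
relevance (checked via F statistics, conventionally F ≥ 10), independence
from confounders, and exclusion (no outcome pathway bypassing the exposure).
The sensitivity suite exists because exclusion is untestable directly.

## Estimators

**Correlation-adjusted IVW (primary).** With exposure effects $\beta_X$
(per SD), outcome effects $\beta_Y$ (log-OR), outcome SEs $\sigma_Y$ and
instrument correlation matrix $\rho$, set
$\Omega = D\rho D$, $D = \mathrm{diag}(\sigma_Y)$. The estimator is GLS
through the origin,
$\hat\theta = (\beta_X^\top \Omega^{-1}\beta_X)^{-1}\beta_X^\top\Omega^{-1}\beta_Y$,
with fixed-effect variance $(\beta_X^\top \Omega^{-1}\beta_X)^{-1}$ and
generalized heterogeneity
$Q = (\beta_Y - \hat\theta\beta_X)^\top\Omega^{-1}(\beta_Y - \hat\theta\beta_X)$
on $k-1$ df. "Random effects" is handled multiplicatively — the SE is
inflated by $\max(1, \sqrt{Q/(k-1)})$ — the convention for summary-data MR
with overdispersion; an additive $\tau^2$ variant was deliberately not used
because with a handful of correlated cis instruments $\tau^2$ is poorly
identified. With identity $\rho$ the estimator reduces algebraically to the
classical IVW ratio form (a test asserts agreement to 1e-10), and with one
instrument to the first-order Wald ratio $\beta_Y/\beta_X$ with SE
$\sigma_Y/|\beta_X|$ — higher-order delta terms are omitted, which slightly
understates uncertainty for weak single instruments (the single-instrument
ancestry analyses this mirrors share that caveat).

**MR-Egger** adds an unconstrained intercept to the same GLS; a non-zero
intercept estimates directional pleiotropy. Instruments are first oriented
so all $\beta_X \ge 0$ (the InSIDE convention; LD rows of flipped variants
change sign). The intercept p-value uses a t distribution on $k-2$ df, SEs
inflated by $\max(1, \sqrt{Q/(k-2)})$.

**Weighted median** takes per-SNP ratios $r_j = \beta_{Y,j}/\beta_{X,j}$
with weights $w_j = \beta_{X,j}^2/\sigma_{Y,j}^2$ and interpolates the value
at cumulative normalized weight 0.5; consistent when valid instruments carry
at least half the weight. **Simple/weighted mode** maximize a
normal-kernel-smoothed density of the ratios (bandwidth
$0.9\,\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$ times a user factor,
defaulting to 1; a degenerate spread falls back to sd and then to a small
floor so identical ratios return that ratio). Median and mode SEs come from
a parametric bootstrap (normal draws of $\beta_X$, $\beta_Y$; default 5,000
replicates, seed recorded). All robust estimators require $k \ge 3$ and
report not-applicable below that rather than erroring, since single-SNP
instruments are a legitimate outcome of cis selection.

Whether the robust estimators should reuse the LD adjustment of the primary
IVW is genuinely open; here the regression-type estimators (`ivw_correlated`,
`mr_egger`) take `use_ld` with default TRUE, and the ratio-based median/mode
operate on per-SNP ratios as usual.

## Diagnostics

**MR-PRESSO.** The observed residual sum of squares uses leave-one-out
predictions (each variant's residual against the slope fitted without it),
weights $1/\sigma_Y^2$; the null distribution is simulated parametrically
under the fitted no-pleiotropy model and the identical LOO procedure
(default 1,000 draws; the attainable p granularity is $1/(n_{sim}+1)$).
Per-variant outliers are declared at Bonferroni $0.05/k$, and a corrected
IVW excluding them is reported alongside — never silently replacing — the
primary estimate. The procedure assumes approximately independent
instruments, so it uses diagonal weights even when $\rho$ is not identity;
with block LD of the strength pruning permits (r² < 0.30) the calibration
tests still hold.

**Steiger directionality.** $r^2_X = \sum 2p(1-p)\beta_X^2$ per SD;
for a binary outcome the observed-scale approximation
$r^2_Y = \sum 2p(1-p)\beta_Y^2 K(1-K)$ (case fraction $K$) is used rather
than a full liability transformation — a documented simplification that is
conservative in the regimes tested, where the exposure-side $r^2$ dominates
by orders of magnitude. The p-value is a two-sample z test on Fisher-
transformed correlations.

**Leave-one-out** recomputes the primary estimator $k$ times and flags
exclusions that change the sign or leave the full-set CI.
**Confounder screening** joins instruments (and proxies at r² > 0.8) to a
local annotation table at p < 5e-8; it reports and never filters, because
instrument exclusion on phenome evidence is a judgment call.

## Meta-analysis, mediation, power

Per-cohort estimates are pooled by DerSimonian–Laird:
$\tau^2 = \max\{0, (Q-(k-1))/(\sum w - \sum w^2/\sum w)\}$, normal CIs.
With three cohorts, Hartung–Knapp adjustment would widen CIs
substantially and was not used; the choice is visible in the pooled-CI
tolerance of the tests. Printed ORs/CIs convert to log scale with
$SE = (\ln U - \ln L)/(2 \times 1.959964)$.

Two-step mediation multiplies the exposure→mediator effect $a$ (SD/SD, from
the same cis instruments) by the mediator→outcome effect $b$ (log-OR/SD,
from mediator instruments, supplied as an estimate):
indirect $= ab$, direct $=$ total $- ab$ (identities held exactly),
proportion $= ab/$total, reported only when indirect and total share sign.
A parametric bootstrap over the three inputs (default 10,000 draws) gives
SEs and a normal two-sided p for the proportion. The total effect divides
the pooled estimate — with the printed per-cohort inputs only the pooled
value is consistent with the published mediated share.

Binary-outcome power uses the Wald approximation
$z = |\ln OR|\sqrt{n\,r^2\,K(1-K)}$; a Monte-Carlo test confirms it within
binomial error. Bonferroni across targets is $0.05/m$ with strict
inequality ($m = 4$ targets gives 0.0125).

## The simulator and what passing tests mean

`simulate_region()` draws, for $m$ variants in an exchangeable-LD block
(single correlation $\rho$): MAFs uniform on the configured range; true
joint per-SD exposure effects $|N(0.08, 0.02^2)|$ (biobank-scale cis signal
— z around 10–20 at $n = 10^5$, keeping weak-instrument bias in the IVW
below the 0.02 recovery tolerance); marginal truth $\rho\gamma$; sampling
noise MVN with cross-SNP correlation $\rho$ and SEs $1/\sqrt{2p(1-p)n}$
(quantitative, per-SD) or $1/\sqrt{nK(1-K)2p(1-p)}$ (binary outcome,
default case fraction 0.024, the European glaucoma case proportion at the
study's combined scale). A configured fraction of variants receives direct
outcome effects $N(\mu_{pleio}, \sigma_{pleio})$; the mediator is
$a\,\beta_X$ plus noise, sharing the exposure's sample size. Truth objects
carry $\theta$, per-SNP pleiotropy, $ab$ and $ab/\theta$.

The generator deliberately omits: decaying LD maps (exchangeable blocks
suffice to exercise the correlation-adjusted contract, not to emulate fine
structure), allele-frequency drift between cohorts, sample overlap,
selection into GWAS, and liability-scale subtleties of binary traits. So
the passing calibration/recovery tests demonstrate correctness of the
estimators under their stated models — not robustness to the full
messiness of real consortium data.

Validation problem sizes — 500 replicates for recovery/coverage and Egger
calibration, 200 for the PRESSO/Steiger properties, 2,000 Monte-Carlo draws
per power setting — were chosen to make binomial error small relative to
the property bands while keeping the whole suite comfortably interactive.

## Numerical choices and edge cases

- LD matrices are symmetrized and eigenvalue-checked; numerically singular
  matrices get a logged 1e-6 ridge; eigenvalues below −1e-8 are an error.
- p thresholds, r² thresholds and Bonferroni all use strict inequalities;
  cis windows are 1-based inclusive and clamp at position 1.
- Greedy pruning ranks by ascending p with lexicographic SNP-id tie-break;
  proxy ties break by r², then genomic distance, then id — all for
  determinism.
- Palindromic variants resolve by frequency only when both traits are
  informative (|EAF − 0.5| > 0.08, a common default; the window is a
  parameter); otherwise dropped with a reason code.
- Zero exposure effects are excluded from ratio-based estimators with a log
  entry; `se ≤ 0`, EAF outside (0,1) and identical alleles are dropped at
  read time with per-reason counts.
- All randomness (simulator, bootstraps, PRESSO null) flows from explicit
  seeds recorded in results; reruns are bit-identical.

## Limitations

Beyond the simulator's scope above: the package does not do multivariable
MR, colocalization, conditional/joint instrument selection or genome-build
liftover; the mediator→outcome estimate in the mediation step is an input
(mediator instruments are typically genome-wide, outside the cis design);
and proxy/confounder lookups use local tables, not live services, by
design — reproducibility over convenience.
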