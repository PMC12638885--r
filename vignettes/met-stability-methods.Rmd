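---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Plant breeders evaluate candidate genotypes in multi-environment trials
(METs): the same G genotypes grown in E location-year environments, with R
replicate blocks per environment (an RCBD repeated across environments).
Because genotypes respond non-uniformly to environments —
genotype-by-environment interaction (GEI) — the genotype with the best
average is not automatically the best choice. metstab implements a
multi-model analysis of balanced METs that quantifies GEI from several
angles and combines mean performance and stability into a single selection
decision across multiple traits.

The observational model throughout is

$$y_{ijr} = \mu + g_i + e_j + (ge)_{ij} + b_{r(j)} + \varepsilon_{ijr},$$

with genotype effects $g_i$, environment effects $e_j$, interaction
$(ge)_{ij}$, blocks nested in environments $b_{r(j)}$, and plot error
$\varepsilon_{ijr}$. All closed forms assume balance, and unbalanced data
are rejected with an explicit error rather than silently accommodated:
every shrinkage and stratum identity used downstream is exact only for the
balanced design.

## Pipeline stages

### Trait screen

Pearson correlations are computed between genotype means across
environments (not plot-level records), with two-sided p-values from the
$t$ transform with $n-2$ df. Traits positively and significantly
($\alpha = 0.05$ by default) correlated with the focal trait are retained;
a forced-keep list covers agronomic judgment calls such as retaining
maturity despite a non-significant association. No multiplicity adjustment
is applied to the pairwise tests — the screen is descriptive, and that
choice affects only borderline traits.

### YREM

Yield relative to the environmental maximum divides each cell mean by the
best cell mean in its environment, $Y_{ij} = X_{ij} / \max_i X_{ij}$, and
averages over environments. Because the environmental main effect cancels,
$1 - \mathrm{YREM}$ isolates the yield a genotype loses to *crossover* GEI.
Ties at the environment maximum all receive 1; the per-genotype average is
unweighted. Ranks descend by average YREM with ties broken by mean yield,
then by label order.

### Joint ANOVA and AMMI

The joint ANOVA partitions plot variation into environment,
replicate-within-environment, genotype, GEI and residual. Genotype and GEI
are tested against the pooled residual; environment against the
replicate-within-environment stratum. The AMMI step then applies an SVD to
the double-centred matrix of cell means
$d_{ij} = \bar y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \bar y_{\cdot\cdot}$,
yielding $K = \min(G, E) - 1$ interaction principal component axes with
singular values $\lambda_k$ and axis sums of squares $R\lambda_k^2$ on the
plot basis. Axis significance uses the Gollob convention
($\mathrm{df}_k = G + E - 1 - 2k$, F against the pooled residual), chosen
because it is the common default that makes published significance stars
reproducible; it is known to be liberal relative to resampling-based
tests. Percent-of-SS is reported over the E + G + GEI total, the three-way
framing conventional in MET reports.

### REML, BLUP and genetic parameters

With environment and replicate-within-environment fixed and genotype and
GEI random, the restricted likelihood of the balanced model factorises
over three orthogonal strata with variances
$\lambda_G = \sigma^2_e + R\sigma^2_{gei} + ER\sigma^2_g$,
$\lambda_I = \sigma^2_e + R\sigma^2_{gei}$ and $\lambda_e = \sigma^2_e$,
carrying the genotype, interaction and residual sums of squares. An
interior REML optimum therefore equals the stratum mean squares — exactly
the expected-mean-squares (EMS) estimates
$\hat\sigma^2_e = MS_{err}$,
$\hat\sigma^2_{gei} = (MS_{GEI} - MS_{err})/R$,
$\hat\sigma^2_g = (MS_G - MS_{GEI})/(ER)$ — and the package takes it in
closed form. Only when a closed-form component is negative does a bounded
quasi-Newton search on log-variances (EMS start) locate the boundary
optimum, after which sub-epsilon variances are truncated to zero and
flagged. The test suite cross-checks components, BLUPs and LRT statistics
against lme4 on the same data.

Genotype BLUPs use the balanced shrinkage identity
$\hat g_i = h^2_{mg} (\bar y_{i\cdot} - \bar y_{\cdot\cdot})$ with the
heritability of genotype means
$h^2_{mg} = \sigma^2_g / (\sigma^2_g + \sigma^2_{gei}/E + \sigma^2_e/(ER))$.
Interaction BLUPs are the double-centred cell residuals shrunken by
$\sigma^2_{gei} / (\sigma^2_{gei} + \sigma^2_e / R)$. The exact
mixed-model-equation solution for $(ge)_{ij}$ additionally carries a
genotype-constant row component (its row sums are proportional to genotype
deviations); the package reports the double-centred matrix because the
stability index below decomposes interaction structure, and the
genotype-level information already lives in $\hat g_i$. The tests verify
that lme4's interaction BLUPs equal this matrix after row-centring.

Genetic-parameter summaries are closed forms of the components:
broad-sense $H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{gei} + \sigma^2_e)$,
the GEI coefficient of determination
$R^2_{gei} = \sigma^2_{gei} / (\sigma^2_g + \sigma^2_{gei} + \sigma^2_e)$,
the genotype-environment correlation
$r_{ge} = \sigma^2_{gei} / (\sigma^2_{gei} + \sigma^2_e)$, and the
selection accuracy $A_s = \sqrt{h^2_{mg}}$. Likelihood-ratio tests for the
random terms compare restricted log-likelihoods of the full model and the
model without the term, referred to $\chi^2_1$. The plain $\chi^2_1$
reference is used deliberately for comparability with conventional MET
reporting; for a variance component on the boundary it is conservative
(the 50:50 mixture reference would halve the p-values), and the
simulation tests confirm the type-I rate stays below nominal.

### WAASB, WAASBY, quadrants

WAASB scores each genotype by the weighted average of its absolute scores
over *all* K axes of the SVD of the interaction BLUP matrix,
$\mathrm{WAASB}_i = \sum_k |s_{ik}| EP_k / \sum_k EP_k$ with
$EP_k = \lambda_k^2 / \sum \lambda^2$ and symmetric-scaled scores
$s_{ik} = \alpha_{ik}\sqrt{\lambda_k}$; smaller is more stable. Using all
axes (no truncation) follows the index's definition; truncation is
available as an option. WAASBY blends the trait mean and WAASB after both
are affinely rescaled to $[0, 100]$ (stability inverted so that the most
stable genotype scores 100), with default weights 65/35 favouring
performance. All traits are rescaled larger-better by default — including
maturity — matching the sense column convention of the selection tables
this design follows; the direction is configurable per call.

The mean-vs-WAASB plane is split at the grand mean on the performance axis
(the stated convention) and at the mean WAASB score on the stability axis
(a package choice — the split point is not standardised anywhere; the
median would be an equally defensible alternative and differs only in
boundary cases). Quadrant IV (high mean, low WAASB) is the breeder's
target. Points exactly on a split line go to the high-mean / low-WAASB
side.

### MTSI

The genotype × trait table of WAASBY values is standardised (sample SD),
its correlation matrix eigen-decomposed, and factors with eigenvalue
greater than 1 retained (Kaiser rule). Retained loadings are
varimax-rotated, and factor scores use the regression (Thomson) method
$F = Z R^{-1} L$ on the rotated solution — the scoring method is a genuine
free choice; the regression method was selected because it is the default
of the reference implementations of this index family, and it is recorded
in the pipeline manifest. The ideotype scores 100 on every trait, is
standardised with the observed column means/SDs, and is scored through the
same transformation. MTSI is the Euclidean distance between a genotype's
factor-score vector and the ideotype's; selection takes the
$\lfloor 0.15\,G \rfloor$ smallest (intensity configurable). Selection
differential per trait is $SD\% = (X_s - X_0)/X_0 \times 100$ and the
expected gain $SG\% = SD\% \times h^2_{mg}$ — the heritability *of
genotype means*, not broad-sense $H^2$; only that definition is consistent
with the published response tables this implementation was validated
against.

## The synthetic generator

`generate_met()` simulates the observational model directly. Its defaults
are the conditions of the motivating horse gram trial: G = 30, E = 6,
R = 6, grand mean 938 kg/ha, and yield-scale components
$\sigma^2_g = 25425$, $\sigma^2_{gei} = 1663$, $\sigma^2_e = 2374$. The
trial report does not state environment or block variances; the defaults
$\sigma^2_{env} = 260$ (consistent with the small environment share of the
yield ANOVA) and $\sigma^2_{block} = 50$ are the package's own realistic
choices, fixed once. The interaction matrix is built from `gei_rank`
(default 2, matching the two dominant axes of this family of trials)
random orthonormal score pairs, is double-centred by construction, and is
scaled so that $\sum (ge)_{ij}^2 = (G-1)(E-1)\sigma^2_{gei}$ — the
normalisation on the interaction's degrees of freedom, which makes the EMS
estimator of $\sigma^2_{gei}$ unbiased for the configured value. With
multiple traits, genotype effects are drawn with a configurable cross-trait
correlation; interaction, block and error draws are independent across
traits, each on its own named sub-stream of the master seed.

Two modelling consequences are worth knowing. First, because the simulated
interaction matrix has exactly zero row sums, it contributes nothing to
the genotype stratum, so the REML/EMS estimand for the genotype variance
is $\sigma^2_g - \sigma^2_{gei}/E$ rather than $\sigma^2_g$ (about 1% low
at the default components); together with the downward skew of the
chi-squared median this places the median genotype-variance estimate about
3.4% below the configured value at the trial design — still within the 5%
recovery band the tests assert, which is why those tests run enough
replicates (1000) that Monte-Carlo error does not dominate the margin.
Second, the generator draws Gaussian, homoscedastic errors and a
low-rank interaction; real METs have heavier tails, heteroscedastic
environments and diffuse interaction structure, so passing tests
demonstrate correctness of the algorithms under the stated model, not
robustness to those departures.

## Numerical choices and degenerate inputs

* REML convergence: closed form where interior (exact); otherwise
  L-BFGS-B on log-variances with a tight factor (`factr = 1e3`) and
  truncation of variances below `1e-8` of the residual scale.
* SVD sign indeterminacy is harmless everywhere by construction: WAASB
  uses absolute scores, MTSI distances are invariant when the ideotype is
  scored under the same rotation/flip, and the tests assert both.
* Constant vectors cannot be rescaled to $[0, 100]$ and raise an error —
  a WAASB vector can only be constant when the interaction BLUP matrix is
  (numerically) zero, in which case stability is uninformative anyway.
* A genotype exactly at the ideotype has MTSI 0 and undefined factor
  shares; shares are reported uniform with a flag.
* Ties: YREM environment maxima all score 1; MTSI selection cuts break
  ties by label order with a warning; quadrant boundary points go to the
  favourable side.
* Negative EMS components truncate to zero with a `truncated` flag rather
  than erroring, matching how such estimates are handled in practice.

## Problem sizes used in the tests

Unit and property tests run on small designs (up to 12 × 4 × 3) plus a
handful of full 30 × 6 × 6 datasets; the parameter-recovery study uses
1000 simulated trials and the LRT size study 200 null trials at the full
design. The bundled worked-example tables (genotype means, variance
components, selection response of the horse gram trial) drive the
reproduction checks of the published summaries.

## Known limitations

* Balanced designs only; no missing-plot imputation, spatial models or
  multi-year weighting.
* Single-trait mixed models (multi-trait correlation enters only the
  generator and the screen); no pedigree/kinship.
* Principal-axis style factor extraction with varimax; no maximum
  likelihood factors or oblique rotations.
* The Gollob axis test is liberal; treat axis stars as descriptive.
* Graphics are out of scope: every figure-type result is emitted as a
  table (biplot scores, quadrant labels, eigenvalues, factor shares).
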