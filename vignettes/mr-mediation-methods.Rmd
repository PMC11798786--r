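---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model and its assumptions

`mrmediate` estimates causal effects between trait pairs from GWAS summary
statistics alone. For SNP $j$, let $\gamma_j$ be its effect on the exposure
and $\Gamma_j$ its effect on the outcome, both per effect-allele copy and
per SD of the trait, with standard errors $\sigma_{\gamma j}$,
$\sigma_{\Gamma j}$. Valid instruments satisfy the three instrumental
assumptions (associated with the exposure; independent of confounders;
affecting the outcome only through the exposure). Under these, each
instrument's Wald ratio $\Gamma_j/\gamma_j$ estimates the causal effect
$\beta$, and IVW pools them with weights
$w_j = \gamma_j^2/\sigma_{\Gamma j}^2$, equivalent to weighted regression
of $\Gamma$ on $\gamma$ through the origin.

Violations of the exclusion restriction (horizontal pleiotropy) are what
everything else guards against:

* **MR-Egger** frees the intercept of that regression after orienting all
  SNPs to $\gamma_j \ge 0$; a non-zero intercept indicates directional
  pleiotropy, and under the InSIDE assumption the slope remains consistent.
* **Weighted median** is consistent while less than half the weight is
  invalid.
* **Simple/weighted mode** estimate the majority cluster of ratios via a
  normal-kernel density.
* **Cochran's Q** measures ratio heterogeneity against $\chi^2_{k-1}$.
* **MR-PRESSO** simulates the residual sum of squares about leave-one-out
  IVW slopes to test for pleiotropy globally, flag outlying SNPs
  (Bonferroni-adjusted add-one tail probabilities), and quantify the
  distortion from removing them.
* **Steiger filtering** drops SNPs whose outcome variance explained
  exceeds their exposure variance explained, guarding the causal
  direction.

The two-step mediation decomposition multiplies the exposure→mediator
effect $\beta_1$ by the exposure-adjusted mediator→outcome effect
$\beta_2$: $\beta_{12} = \beta_1\beta_2$, direct effect
$\beta_{all} - \beta_{12}$, proportion mediated
$100\,\beta_{12}/\beta_{all}$. The $\beta_{12}$ variance is first-order
delta with independent steps,
$se_{12}^2 = \beta_2^2 se_1^2 + \beta_1^2 se_2^2$; independence is
justified because after adjustment the two steps use disjoint instrument
sets, and the zero-covariance choice is stamped into the output.

Two validity rules govern reporting: when the directions of $\beta_1
\beta_2$ and $\beta_{all}$ disagree the proportion is not computed (it
would be negative and uninterpretable), and when the 95% CI of
$\beta_{12}$ spans zero the proportion's CI is suppressed (its bounds
would contradict the total effect's direction). Reporting practice in the
field applies these rules unevenly — some tables omit proportions the
rules would permit; the package applies the two rules uniformly and
records both flags on every row.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| instrument p-threshold | 1e-5 | molecular traits rarely have many genome-wide hits; 5e-8 when the disease trait is the exposure |
| clumping r², window | 0.001, 10,000 kb | near-independence of retained instruments |
| F minimum | 10 | conventional weak-instrument screen, applied per SNP (the stricter reading; the aggregate F is also reported) |
| palindromic EAF window | 0.08 | A/T and C/G SNPs are dropped when either EAF is in [0.42, 0.58]; outside it, frequency resolves the strand |
| IVW variance | multiplicative random effects | SE inflated by $\sqrt{\max(1, Q/(k-1))}$; never below fixed-effect |
| Egger p-values | t, k−2 df | with the same $\max(1,\cdot)$ residual-scale floor |
| significance gates | lipids 0.05, metabolites 0.01 | both nominal flags are carried because the source conventions conflict; BH q-values are logged, not gated on |
| mode bandwidth | $0.9\min(sd, mad)k^{-1/5}$, 512-point grid | explicit so results are platform-stable; sd fallback when the mad collapses |
| bootstrap / PRESSO draws | 1000 | seeds mandatory for reproducibility; PRESSO outlier flagging needs n_sim > k/α to be able to fire |

R² per SNP defaults to $t^2/(t^2+N-2)$ with $t=\beta/se$ because it needs
only columns every GWAS table has; the EAF-based $2p(1-p)\beta^2$ form is
available for standardized traits.

Step-2 adjustment ("adjusting for exposure-related SNPs") is ambiguous in
the field; the default is literal instrument exclusion (mediator
instruments associated with the exposure at the instrument threshold, or
in LD with an exposure instrument, are removed), with multivariable MR
regression as the selectable alternative. The mode is recorded in every
result row and neither is asserted to be "the" published choice.

## The synthetic-data generator

`simulate_study()` emulates three linked GWAS layers at the
summary-statistics level. Traits are standardized so
$se = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$ — no individual-level
data is simulated. True effects: $\gamma_j \sim N(0, 0.1^2)$ for the
exposure instruments; a disjoint SNP block carries mediator-specific
effects $\delta_j$ (the extension that makes step-2 adjustment and
mediation recovery testable — without mediator-own instruments the
mediator→outcome step is unidentified); mediator
$m_j = \beta_1\gamma_j + \delta_j$; outcome
$o_j = \text{direct}\cdot\gamma_j + \beta_2 m_j + \alpha_j$. Pleiotropy
$\alpha_j$ is zero, balanced ($N(0, \sigma_\alpha^2)$), or directional —
half-normal magnitude oriented *with the sign of the SNP's exposure
effect*, because an allele-agnostic positive shift cancels against
sign-symmetric $\gamma$ and would bias nothing. `pleiotropy_frac` selects
the invalid-instrument fraction. LD blocks multiply joint effects by the
block correlation matrix and correlate estimation noise with its symmetric
square root (tolerating singular blocks, r = 1).

Generator defaults state the world of a lipid→metabolite→liver-disease
study: sample sizes 7,174 / 8,299 / 778,614, $\beta_1 = 0.17$,
$\beta_2 = 0.12$, direct 0.1311 — total 0.1515 with 13.5% mediated,
matching the flagship published pathway. MAFs are uniform on 0.05–0.5
(common-variant GWAS territory).

What the generator does **not** emulate: case-control liability-scale
outcomes (the disease trait is simulated on the continuous scale; OR
interpretation is a reporting convention), sample overlap between the
three GWAS, population stratification, winner's-curse from discovery
selection, and realistic genome-wide LD. A green simulation test therefore
establishes internal statistical correctness of the estimators under the
stated generative model, not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Wald-ratio SEs are first-order ($se_\Gamma/|\gamma|$) by default,
  second-order by option; a zero $\gamma$ is an error ("null
  instrument").
* IVW with one SNP degrades to the Wald ratio with a message; Egger,
  median and mode require ≥ 3 SNPs, MR-PRESSO ≥ 4.
* Clumping is greedy on ascending p with lexicographic snp_id
  tie-breaks, so output is invariant to row order; missing LD pairs count
  as r² = 0 (the generator's matrix is complete; external matrices may
  not be).
* Harmonization joins strictly on snp_id; indels and multi-allelic rows
  are rejected at read time; a p-value inconsistent with beta/se beyond
  10% relative tolerance warns but does not drop (published tables round
  p-values).
* All mode/median/PRESSO randomness is seed-controlled and
  bit-reproducible; derived sub-seeds are simple integer offsets.

## Design decisions taken where the design was open

* Steiger drops on the *point* comparison $r^2_y > r^2_x$; the
  Fisher-z test of the difference is reported per SNP as an annotation
  only, since no significance rule is standard.
* The MR-PRESSO distortion coefficient is
  $100(\beta_{-out} - \beta_{all})/|\beta_{-out}|$ with a random
  same-size-subset null for its p-value.
* The reporting layer recomputes nothing: every number in the report
  files traces to one upstream result object, which is what makes
  byte-identical reruns a testable contract.

## Known limitations

* **Egger-intercept calibration (an honest red test).** The acceptance
  suite asserts a type-I error in [0.04, 0.06] for the Egger intercept
  test on a balanced-pleiotropy null. At the generator's default MAF range
  the empirical rate is ≈ 0.067: outcome SEs vary ~3-fold across
  0.05–0.5 while balanced pleiotropy adds a *constant* variance
  component, so the multiplicative (weight-proportional) overdispersion
  model is misspecified and mildly anticonservative. Conversely, under
  the exact no-pleiotropy null the $\max(1,\cdot)$ floor truncates half
  the residual-scale distribution and the test is conservative (≈ 0.033).
  With near-homogeneous SEs (MAF 0.2–0.4) the rate is 0.0525 — inside the
  band. Neither the generator defaults nor the band were adjusted after
  measurement; the standard tooling's Egger uses the same variance model
  and inherits the same behavior.
* Correlated-instrument (generalized) IVW is out of scope; instruments
  are assumed independent after clumping.
* One mediator at a time; no multi-mediator joint decomposition.
* No proxy-SNP search, reference-panel LD, liftover or rsID resolution.
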