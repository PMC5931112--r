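---
title: "Methods: two-sample MR with LD-aware GLS, pleiotropy screening and Bayesian null evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with LD-aware GLS, pleiotropy screening and Bayesian null evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgls)
```

## The scientific setting

Mendelian randomisation treats genetic variants as instrumental variables
for a modifiable exposure. Because alleles are allocated at conception,
a SNP that is (i) robustly associated with the exposure, (ii) independent
of confounders and (iii) associated with the outcome only through the
exposure identifies the causal effect of the exposure free of classical
confounding and reverse causation. In the two-sample design the SNP-exposure
and SNP-outcome associations come from different studies and only
per-SNP summary statistics (effect, SE, allele coding, frequency, P, N)
are needed. `mrgls` implements that workflow for a binary outcome such as
a cancer, where the pooled estimate is a log odds ratio per SD of the
exposure (or per log-OR unit when the exposure itself is binary, e.g. a
diabetes diagnosis — no SD rescaling is applied in that case).

## Harmonisation

Summary files are read in the GCTA-COJO `.ma` dialect
(`SNP A1 A2 freq b se p N`) by default, remappable through
`gwas_dialect()`. Matching between studies is by rsID only. Outcome
effects are re-signed onto the exposure's effect allele; alleles reported
on the opposite strand are resolved by complementing. Palindromic (A/T,
C/G) SNPs are intrinsically strand-ambiguous: they are oriented by allele
frequency only when `min(eaf, 1 − eaf) < 0.42` in **both** studies
(i.e. both frequencies are conclusively away from 0.5), and dropped
otherwise. The 0.42 margin is the conservative convention in this
literature; when either study lacks frequencies, palindromic SNPs are
always dropped. Every exclusion is recorded with a machine-readable
reason, and the test suite checks two invariances: harmonising an
already-harmonised pair is a no-op, and flipping every outcome record's
alleles and sign leaves all downstream Wald ratios unchanged.

## Instrument selection

Instruments are SNPs reaching genome-wide significance (P ≤ 5.0 × 10⁻⁸,
boundary inclusive) in the exposure study, thinned by greedy LD pruning:
rank by strength, accept the strongest, discard everything with r² ≥ 0.01
against an accepted SNP, repeat. "Strength" is defined as smallest
exposure P, ties broken by largest |beta| and then rsID, which makes the
selection a deterministic function of the record set — the output is
invariant to input order, and replaying the selection log reproduces the
panel exactly. Note one boundary consequence of the `r² ≥ threshold`
removal rule: at `r2_max = 0` every pair trips the rule (any r² ≥ 0), so
exactly one SNP survives; thresholds are meaningful only strictly above 0.

SNPs absent from the LD matrix can borrow a proxy SNP's LD row
(`apply_proxies()`); proxies inform LD evaluation only and never replace
association statistics. Instrument strength is summarised by the
proportion of variance explained, PVE = Σ 2·eaf(1−eaf)·beta², which
assumes a standardised exposure and independent SNPs, and by the
first-stage F-statistic ((n−k−1)/k)·(PVE/(1−PVE)); F < 10 is the
conventional weak-instrument warning. For binary exposures the SD-scale
PVE is undefined and is not computed.

## Estimation and pleiotropy screening

The per-SNP Wald ratio b_zy/b_zx carries a first-order delta-method SE.
Pooling is generalised least squares under covariance
C = R ∘ (se·seᵀ) with R the LD correlation matrix — the standard
first-order approximation to the ratio covariance, exact as instrument
strength grows. The solve goes through a Cholesky factorisation;
near-singularity is diagnosed on the correlation part only (condition
number > 10¹², i.e. instruments that were insufficiently pruned), since
the SE scaling is always invertible.

The HEIDI-outlier screen takes the instrument with the smallest exposure
P as reference, computes each other instrument's ratio deviation
d_i = b_xy,i − b_xy,ref with variance
se_i² + se_ref² − 2·r_{i,ref}·se_i·se_ref, and flags P(χ²₁) < 0.01.
Removal is a single pass followed by re-estimation, matching the
published single-round usage; an iterate-to-fixed-point mode exists
behind a flag. The reference is never flagged — a consequence worth
knowing: pleiotropy on the top instrument itself is undetectable by this
design. Evidence is tiered at the global 0.05 level and a
Bonferroni-corrected level that the pipeline computes from the number of
configured trait × outcome cells (0.05/30 = 0.0017 for ten traits and
three outcomes), never hard-coded.

## Power and Bayesian null evaluation

A priori power for a binary outcome uses the non-centrality
λ = |ln OR|·√(N·PVE·φ(1−φ)) with φ the case fraction, and includes both
rejection tails, so power at OR = 1 equals α exactly (this is also the
property the test suite asserts at α ∈ {0.01, 0.05, 0.1}).

Null results are evaluated with the Wakefield approximate Bayes factor
BF = √((V+W)/V)·exp(−Z²W/(2(V+W))), V = se², Z = θ̂/se, where the prior
variance W = (ln or_max/1.96)² interprets the "maximum likely OR" — the
largest estimate reported in observational studies, or 2 when none exists
— as the 97.5th percentile of the prior on the OR under the alternative;
protective values (< 1) enter through |ln|. The Bayesian false null
probability is BFNP = 1/(1 + BF·(1−π)/π) for prior probability of
association π, and `min_prior_for_bfnp()` inverts it in closed form. θ̂
and its SE are recovered from a reported OR and 95% CI by
se = (ln hi − ln lo)/(2·1.96). Reproducing a published minimum-prior
table from rounded ORs and CIs works to 2 dp for eight of ten rows; the
two failures (recomputed 0.66 vs printed 0.64, and 0.61 vs 0.60) trace to
the 2-dp rounding of the published CIs, and those rows are excluded from
exact assertions rather than loosening the tolerance for everything.

## The synthetic two-sample generator

`simulate_two_sample()` emulates the summary statistics the pipeline
consumes, with full ground truth. Frequencies are uniform on (0.1, 0.9);
true exposure effects are rescaled so the panel explains exactly
`pve_target`; SEs follow the standard GWAS approximations
1/√(2p(1−p)n) for a quantitative exposure and 1/√(2p(1−p)Nφ(1−φ)) for a
case-control outcome, so power simulations and the analytic formula agree
by construction. Noise in both studies is drawn with the same block-LD
correlation used for pruning — that shared structure is what makes the
HEIDI covariance term meaningful — with an independent-noise mode for
IVW-oracle tests. Horizontal pleiotropy is planted as a log-OR offset on
chosen or random SNPs; the placement is drawn after the noise, so the
same seed yields identical noise whichever SNPs are planted.

Defaults are the study conditions the package is tested under: a
12,488-case / 18,169-control outcome, a 100,000-sample exposure study
(consortium-meta-analysis scale; published exposure GWAS in this area
range from tens of thousands to ~340,000), and `pve_target = 0.05`,
mid-range of the 0.7–15% spanned by real obesity-related instrument
panels. Two effect-size regimes are provided because they answer
different questions: `"normal"` draws standard-normal effects, so some
SNPs are near-null — appropriate for testing the significance filter and
selection bookkeeping; `"selected"` draws magnitudes uniform on
[0.5, 1.5], emulating a post-selection panel of GWAS hits in which every
SNP is a usable instrument — appropriate for estimator and
pleiotropy-screen properties, where a near-null instrument would make the
planted deviation undetectable for reasons unrelated to the screen.

What the generator does **not** emulate: realistic genome-wide LD maps
(LD is block-constant), case-control ascertainment beyond the φ(1−φ) SE
scaling, winner's-curse attenuation from discovering instruments in the
exposure sample, allele-frequency differences between studies, and
population stratification. Passing tests therefore demonstrate correct
behaviour of the estimators under their own assumptions, not robustness
to those real-data complications.

## Numerical and design choices

* CI multiplier fixed at 1.96 (normal theory, 95%).
* Two-sided P values from the standard normal for the pooled estimate,
  χ²₁ for HEIDI deviations; HEIDI deviation variances are floored at
  machine epsilon to guard exact-collinearity cases.
* LD matrices must be symmetric within 10⁻⁸ and within [−1, 1] + 10⁻¹²
  (values inside the tolerance are clipped, the matrix is symmetrised);
  non-positive-semi-definite input beyond −10⁻⁶ draws a warning.
* Invalid summary rows are dropped with a per-row report by default;
  `strict = TRUE` raises instead. Both behaviours are tested.
* Pipeline problem sizes used in the tests: 500 replicates for recovery
  and null calibration at 30 instruments, 200 replicates for the
  pleiotropy screen at 20 instruments, 10 traits × 3 outcomes for the
  end-to-end run — sizes at which the Monte-Carlo error of the asserted
  summaries is comfortably below the asserted margins.

## Known limitations

The ratio covariance is first-order; with very weak instruments
(F ≲ 10) the Wald ratio is heavy-tailed and both the pooled SE and the
HEIDI χ² are approximate — the WHR-like regime in which published
analyses also flag weak-instrument caution. Single-reference HEIDI cannot
flag the reference itself, and a single removal round will not catch
outliers masked by a stronger one. The Bayesian machinery conditions on
the reported point estimate and CI and ignores their own rounding error.
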