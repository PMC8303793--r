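---
title: "Methods: two-sample MR estimation, screening and causal-web classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation, screening and causal-web classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrweb` implements a complete two-sample Mendelian randomization (MR)
workflow over GWAS summary statistics. This vignette documents the models,
the assumptions behind each estimator, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where conventions diverge. No empirical claim is made here that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The instrumental-variable model

For SNP $j$, let $\beta_{Xj}$ be its effect on the exposure and
$\beta_{Yj}$ its effect on the outcome, estimated in two disjoint cohorts of
sizes $n_X$, $n_Y$. If the SNP is a valid instrument — associated with the
exposure, affecting the outcome only through the exposure, and unconfounded
— the Wald ratio $\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ estimates
the causal effect $\theta$, with first-order delta-method standard error
$se(\hat\beta_{Yj}) / |\hat\beta_{Xj}|$ (`wald_ratio()`; a second-order
variant including the exposure-side term is available via
`second_order = TRUE`, and is off by default because downstream weighting
conventions in this literature use the first-order form).

### IVW

`mr_ivw()` is the zero-intercept weighted regression
$\hat\beta_{Yj} = \theta\,\hat\beta_{Xj} + \epsilon_j$,
$\epsilon_j \sim N(0, \sigma^2 se(\hat\beta_{Yj})^2)$, i.e.
$\hat\theta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j \beta_{Xj}^2$ with
$w_j = 1/se(\hat\beta_{Yj})^2$. The fixed-effects SE is
$(\sum w_j\beta_{Xj}^2)^{-1/2}$. The random-effects variant — the primary
analysis throughout, because per-SNP ratios are not expected to be identical
even under a shared causal direction — uses multiplicative overdispersion:
$\hat\sigma^2 = \max(1, Q/(J-1))$ multiplies the squared SE, leaving the
point estimate unchanged. This is the dominant convention in two-sample MR
tooling; an additive-heterogeneity (DerSimonian–Laird) variant was
deliberately not implemented to keep the FE/RE point estimates identical.
P-values are two-sided normal.

### MR-Egger

`mr_egger()` frees the intercept:
$\hat\beta_{Yj} = \theta_0 + \theta_1 \hat\beta_{Xj} + \epsilon_j$. Each SNP
is first reoriented so $\beta_{Xj} > 0$ (negating both betas — this changes
nothing about the ratios but is required for the intercept to mean *average
directional pleiotropy*). The slope is the pleiotropy-adjusted causal
estimate under InSIDE (pleiotropic effects independent of instrument
strengths); the intercept test is the horizontal-pleiotropy test. The fit
uses closed-form weighted normal equations; SEs are scaled by
$\sqrt{\max(1, Q_E/(J-2))}$ and p-values use $t_{J-2}$. IVW p-values are
normal while Egger's are $t$: with an estimated intercept and typically few
instruments, the extra-parameter penalty matters, whereas IVW's single
parameter under many instruments does not. When the data carry no intercept,
Egger and IVW coincide — this equivalence is asserted to $10^{-10}$ in the
tests on exact through-origin designs.

**Finite-sample behaviour worth knowing:** the exposure-side sampling noise
$se(\hat\beta_{Xj})$ attenuates the weighted slope by
$S_{\gamma\gamma} / (S_{\gamma\gamma} + \overline{se_X^2})$ (regression
dilution), and since the weighted fit satisfies
$\hat\theta_0 = \bar y_w - \hat\theta_1 \bar x_w$ exactly, the complement
$(\theta - E[\hat\theta_1])\,\bar\gamma_w$ leaks into the intercept. At the
default simulation conditions this is a $\sim$2% effect on the intercept;
the acceptance test compares the intercept against this theory-derived
finite-sample expectation rather than against the pleiotropy mean alone,
which it equals only in the no-measurement-error (NOME) limit.

### Median and mode estimators

`mr_median()` takes the (weighted) median of the Wald ratios: the cumulative
normalized inverse-variance weights of the sorted ratios are interpolated
linearly at 0.5; with equal weights this reduces exactly to the sample
median. It is consistent when at least half the instrument *weight* is
valid. `mr_mode()` smooths the ratio distribution with a Gaussian kernel —
bandwidth $\phi \times 0.9\,\min(sd, mad)\,J^{-1/5}$ (the MAD-based modified
Silverman rule; if the MAD degenerates to zero the SD is used, and if all
ratios are identical that value is returned exactly) — and takes the argmax
over a 512-point grid spanning the ratios $\pm 3$ bandwidths, with argmax
ties broken toward the median ratio. Under the zero-modal-pleiotropy
assumption (the largest cluster of ratios is the valid one) it tolerates a
majority of invalid instruments. The mode is computed as this
density-argmax; an alternative reading of "cluster then meta-analyze within
the modal cluster" exists in the literature and was considered but not
implemented, as the density construction is the standard concrete form.
Both estimators get SEs from a seeded parametric bootstrap (default
`n_boot = 1000`): $\beta_{Xj}^*, \beta_{Yj}^*$ are redrawn from
$N(\hat\beta, se^2)$ and the estimator recomputed, with weights recomputed
from the resampled $\beta_{Xj}^*$. The data are put into canonical
orientation ($\beta_{Xj} > 0$) before bootstrapping so the reported SE is
bit-reproducible and invariant to the arbitrary allele orientation of the
input, not just invariant in distribution.

## 2. Harmonization

`harmonize_studies()` aligns the two studies SNP by SNP:

1. SNPs absent from the outcome are dropped with reason
   `missing_in_outcome`. Proxy-SNP substitution through reference panels is
   intentionally out of scope — a drop-with-reason policy keeps the audit
   trail complete and removes a dependency on external LD panels.
2. Palindromic SNPs (A/T or C/G) are always dropped, never rescued by
   allele-frequency inference; frequency-based rescue trades an unresolvable
   strand for a dependency on allele-frequency quality, and the conservative
   policy costs only a fraction of instruments.
3. Outcome alleles matching in order are kept; reversed alleles negate
   $\beta_Y$ and reflect the allele frequency; otherwise a strand-complement
   (A↔T, C↔G) rescue is attempted before declaring `allele_mismatch`.
4. Survivors are greedily LD-clumped on exposure p-values (ties broken by
   position then rsid, making output deterministic): a SNP is kept iff its
   $r^2$ with every already-kept SNP within the window on the same
   chromosome is `< r2_threshold` (default 0.001).

Every input rsid lands exactly once in the kept set or the audit (tested as
a conservation invariant), harmonization is idempotent, and the output is
invariant to the allele orientation of the input records.

The clump window default is 10,000 **bp**. Production clumping pipelines
conventionally use a 10,000 **kb** window; the parameter is exposed
(`window_bp = 1e7` reproduces the conventional behaviour) and the default is
kept at the conservative printed value rather than silently substituting
intent. LD is taken as an input $r^2$ matrix (TSV or simulated); no
reference panel ships with the package.

## 3. Sensitivity diagnostics

* **Cochran's Q** (`cochran_q()`, `mr_heterogeneity()`):
  $Q = \sum_j w'_j (\hat\theta_j - \hat\theta)^2$ with ratio-scale weights
  $w'_j = \beta_{Xj}^2/se(\hat\beta_{Yj})^2$, $\chi^2_{J-1}$ in the IVW
  context and $\chi^2_{J-2}$ for the Egger residual Q.
* **Leave-one-out** (`leave_one_out()`): $J$ random-effects IVW re-fits. A
  left-out SNP is flagged when the estimate moves by more than one
  *reduced-set* SE. The reduced-set SE (not the full-set one) is the
  reference because an influential outlier inflates the full-set
  random-effects SE through Q and would thereby mask exactly the SNP the
  diagnostic exists to find.
* **Steiger directionality** (`steiger_direction()`): per-SNP variance
  explained $r^2_j = Z_j^2/(Z_j^2 + n - 2)$, $Z_j = \beta/se$, summed per
  study and capped at 1 with a warning (only degenerate simulated inputs
  reach the cap). The Z-based form is the default so the test works without
  allele frequencies; an eaf-based $2\,maf(1-maf)\beta^2$ form is available
  via `use_eaf = TRUE`. The two study-level correlations come from disjoint
  cohorts, so the comparison uses independent-sample Fisher transforms:
  $z = (\mathrm{atanh}\,r_X - \mathrm{atanh}\,r_Y)/\sqrt{1/(n_X-3) + 1/(n_Y-3)}$.
  Direction is assigned by the sign of $z$ only when $p < \alpha$, else
  `indeterminate`. Steiger is reported post hoc, not applied as an
  instrument pre-filter; a filtering mode can be composed manually by
  subsetting on the per-SNP $r^2$ if desired.

## 4. Screening and FDR

`screen_and_analyze()` runs each candidate pair through harmonization and
the primary estimator (random-effects IVW), retains pairs passing the screen
threshold (genome-wide 5e-8 by convention; set `screen_p = 1` to retain
all), and applies Benjamini–Hochberg FDR (`bh_fdr()`, delegating to
`stats::p.adjust`) across the retained pairs' primary p-values **only** —
the robust estimators are reported unadjusted, as per-study sensitivity
narratives. Significance is `q < 0.05`. Primary p-values that underflow to
exactly zero are clamped to the smallest positive double before adjustment
(BH is defined on (0, 1]). Retained pairs are processed in a deterministic
id-sorted order, so results are invariant to candidate input order, and
manual curation is an explicit include/exclude list in the config rather
than anything automated. Pairs failing harmonization are reported in
`$failed`, never silently dropped.

## 5. Causal-web classification

For a significant pair (E, O) and any third trait C, using only database
edges with $p < 10^{-5}$ (strict, fixed-effects IVW convention):

| motif | role |
|---|---|
| C→E and C→O | confounder |
| E→C and C→O | intermediate |
| C→E and O→C | reverse intermediate |
| E→C and O→C | collider |

The reverse-intermediate pattern is the remaining directed two-edge motif
and is documented as an interpretation of that database category. A trait
may satisfy several motifs through distinct edge pairs; *all* matches are
reported, unranked. When several parallel edges connect the same ordered
trait pair, the minimum-p edge supports the motif. Classification is tested
for exact agreement with an exhaustive enumeration oracle on graphs up to 30
nodes, for monotonicity in the threshold, and for permutation equivariance
under trait relabeling. `write_web_graph()` exports GraphML, a
Cytoscape-importable edge table, or JSON, with node roles
(exposure/outcome/third) and edge roles (causal/…_link) as attributes; no
layout is computed.

## 6. The synthetic-data generator

`simulate_two_sample()` inverts the estimation model: instrument strengths
$\gamma_j$ are drawn from a configurable distribution (default
$U(0.05, 0.15)$ — strong instruments, $Z_X \approx 7$–22 at the default
$n = 50{,}000$, matching the genome-wide-significant instruments a real
analysis would select); pleiotropy $\alpha_j$ is none, balanced
(zero-centred) or directional, optionally on only a fraction of SNPs
(`frac_pleiotropic`, modelling partly-invalid instrument sets); the true
outcome effect is $\Gamma_j = \theta\gamma_j + \alpha_j$; observed effects
add Gaussian noise with the additive-genetics standard error
$1/\sqrt{2\,maf(1-maf)\,n}$ (the generating GWAS model is never stated in
the sources this field draws on; this standard approximation lets $n$ and
$maf$ control the noise). InSIDE holds by default; `inside_violation`
correlates $\alpha$ with $\gamma$ for demonstrating Egger failure modes.
Allele-level corruption: a fraction of SNPs get palindromic allele pairs
(relabeling only — they are unrecoverable by design and must be dropped),
and a fraction of non-palindromic outcome records are strand-flipped with
$\beta$ negated jointly, so a correct harmonizer restores the pre-corruption
values *bit-exactly* — which the tests assert. A `flip_exposure_coding` flag
emulates exposure GWAS coded in the opposite trait direction (e.g.
morningness- vs eveningness-coded chronotype), since the appropriate coding
cannot be guessed from summary statistics. One `set.seed()` per call; a
fixed seed fixes every emitted byte.

`simulate_ld_block()` builds block-diagonal LD ($r^2$ = `block_corr` within
blocks, 0 between; noise correlated via the Cholesky factor of the
compound-symmetry correlation matrix, positive semi-definite by
construction, with block members ~100 bp apart and blocks megabases apart).
`simulate_trait_network()` emits MR edge lists with planted roles; planted
edges beat the significance threshold by at least an order of magnitude,
null traits receive only edges with $p \ge 10^{-2}$. The acyclicity check
applies to user-supplied extra edges; role motifs are exempt because the
reverse-intermediate motif (C→E with O→C) is inherently cyclic through the
causal edge — real trait databases do report such bi-directional structures.

**What the generator does not emulate:** individual-level genotypes,
genome-wide realistic LD, case/control liability-scale effects, sample
overlap between the two studies, winner's-curse selection of instruments,
and population stratification. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generative model,
not robustness to those real-data pathologies.

## 7. Validation scenarios and problem sizes

The acceptance layer (test suite and `scripts/acceptance.R`) uses these
scenarios, chosen once as the package's study conditions:

* **IVW recovery/coverage:** $J = 100$, $\theta = 0.2$, $n = 50{,}000$, 500
  replicates; bias and 95%-CI coverage of the random-effects interval.
* **Egger:** same sizes with directional pleiotropy
  $\alpha \sim N(0.05, 0.02^2)$ on all SNPs, InSIDE holding; slope recovery,
  attenuation-corrected intercept recovery (§1), and the IVW bias for
  contrast.
* **Weighted median:** $J = 50$, 40% of SNPs carrying
  $\alpha \sim N(0.1, 0.02^2)$, $n = 500{,}000$. The larger $n$ is
  deliberate: the median's contamination robustness is an asymptotic
  property of well-measured ratios. With one-sided contamination occupying
  40% of weight, the 0.5 weight quantile sits at the $0.5/0.6 = 0.83$
  quantile of the valid-ratio distribution, i.e. an irreducible shift of
  $\approx 0.97\,\sigma_{ratio}$ where
  $\sigma_{ratio} \approx se_Y/\gamma$ — about 0.07 at $n = 50{,}000$ and
  0.02 at $n = 500{,}000$. The scenario is set in the regime where the
  estimator's designed property (robustness, not the quantile shift)
  dominates what is measured.
* **Mode:** 60 SNPs as three concatenated simulator runs — 33 valid, an
  invalid cluster of 14 at $\alpha \approx +0.08$ and one of 13 at
  $\alpha \approx -0.06$ (55% valid weight; the config models one pleiotropy
  component, so multi-cluster sets are built by concatenation).
* **Cochran Q calibration:** 2000 homogeneous-null replicates at $J = 30$
  (exposure effects effectively noise-free so Q is exactly
  $\chi^2_{J-1}$-distributed); the rejection rate at $\alpha = 0.05$ is
  checked against its binomial 95% interval.
* **FDR:** 100 batches of 5 causal ($\theta = 0.3$) + 15 null pairs at
  $J = 30$, $n = 10^5$; the realized false-discovery proportion among
  flagged studies is compared to 0.05 with binomial slack (BH with 75%
  nulls targets $0.05 \times 15/20 = 0.0375$).
* **Clumping / causal web / Steiger:** 200 random 20-SNP LD instances
  against a brute-force oracle; 100 planted networks recovered exactly and
  checked against exhaustive enumeration; 200 directional replicates.

Each scenario's replicate count keeps its Monte-Carlo error well inside the
asserted tolerance. Bootstrap SEs use small `n_boot` inside these recovery
loops (the bootstrap affects only the SE, not the point estimates being
averaged); user-facing defaults stay at `n_boot = 1000`.

## 8. Repository shape and limitations

The package's computations all live in `R/` and are exercised by the test
suite; `analysis/` presents the same machinery as a numbered, narrative
workflow (simulate → screen/FDR → estimator battery → sensitivity → causal
web) writing tables under `results/`, which together with the exported
functions constitutes the interface — there is no separate shell tool.

Known limitations: no multivariable MR, no MR-PRESSO outlier correction, no
correlated-instrument (generalized) IVW, no proxy-SNP lookup, no network
clients for the public MR databases (inputs are files or simulations), and
odds ratios must be supplied as log(OR) (`log_or = TRUE` at read time).
Wald-ratio SEs are first-order by default. The mode estimator's bandwidth
multiplier `phi` defaults to 1 and, as in all kernel-mode methods, very
small valid clusters at extreme bandwidths can mislead it — the ZEMPA
assumption is untestable from data.
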