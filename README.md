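# mrweb

Two-sample Mendelian randomization (MR) with causal-web confounder
classification.

`mrweb` is for epidemiologists and statistical geneticists who want to (i)
estimate the causal effect of an exposure on an outcome from two independent
GWAS summary-statistics studies, (ii) screen many exposure/outcome pairs at
once under false-discovery-rate control, and (iii) map how *third* traits —
confounders, intermediates (mediators), reverse intermediates and colliders —
relate to each significant pair on a weighted directed graph. Because the
public MR databases the method is normally pointed at (MR-Base-style GWAS
accessions, precomputed MR edge lists) require network access, the package
ships a ground-truth simulator so every stage runs, and is validated, on
synthetic data.

## The model

Each genetic variant *j* is an instrumental variable with effect
β<sub>Xj</sub> on the exposure and β<sub>Yj</sub> on the outcome. The per-SNP
**Wald ratio** estimates the causal effect θ:

θ̂<sub>j</sub> = β<sub>Yj</sub> / β<sub>Xj</sub>

Multi-SNP estimators combine the instruments under different validity
assumptions:

| estimator | estimate | valid when |
|---|---|---|
| IVW (fixed/random) | θ̂ = Σw<sub>j</sub>β<sub>Xj</sub>β<sub>Yj</sub> / Σw<sub>j</sub>β<sub>Xj</sub>², w<sub>j</sub> = 1/se(β̂<sub>Yj</sub>)² | all instruments valid (random-effects SE inflates by √max(1, Q/(J−1))) |
| MR-Egger | weighted regression β̂<sub>Yj</sub> = θ₀ + θ₁β̂<sub>Xj</sub>; slope θ₁ is causal, intercept θ₀ is mean directional pleiotropy | InSIDE: pleiotropy independent of instrument strength |
| weighted median | weighted median of the θ̂<sub>j</sub> | ≥ 50% of instrument weight valid |
| mode (simple/weighted) | mode of the kernel-smoothed θ̂<sub>j</sub> density | largest ratio cluster valid (ZEMPA) |

Sensitivity diagnostics: Cochran's Q heterogeneity (IVW and Egger contexts),
leave-one-out IVW, and the Steiger directionality test (do the instruments
explain more variance in the exposure than the outcome?). Across studies,
the primary random-effects IVW p-values are Benjamini–Hochberg adjusted and
pairs with q < 0.05 are flagged. For each significant pair (E, O), any third
trait C with database edges at p < 1e-5 is classified by the directed
two-edge motif it forms: C→E & C→O confounder, E→C & C→O intermediate,
C→E & O→C reverse intermediate, E→C & O→C collider.

Before any estimation, exposure and outcome records are harmonized: alleles
aligned to a common effect allele (with strand-complement rescue),
palindromic (A/T, C/G) SNPs discarded, absent SNPs dropped with reason, and
instruments LD-clumped greedily (keep the best p-value, drop anything with
r² ≥ 0.001 inside the window).

## Worked example

```r
library(mrweb)

# two-sample studies with a true causal effect of 0.2, 30% of outcome
# records strand-flipped and 20% of SNPs palindromic
s <- simulate_two_sample(sim_config(
  n_snps = 100, theta = 0.2, frac_flipped = 0.3, frac_palindromic = 0.2,
  seed = 5
))
h <- harmonize_studies(s$exposure, s$outcome)
h
#> harmonized_set: 80 instruments kept, 20 dropped
#>
#> palindromic
#>          20

mr_ivw(h)
#> ivw_re: theta = 0.1994 (SE 0.007436, p = 1.99e-158), J = 80

mr_egger(h)
#> egger: theta = 0.1635 (SE 0.02662, p = 3.16e-08), J = 80
#>   intercept = 0.00398 (SE 0.002835, p = 0.164)

steiger_direction(h)$direction
#> [1] "exposure_to_outcome"
```

The 20 palindromic SNPs are discarded (their strand is unresolvable), the 30
strand-flipped outcome records are restored exactly, IVW recovers the true
θ = 0.2 within one standard error, the Egger intercept is consistent with
zero (no directional pleiotropy was simulated, p = 0.16), and Steiger
confirms the instruments act through the exposure.

The `analysis/` directory holds the same machinery as a narrative workflow:
`01_simulate_studies.R` (a 20-pair study battery, 5 causal),
`02_screen_fdr.R` (harmonize + IVW screen + BH-FDR; writes the forest
table), `03_estimator_battery.R` (all seven estimator variants on one pair),
`04_sensitivity.R` (Q, leave-one-out, Steiger) and `05_causal_web.R`
(role classification; writes GraphML and a Cytoscape-ready edge table under
`results/`). Run them in order with `Rscript`.

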