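---
title: "Methods: the asymmetric lung injury analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the asymmetric lung injury analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymali)
```

This vignette is the package's account of the science it implements: the
models and scoring systems, the parameters that matter and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and the numerical and design choices made where the
published descriptions leave room.

## The experimental design being analysed

A porcine model of asymmetric acute lung injury: one lung (the left, by
lateral positioning during lavage) is surfactant-depleted, and animals are
ventilated for six hours under one of three arms — fixed PEEP 5 cmH2O with
injury (`ALI_PEEP5`), PEEP titrated hourly to a slightly positive
end-expiratory transpulmonary pressure (`ALI_TPP`), and a small sham arm
(`SHAM_PEEP5`). Outcomes are read at four levels: ventilator mechanics,
histology, computed tomography, and plasma antibody microarrays. The
package implements the computation at each level plus the statistical
battery connecting them.

## Derived mechanics and the titration rule

All pressures are static hold-maneuver values in cmH2O. The derived
quantities are algebraic identities — driving pressure
$\Delta P = P_{plat} - PEEP$, transpulmonary pressures
$TPP_{exp} = PEEP - P_{ES,exp}$ and $TPP_{insp} = P_{plat} - P_{ES,insp}$,
their difference $\Delta P_L$ — plus mechanical power

$$MP = 0.098 \cdot RR \cdot V_T \cdot \left(P_{peak} - \tfrac{1}{2}(P_{plat} - PEEP)\right) \; \mathrm{J/min},$$

with $V_T$ converted from mL to litres only inside this formula (0.098 J
per L·cmH2O). A quasi-static compliance estimate $V_T/\Delta P$ is computed
and explicitly labelled `crs_quasistatic`; ventilator-reported compliance,
when present, is carried as a pass-through column and never conflated with
it — the two can differ materially because the device estimates compliance
from its own breath model. Resistance has no computable definition without
a flow signal and is pass-through only. When $\Delta P = 0$ the compliance
estimate is undefined (`NA`); the other outputs are still returned.

**Titration.** The published protocol states only the target band
(TPP$_{exp}$ between 0 and 3 cmH2O, adjusted hourly). Whether PEEP was
moved incrementally or set directly is not described; we chose a **one-shot
set rule**: if the current TPP$_{exp}$ is in band, do nothing, else set
PEEP to $P_{ES,exp}$ plus the band midpoint, rounded to the ventilator step
(1 cmH2O, ties away from zero) and clamped to [4, 24] cmH2O. This is the
simplest policy that reproduces the observed endpoint (PEEP near 10–11 for
an expiratory esophageal pressure near 9.5) and, under any linear
chest-wall response with slope below 1, is a contraction: the acceptance
suite verifies convergence into the band within 10 steps over a 10 × 10
grid of slopes (0–0.8) and intercepts (0.5–6 cmH2O), with widened PEEP
bounds in that test so the fixed point is interior. All band, bound and
step parameters are configurable through `titration_policy()`.

## Modified lung injury score

Twenty random high-power fields per tissue sample are scored on three
components, each 0–2 points: alveolar neutrophils (none/1–5/>5),
interstitial neutrophils (same bins), and septal thickening (<2×, 2–4×,
>4×). The weighted sum $20A + 14B + 2C$ is normalized per field. The
published description contains an internal conflict: the printed formula
divides by $n_{fields} \times 72$ (which would give a 0–1 range) while the
stated range is 0–0.72. We default to the **per-field-100** denominator —
the original five-component score normalizes by 100 points per field, and
dropping the two 7-weighted components (hyaline membranes, proteinaceous
debris, absent in the early exudative phase) while keeping that
normalization yields exactly the stated 0–0.72 range. The literal ×72 mode
is selectable (`denominator = "per_field_72"`).

Boundary inclusivity is declared, not inferred: a count of exactly 5 scores
1 point; a fold of exactly 2 or exactly 4 scores 1 point (bins read as
[2, 4]). Three site samples per lung side are averaged to one value per
animal-side before pairing — the mean rule mirrors the averaging convention
the CT scoring states explicitly, and keeps one value per animal-side for
the paired Wilcoxon comparison.

## Modified Ichikado HRCT score

Readers grade each lung region's area into four patterns; the original
system's two traction-bronchiectasis grades are merged into a single
"bronchodilatation" grade and honeycombing is excluded (not expected six
hours into injury). The published account names the grade merge but not
numeric weights; we retain the ordinal weights 1 (normal), 2 (ground
glass), 3 (consolidation) and assign 4 to the merged grade, all
configurable. The region score is the extent-weighted sum
$\sum_g w_g \cdot \mathrm{extent}_g(\%)$ — the operational reading that
makes side scores of magnitude 100–400 arithmetically possible, matching
the reported range. Extents must sum to 100 ± 0.5%; the tolerance is a
parameter. Regions (default 3 per side in the generator; the true partition
is not described) average to one score per side and hold, and
recruitability is the expiratory-minus-inspiratory score difference —
positive when the inspiratory hold aerates (de-scores) recruitable regions.

## Antibody-array processing

The arrays follow a reference-based dual-colour design: every sample is
hybridized against a common pooled reference, each antibody printed in
quadruplicate. Processing:

1. **Aggregation**: optional local-background subtraction, floor at
   $\epsilon = 1$ intensity unit (so log2 stays finite), median across
   replicate spots; the replicate CV is reported.
2. **MA transform**: $M = \log_2(S/R)$, $A = \tfrac{1}{2}\log_2(S \cdot R)$.
3. **Rank-invariant lowess normalization**: per array, antibodies whose
   channel ranks differ by at most 5% of the panel are taken as the
   invariant (non-regulated) set; a lowess curve (span 0.4) of M on A over
   that set estimates the intensity-dependent dye bias, which is subtracted
   from all M values. Two numerical refinements matter in practice: (a) a
   refinement pass drops invariant-set members whose residual around the
   first fit exceeds 5× the median absolute residual — rank-near-invariant
   antibodies that are actually regulated betray themselves this way — and
   refits; (b) outside the invariant set's A-range the trend is extended
   linearly with the end-segment slopes rather than held constant, so
   extreme-intensity antibodies are not left with edge bias. If fewer than
   10 antibodies survive selection the array falls back to global-median
   centering with a warning. The vendor's "specialized invariant Lowess" is
   proprietary; this reconstruction is a declared approximation.
4. **Moderated contrasts**: per antibody, an OLS cell-means model over
   condition labels; empirical-Bayes variance moderation
   $s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with $(d_0, s_0^2)$
   estimated by the method of moments on $\log s^2$ (the standard
   scaled-inverse-chi-square construction; antibodies with zero variance
   are excluded from the hyperparameter fit). The moderated t is referred
   to $d_0 + d$ degrees of freedom. A non-finite moments estimate is
   treated as an infinite, fully pooled prior; `d0 = 0` disables moderation
   and reproduces the ordinary per-antibody t exactly. The test suite
   cross-checks statistics against the established `limma` implementation.
5. **Multiplicity and classification**: Benjamini–Hochberg step-up control;
   default thresholds call an antibody *differential* at |logFC| > 0.5 and
   adjusted p < 0.05, and *noteworthy* at |logFC| > 0.5 with adjusted p in
   [0.05, 0.9). The published Methods section states a stricter variant
   (adjusted p < 0.005; noteworthy as 0.25 < |logFC| ≤ 0.5) that conflicts
   with the Results and figure captions; defaults follow the
   Results/captions reading and the Methods variant ships as the
   `"methods"` preset of `classification_thresholds()`. All four numbers
   are configurable.
6. **Clustering order**: differential antibodies are z-scored per antibody
   (zero-variance rows become all-zero with a warning) and ordered by
   average-linkage hierarchical clustering on Euclidean distances, rows and
   columns, for heatmap rendering.

Contrasts implemented by the orchestrator mirror the study's two questions:
each group's t6 samples against the pooled baselines, and group against
group at t6; the contrast specification itself is free-form.

## The comparison battery

Group sizes of 2–6 make asymptotic p values untrustworthy, so the rank
tests are exact by default:

- **One-way ANOVA** (classical F) with Bonferroni post hoc pairwise
  pooled-variance t tests — each raw pairwise p multiplied by the number of
  pairs performed, capped at 1. Constant data (zero between- and
  within-group variance) is defined as F = 0, p = 1.
- **Mann–Whitney U**: mid-ranks for ties; tie-free data up to combined
  n = 25 uses the exact null distribution of U; the two-sided p is twice
  the smaller tail, capped at 1. Ties switch to a seeded Monte-Carlo
  permutation (10⁴ reassignments); larger tie-free samples use the normal
  approximation with continuity and tie correction.
- **Wilcoxon signed-rank**: the classic zero-drop convention (zeros removed
  and noted — the most common default), mid-ranks on absolute differences,
  and an exact null distribution computed by generating-function
  convolution over doubled mid-ranks for up to 20 nonzero pairs. The
  convolution handles mid-rank ties exactly, which the standard tie-free
  distribution function cannot; the suite checks it against both
  `psignrank` and full $2^m$ enumeration.

The published analysis maps ANOVA to mechanics and histology group effects,
Wilcoxon to paired side and hold comparisons, and Mann–Whitney to HRCT
group contrasts; the orchestrator follows that mapping. Normality claimed
in the source is not re-adjudicated — both parametric and rank tests are
exposed.

## The synthetic-cohort generator

The generator replaces the animal data with virtual cohorts whose group
summaries are calibrated, in expectation, to the published t6 group means;
per-animal raw values were never published, so calibration matches moments,
not individuals. Defaults (all overridable through `cohort_config()`):

- **Cohort**: 6 + 6 + 2 animals (the 17 enrolled minus 3
  pneumothorax-style exclusions; an optional dropout flag emulates the
  exclusions, default off), body weight 50 ± 6 kg, tidal volume 6 mL/kg.
- **Mechanics**: single-compartment model
  $P_{plat} = PEEP + V_T / C_{rs}$, $P_{peak} = P_{plat} + R_{term}$, with
  healthy compliance 37.5 mL/cmH2O, injured compliance 25 (fixed arm ΔP
  then lands near the published 12.3 cmH2O), and a recruitment gain of
  1.7 mL/cmH2O per cmH2O of PEEP above 5 in the injured arms — chosen so
  the titrated arm's compliance reaches ≈ 33 mL/cmH2O and its ΔP ≈ 9 at
  the titration fixed point. The chest wall responds linearly,
  $P_{ES,exp} = 4.7 + 0.45 \cdot PEEP$ in the injured arms (sham intercept
  1.05): one line cannot reproduce both published (PEEP, $P_{ES,exp}$)
  pairs exactly — they imply slope ≈ 0.34 through different intercepts —
  so the chosen line passes within roughly one published SEM of both, and
  the hand-iterable noiseless titration fixed point is PEEP = 10 with
  TPP$_{exp}$ = 0.8 in band. Gaussian noise, sd 1.5 cmH2O on airway
  pressures and 1.0 on esophageal pressures, matches the published SEMs at
  n = 6. The inspiratory esophageal swing is $V_T$ over a chest-wall
  compliance of 55 mL/cmH2O.
- **Histology**: Poisson neutrophil counts and log-normal thickening folds
  per side and group. Injured-left rates (alveolar mean 7, interstitial 5,
  fold lognormal(log 3, 0.5)) give a closed-form expected score — exposed
  as `expected_modified_lis()` and used as the analytic test oracle — of
  ≈ 0.55; non-injured and sham rates give ≈ 0.27–0.30.
- **HRCT**: per-region extents drawn as Dirichlet × 100, with
  concentration presets whose closed-form expectations
  (`expected_hrct_score()`) sit at the published side means — ≈ 260 for
  injured-left, ≈ 115–145 for the right side with the fixed arm above the
  titrated arm, and ≈ 110–115 for sham.
- **Array**: log-normal baseline abundances (log2 mean 10, sd 2) shared
  with the pooled reference; a flagged 5% of antibodies carries a planted
  group-by-timepoint effect (default +2 log2 units in the titrated arm at
  t6 — the effect size used throughout the recovery properties), a smooth
  dye bias $0.3 + 0.1 A$ on the sample channel, biological residual sd
  0.5, spot-level sd 0.1 across 4 replicates. The ground-truth table (flag,
  effect, true bias) is emitted alongside.

Distribution families (Poisson, Dirichlet, log-normal, Gaussian) are
modelling choices, not published facts. The generator is fully
deterministic given config and seed (one RNG stream for the whole bundle).

**What passing tests do and do not show.** The generator emulates group
structure, side asymmetry, intensity-dependent dye bias, and replicate
noise. It does not emulate waveform dynamics, gas exchange, hemodynamics,
reader disagreement, spatial correlation between fields or regions, or
heavy-tailed array artefacts. Pipeline properties verified on it (score
calibration, effect recovery, test exactness) are therefore statements
about the methods, not about any real cohort; the published real-data
outcomes (e.g. the count of differential proteins) depend on unpublished
per-animal data and a proprietary vendor pipeline and are deliberately not
reproduction targets.

## Numerical choices and degenerate inputs

- Rounding of PEEP settings: ties away from zero (`round()` would go to
  even, which is wrong for a ventilator knob).
- Two-sided exact p values: twice the smaller tail, capped at 1.
- BH adjustment: the step-up definition; note it is *not* idempotent as a
  map (re-adjusting adjusted values re-inflates them by design); the
  idempotent component is the from-the-top cumulative-minimum enforcement,
  and tied inputs are fixed points. The suite asserts those properties.
- Signed-rank exactness uses doubled mid-ranks so the convolution runs on
  integers; zero differences error out only when nothing remains.
- Extent sums are validated to 100 ± 0.5%; Dirichlet concentrations must be
  strictly positive.
- The normalization's invariant-set refinement threshold (5 × MAD) and the
  linear end-segment extrapolation are described above; with heavy
  biological noise (residual sd 0.5) individual antibodies near the
  intensity extremes can still retain trend error of ~0.2 log2 units —
  an intrinsic limitation of rank-invariant selection, which the
  statistical calibration and recovery properties absorb.
- Problem sizes in the test suite (1000-antibody null panels and
  300-antibody effect panels over 20 seeds; 2000-replicate type-I-error
  sweeps; 10⁴-field and 10⁴-region oracle checks) were chosen so the
  Monte-Carlo error of each asserted quantity is several times smaller
  than its tolerance.

## Known limitations

- The titration one-shot rule is a declared reconstruction; incremental
  in-study adjustment would converge to the same band but along a
  different trace.
- HRCT weights and the region partition are configurable reconstructions;
  only the grade ordering is published.
- The histology side means use the mean-of-samples rule; the published
  aggregation is unstated.
- The exact tests' tie and zero conventions are declared defaults, not
  inferred from the source.
- The array normalization approximates a proprietary vendor method; its
  per-antibody guarantees degrade under heavy biological noise as noted
  above.
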