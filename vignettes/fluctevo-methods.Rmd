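---
title: "Models and methods behind fluctevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluctevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctevo)
```

fluctevo implements the analysis pipeline of a batch-culture laboratory
evolution design in which *Escherichia coli* populations are serially
passaged while the incubation temperature alternates between two extreme but
survivable values, 15 and 43 °C. Two periodic regimes switch temperature at
culture-density thresholds (slow: one switch per transfer cycle at
OD~830~ 0.25; fast: three switches at 0.15/0.30/0.45), and a random control
regime switches on uniformly drawn timers, 3–5 h at 43 °C and 5–15 h at
15 °C, chosen so comparable generation numbers accrue at the slow-growing
cold temperature. The pipeline covers four analyses: estimating growth-rate
changes and classifying strains as generalists or specialists; gene-level
mutation parallelism and enrichment; and the classification of phenotype-
microarray responses as restorative toward the unstressed 37 °C state. A
synthetic-data generator with known ground truth backs every stage, so
estimator accuracy, test calibration and classifier recovery are all
verifiable properties rather than assumptions.

## Culture simulator

Within a temperature segment, growth follows the modified Gompertz law in
log OD (Zwietering parameterization),

$$\log \mathrm{OD}(t) = \log \mathrm{OD}_0 +
  A \exp\!\left[-\exp\!\left(\frac{\mu e}{A}(\lambda - t) + 1\right)\right],$$

with $A = \log(K/\mathrm{OD}_0)$ the remaining log-growth toward the
carrying capacity $K$, $\mu$ the maximum slope of log OD (the maximum
specific growth rate, min^-1^) and $\lambda$ the lag time (min). Writing the
law this way makes $\mu$ exactly the quantity the growth module estimates.
At a temperature switch the curve is re-anchored: growth continues from the
current density with the new temperature's $\mu$ and $K$ and a configurable
secondary lag, zero by default because post-shift lag behaviour is not
resolvable at the instrument's 4-minute sampling. Temperature transitions
are treated as instantaneous: the physical transition takes under 35 min,
less than one generation, so its growth effect is neglected.

Switch and transfer events are located exactly by inverting the Gompertz
curve in closed form, so density-triggered switches occur at precisely the
configured thresholds while sampling stays on the fixed 4-minute grid.
"Just before stationary phase" is operationalized as the noiseless OD
reaching 95 % of the active temperature's capacity; in the periodic regimes
this trigger is armed only after the full switch schedule has run, while in
the random regime it ends the cycle whenever it fires (the drawn segment
schedule is abandoned at saturation). Each transfer dilutes 100 µL into
20 mL of fresh medium, a factor of 201, and the next cycle starts at the
temperature the previous one ended at — the start-temperature alternation
of the experimental design. Measurement noise is additive Gaussian on OD
(default SD 0.002), truncated at a floor of 10^-4^ to keep readings
positive.

Generations are counted two ways, because neither is canonical: per-segment
doublings $g = \log_2(\mathrm{OD}_{end}/\mathrm{OD}_{start})$ from the
noiseless boundaries (additive over segments and attributable to a
temperature), and the dilution-based $\log_2 201 \approx 7.65$ per completed
cycle. `ledger_totals()` reports both. An optional carryover term rescales
$\mu$ at one temperature conditional on the previous segment's temperature,
reproducing the "internalized fluctuation" phenotype in which growth at
15 °C depends on prior exposure to 43 °C.

Default strain parameters are realistic for these strains in M9 glucose:
$\mu$ = 0.012 min^-1^ at 37 °C, 0.010 at 43 °C and 0.0014–0.0016 at 15 °C
(the 606 founder slightly faster in the cold), capacity 0.55 so the slow
regime's 0.25 threshold sits near half of it, and lags of 120–400 min.

## Growth-rate estimation

`estimate_growth_rate()` fits a cubic smoothing spline to log OD versus time
and returns the maximum of its first derivative. Three pre-processing steps
make this reliable across the pipeline's full signal-to-noise range:

* **Quantification floor.** Additive OD noise makes log OD meaningless near
  the detection limit. A first-stage spline on *raw* OD provides a fitted
  trend; samples whose trend falls below the larger of `min_od` (default
  0.005) and five times the estimated instrument noise (robust SD of first
  differences) are dropped. Thresholding the trend rather than the noisy
  readings avoids the selection bias of keeping only upward noise
  excursions.
* **Precision weights.** log OD is heteroscedastic under additive noise; by
  the delta method its precision is proportional to OD², so the second-stage
  spline is weighted by the squared fitted trend.
* **Saturation trim.** Samples beyond 95 % of the observed log-OD range are
  discarded, so a long stationary tail cannot drag the cross-validated
  bandwidth away from the growth peak.

Smoothing is chosen by generalized cross-validation with a floor of 0.3 on
the smoothing parameter (on `smooth.spline`'s normalized scale) so noise is
never interpolated; the value used is recorded in the estimate. The analysis
window is the first 2 500 min of the series. A flat series returns
$\hat\mu = 0$ with a `flat` flag, and a declining series returns its
non-positive maximum slope with a warning rather than an error.

`fit_gompertz()` fits the same Gompertz form by Levenberg–Marquardt
nonlinear least squares (precision-weighted, deterministic initialization:
$\mu$ from the spline, $A$ from the observed log-range, $\lambda$ from the
first doubling). On noiseless curves it recovers the generating parameters
to machine precision. The two estimators serve as mutual cross-checks;
`assay_strategy_analysis()`'s default *consensus* mode uses the spline
estimate unless the parametric fit disagrees by more than 20 %, which flags
the occasional spline failure on very low signal-to-noise curves (15 °C
assays spend most of the window barely above the noise floor).

## Relative growth and strategy classification

For each evolved strain and temperature, the relative growth rate is the
ratio of replicate means, evolved over founder. Significance uses the
pooled-variance two-sample statistic

$$t = \frac{\bar x_1 - \bar x_0}{s_p\sqrt{1/n_1 + 1/n_0}},$$

with $s_p$ estimated from within-strain deviations across *every* replicate
group measured at that temperature and $\mathrm{df} = \sum_i (n_i - 1)$.
Pooling the whole temperature panel stabilizes the variance when groups have
only three replicates; a `pool_scope = "pair"` switch restricts pooling to
the compared pair. Tests are two-sided; direction enters only at
classification: a strain is a **generalist** when the ratio significantly
exceeds 1 at both 15 and 43 °C, a **specialist** at exactly one temperature,
and **not-significant** otherwise. Significant decreases never create or
veto calls. An optional strict mode additionally requires ratios of 1.15
(15 °C) and 1.30 (43 °C), the typical effect sizes such experiments report;
by default the significance rule alone decides, avoiding arbitrary effect
thresholds. Group comparisons use the variance-ratio F-test (two-sided) and
the two-sided Fisher exact test on strategy-by-regime tables.

Under a null with 26 strain groups of 3 replicates per temperature, the
per-temperature rejection rate of this procedure is 0.05 to within Monte
Carlo error, and generalist calls occur at roughly $(\alpha/2)^2$ — both
verified by simulation in the test suite at 10^4^ panels.

## Mutation analysis

Population-sequencing calls below 5 % frequency are removed (the boundary is
kept; clone calls are fixed by definition). Calls are coarse-grained to the
gene level: multi-gene deletions and amplifications count once, attributed
to an explicitly supplied anchor gene — anchors are never inferred
automatically, to avoid silent misattribution — and repeated hits to one
gene in one strain are one incidence but preserved in a parallel count
matrix. Clone and population tables are analyzed separately.

Enrichment between two strain groups uses the pooled two-proportion z-test
for every gene mutated in at least three strains, with Benjamini–Hochberg
false-discovery control across tested genes (the FDR procedure is a
package choice; BH reproduces the characteristic p-to-q inflation at these
test counts). Per-strain counts of a mutation class or functional category
are compared with the Mann–Whitney U test: exact by full enumeration over
group assignments of mid-ranks whenever the combined sample size is at most
20 — so every 12-vs-12 comparison in the experimental design is exact even
with the heavy ties count data produce — and by the tie- and
continuity-corrected normal approximation above that. Per-generation
mutation rates are counts over the generation ledger, compared with a pooled
t-test (Welch behind a flag).

## Phenotype-microarray analysis

GEN III plates hold 70 metabolic wells with a negative control, 22
chemical-sensitivity wells with a positive control, and two tetrazolium dye
wells (86 and 94) that develop color in every sample and are dropped.
Normalization subtracts the negative control from metabolic wells and
subtracts chemical wells from the positive control, leaving 92 features per
plate in a fixed order; both operations are within-plate differences, so
plate-wide offsets cancel. The default layout places the negative control at
well 1 and the positive control at well 72 (1-based row-major numbering);
any layout with the same 70+1+22+1+2 role partition can be supplied.

**Replicate QC.** A reading is flagged as inconsistent when its leave-one-out
deviation, standardized to the noise-SD scale, exceeds 5 times the set's
typical replicate noise (the larger of that well's leave-one-out SD and the
chi-square-debiased median leave-one-out SD across wells). A threshold
stated in per-well SD units alone cannot work here: with $n$ replicates the
deviation-to-SD ratio is bounded by $(n-1)/\sqrt n$, below 1.3 for
triplicates, so no such rule would ever fire. The standardized rule flags a
grossly deviant well immediately while false flags on clean Gaussian
replicates are essentially impossible across a full plate set. Flagged
readings are imputed as the mean of the remaining replicates. With only two
replicates the deviant one is unidentifiable, so automatic flagging refuses
and explicit flags must be supplied.

**Embedding.** Features are column-centered (not scaled — all features share
the OD~590~ scale) and embedded by PCA. With `n_components = "auto"` the
retained count is where the variance proportions stop exceeding the
broken-stick reference $b_k = \frac1p\sum_{i=k}^{p} 1/i$; the talus
heuristic (leading log-eigenvalue gaps standing clear of the flat tail) is
computed as a second opinion, and on disagreement the count falls back to 3,
the dimensionality this assay family typically supports. Founder centroids
per temperature are k-means with $k = 1$ on the retained scores —
analytically the replicate mean — computed per lineage by default, with a
pooled mode for designs whose founders are phenotypically indistinguishable.

**Restoration calls.** For every evolved strain, stress temperature and
retained component, three two-sided pooled-variance t-tests are run on
replicate scores: founder-at-stress vs founder-at-37 °C (ancestral
plasticity, $D_a$), evolved vs founder-at-stress ($D_s$) and evolved vs
founder-at-37 °C ($D_o$). Pooled variance is appropriate because technical
replicates have comparable dispersion across conditions, and it buys power
at 3-vs-6 replicates. Within each strain-temperature, each test family's
p-values are Holm-corrected across the retained components (Bonferroni
behind a flag); correcting within strain-temperature rather than across
strains follows the per-strain decision structure of the classification.
The significance pattern plus the geometry of the evolved mean $E$ relative
to the founder centroids $A_s$ (stress) and $A_o$ (optimum) yields exactly
one of seven categories:

| $D_a$ | $D_s$ | $D_o$ | geometry | category |
|---|---|---|---|---|
| ns | ns | – | – | uninformative |
| ns | sig | – | – | novel |
| sig | ns | – | – | unrestored |
| sig | sig | ns | – | restored |
| sig | sig | sig | $E$ strictly between $A_s$ and $A_o$ | partially restored |
| sig | sig | sig | $E$ past $A_o$, away from $A_s$ | over-restored |
| sig | sig | sig | $E$ past $A_s$, away from $A_o$ | reinforced |

The rule is exhaustive and mutually exclusive over all significance patterns
and positions (verified by enumeration), and equivariant under sign flips of
a component. Restored, partially restored and over-restored collapse to a
single *restorative* group for reporting. A strain-temperature headline call
is the majority collapsed category over informative components, ties broken
toward the less restorative state (unrestored < reinforced < novel <
restorative), a conservative aggregation since no standard exists. Group
comparisons reuse the shared kernels: Fisher exact tests of category
presence between the 15 and 43 °C conditions, and one-sided Mann–Whitney
tests of per-strain category counts between strain groups. Sample
clustering is Ward linkage on Euclidean distances of the centered features,
with Newick export.

## Synthetic-data generators

The generators define the conditions every validation runs under; they are
first-class, tested code.

* **Trajectories** come from the simulator above at the full 2 × 3 × 4
  design.
* **Growth assays** plant multiplicative rate changes per strain and
  temperature — periodic-regime strains mostly gain at both temperatures
  (×1.25 at 15 °C, ×1.35 at 43 °C), random-regime strains at one — with 3 %
  between-replicate scatter, and emit replicate Gompertz curves with
  measurement noise.
* **Mutation tables** draw per-gene Bernoulli hits with group-specific
  probabilities (planted contrasts: a gene at 0.9 in one lineage and 0 in
  the other, regime-linked genes, a 0.15 background), classes from a fixed
  distribution and population frequencies from a right-skewed Beta.
* **Biolog plates** place founder phenotypes at a base vector displaced
  along one orthonormal 92-dimensional axis per stress temperature (12.5 and
  15 noise-SD units at 15 and 43 °C — the hot condition is the more
  perturbed state), and realize each planted category as the corresponding
  mean position on the relevant axis: unrestored at $A_s$, restored at
  $A_o$, partial at the midpoint, over/reinforced at half-separation
  overshoots, and novel as a 6-SD displacement along a third,
  founder-neutral axis. Novel displacements alternate in sign across strains
  so the novel axis stays uncorrelated with the stress axes in the sample
  covariance — otherwise PCA would rotate the axes together. Control and
  dye wells carry one tenth of the assay wells' noise: they hold no growth
  signal, while assay-well variance is dominated by biological variation
  between replicate inoculations; without this the normalization would
  propagate control noise into all 70 (or 22) features of a plate and
  manufacture dominant technical components that are artifacts of the
  synthetic construction, not of the assay.

What the generators deliberately do not emulate: mutation–phenotype
coupling (mutation tables and growth parameters are configured
independently), allele-frequency dynamics within populations, kinetic
(time-course) Biolog curves, plate-position or batch effects, and
non-Gaussian measurement error. Passing tests therefore demonstrate that
the estimators and classifiers recover truth under clean replicate designs
of realistic size and noise — not that they are robust to every artifact of
real plate data.

## Validation problem sizes

The test suite and the acceptance script validate, among others: exact
agreement of the Fisher kernel with hypergeometric enumeration over all 2×2
tables with margins ≤ 8 and of the Mann–Whitney kernel with full permutation
enumeration at combined n ≤ 10; spline recovery of planted µ within 5 %
median relative error over 200 curves spanning µ ∈ [0.001, 0.02] min^-1^
and noise SD ∈ [0, 0.005] (observed ≈ 1 %); machine-precision noiseless
Gompertz round-trips; per-temperature null rejection of 0.05 ± 0.01 over
10^4^ simulated 26-group panels; and ≥ 95 % recovery of planted restoration
categories at effect 5 SD with 6 founder / 3 evolved replicates aggregated
over 200 seeds (observed ≈ 97 %).

## Known limitations

Growth-rate estimation near the detection limit remains the weakest link:
for cultures that spend the whole window barely above the noise floor the
spline occasionally fails badly, which is why the assay-level analysis
defaults to the spline–Gompertz consensus. The generation ledger's OD-based
and dilution-based counts disagree whenever a cycle is transferred before
full regrowth; both are reported rather than reconciled. The restoration
scheme is defined per principal component; the headline aggregation across
components is a package convention. And all calibration claims are
conditional on the synthetic generators' assumptions listed above.
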