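---
title: "Methods: rank-order differential expression for censored Ct arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-order differential expression for censored Ct arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrank)
```

This vignette documents the statistical model behind `ctrank`, the meaning
and defaults of every tuning parameter, what the bundled simulator does and
does not emulate, and the numerical conventions the implementation commits
to. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A low-density TaqMan array reports, for each *detector* (miRNA assay) in
each sample, a cycle threshold Ct: the PCR cycle at which fluorescence
crosses a fixed threshold. Under near-perfect amplification the template
doubles each cycle, so Ct is minus log2 abundance up to a per-sample
constant, and **lower Ct means more abundant**. Two facts dominate the
analysis design:

1. **Censoring.** Reactions that never cross the threshold are reported as
   `Undetermined` or clamped at the instrument limit (default 40 cycles).
   These wells carry only the information "abundance below the detection
   limit". `ct_matrix()` stores an explicit censoring mask; clamped values
   at or above the limit are set to the limit and flagged.
2. **Per-sample offsets.** Loading and RT efficiency shift every Ct of a
   sample by an approximately common constant, which must be removed
   (normalization) or made irrelevant (ranking) before groups are compared.

## Rank-order statistic

`rank_within_samples()` force-ranks detectors within each sample (rank 1 =
lowest Ct = most abundant). All ties — in particular the whole censored
block at the detection limit — receive the mid-rank, i.e. the mean of the
positions they occupy, so each sample's ranks always sum to D(D+1)/2. The
mid-rank choice (rather than, say, the maximum rank) keeps that invariant
and treats censored wells symmetrically; `ties = "max"` is available for
comparison.

Ranking is invariant to any strictly increasing per-sample transform, so
per-sample offsets vanish by construction and no normalizer needs to be
chosen or trusted. The price is a floor/ceiling effect: a detector already
near rank 1 cannot move further up no matter how strongly it is induced.

`rank_diff_test()` compares mean within-sample ranks between two groups
with a two-sided unequal-variance (Welch) t-test, Welch–Satterthwaite
degrees of freedom. The reported effect is

> `rank_diff = mean rank(reference) − mean rank(case)`,

positive when the detector is more abundant (lower rank number) in the case
group. Degenerate inputs follow documented conventions: both groups
constant with equal means gives p = 1; constant but unequal gives p = 0,
with a `degenerate` flag either way. With integer-valued ranks and small
groups, exact group-mean ties (t = 0, p = 1) occur with non-negligible
probability, so the null p-value distribution carries a small atom at 1;
this is a property of the statistic, not an implementation artifact.

`prediction_interval_outliers()` regresses case mean ranks on reference
mean ranks by ordinary least squares and flags detectors strictly outside a
95% band. `band = "pointwise_pi"` is the textbook pointwise prediction
interval, `ŷ ± t·s·sqrt(1 + 1/n + (x0 − x̄)²/Sxx)`; `band = "parallel"`
draws constant-width lines at `± t·s`, a common plotting convention that
under-covers at the extremes. The pointwise band is the default because its
nominal level is exact under the linear-Gaussian model; both are kept
because the parallel variant is what rank–rank scatter plots convention-
ally show.

## Normalization and fold change

- `median_normalize()` subtracts each sample's median Ct. Censored wells
  are excluded from the median by default (their clamped values are floor
  artifacts) but are still shifted so the matrix stays complete.
- `stability_m()` implements geNorm-style control selection: for candidate
  j, `M_j` is the mean over other candidates k of the standard deviation
  across samples of `Ct_k − Ct_j`. The lowest-M pair is selected
  (`method = "exclusion"` reproduces the stepwise-elimination variant).
  The report checks the conventional acceptance thresholds M < 0.15 per
  control and combined (mean) M < 0.10; these are flags, not gates.
- `control_normalize()` subtracts the arithmetic mean Ct of the selected
  controls per sample — the geometric mean on the quantity scale, the
  standard multi-control normalizer.
- `ddct_fold_change()` computes `ΔΔCt = mean ΔCt(case) − mean ΔCt(ref)`;
  since Ct falls one cycle per doubling, `log2FC = −ΔΔCt` and the linear
  fold change is `2^−ΔΔCt`. `calibrated_expression()` returns per-well
  relative quantities `2^−(ΔCt − mean ΔCt over reference samples)`, so the
  reference group averages to 1 on the log scale.

## Moderated t-test

`fit_moderation()` implements the standard empirical-Bayes moment
estimator for the variance prior: with `e_g = log s²_g − digamma(d_g/2) +
log(d_g/2)`, solve `trigamma(d0/2) = var(e) − mean(trigamma(d_g/2))` for
the prior degrees of freedom d0 by a Newton iteration on the inverse
trigamma (tolerance 1e-8, at most 50 iterations, with asymptotic guards
for arguments above 1e7 and below 1e-6), then `s0² = exp(ē +
digamma(d0/2) − log(d0/2))`. If the observed spread of `e` does not exceed
its sampling expectation, d0 = ∞ and s0² is the arithmetic mean of the
variances (their common value when the spread is exactly zero). Zero or
non-finite variances are dropped with a warning; at least 10 usable
detectors are required.

`moderated_t()` forms the posterior variance `s̃² = (d0·s0² + d·s²)/(d0 +
d)` and refers `t = diff / (s̃·sqrt(1/n1 + 1/n2))` to a t distribution on
`d0 + d` degrees of freedom; d0 = 0 reproduces the ordinary pooled t-test
exactly, and d0 = ∞ uses the normal reference. The installed `limma`
package is used in the test suite as an independent oracle for both the
prior fit and the posterior variances; it is never called by the
implementation itself.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`bh_adjust()`, a validated wrapper around `stats::p.adjust`).

## Amplification-kinetics curation

Near-perfect PCR doubles template each cycle, so log2 fluorescence in the
exponential phase rises ~1 per cycle. `kinetics_qc()` isolates that phase
as the cycles whose fluorescence lies between `floor_frac` (default 0.05)
and `plateau_frac` (default 0.60) of the curve maximum, at most `window`
(default 5) cycles past the first crossing — the region after baseline
noise and before plateau saturation, where a 5-cycle cap keeps the fit
local. It then regresses log2 fluorescence on cycle and passes the
reaction iff slope ∈ [0.8, 1.2] and R² ≥ 0.98 (slope 1 ⇔ amplification
efficiency 2). Fewer than 3 usable points fails with reason
"insufficient exponential phase". `curation_from_qc()` aggregates
per-reaction verdicts to per-detector flags; the default `rule = "any"`
(one bad reaction disqualifies the detector) is the conservative choice
appropriate for small n, `"majority"` is available.

## The pipeline and its filters

`run_pipeline()` chains everything: rank test; median-normalized ΔΔCt with
Welch t; control-normalized ΔΔCt with the moderated t (falling back to
median normalization when fewer than two control candidates exist);
significance filters; kinetics curation; rank–rank concordance. Filters
are **inclusive** at their thresholds (defaults |rank_diff| ≥ 10,
|log2FC| ≥ 1, p ≤ 0.01; `NA` never passes), `venn_overlap()` partitions
the union of the three hit sets, and the focus list is the rank-filter
hits that survive curation, ordered by |rank_diff|. The rank threshold of
10 positions and fold-change threshold of 2 (|log2FC| ≥ 1) are the
conventional screening cuts for this assay family; both are plain
parameters of `filter_spec()`.

## What the simulator emulates — and what it does not

`simulate_ct()` draws
`Ct[g, s] = baseline_g + δ_s + β_g·1[case] + ε`, with detector baselines
uniform on `baseline_range` (default 18–38, spanning the usable assay
range), per-sample loading offsets δ ~ N(0, `loading_sd` = 1), well noise
ε ~ N(0, `noise_sd` = 0.5), and clamping/censoring at the detection limit
(40). Designated endogenous controls get tighter noise
(`control_noise_sd` = 0.05) and mid-range baselines (20–28) so that they
behave like the stable normalizers the geNorm thresholds presuppose —
with two controls, the expected pairwise-difference SD is √2 ×
`control_noise_sd` ≈ 0.07, comfortably below the 0.10 combined-M
convention. Detectors carrying planted effects draw their baselines from
the interior `de_baseline_range` (default 22–34) so that a |β| = 3 shift
is observable rather than destroyed by the rank floor or the censoring
ceiling; planting an effect at the boundary is still possible by widening
that range. A truth table (baseline, β, control flag) accompanies every
draw, and all randomness flows through `withr::with_seed`, so draws are
reproducible and leave the caller's RNG untouched.

The simulator deliberately does **not** model probe cross-hybridization,
pre-amplification bias, plate spatial effects, or correlated detector
noise; group sizes are balanced and noise is homoscedastic and Gaussian.

`simulate_curves()` produces amplification curves
`f(c) = plateau · min(1, efficiency^(c − c0))` — exactly log-linear below
the plateau, so a conforming efficiency-2 curve has slope exactly 1 in the
QC window. A smooth sigmoid was rejected here because its curvature near
the plateau leaks into any finite QC window and makes even a perfect
doubling reaction's window slope deviate from 1; the piecewise form makes
"the curve the QC should accept" well-defined. `drift_mode = "linear"`
gives a non-exponential ramp that the QC must reject.

`simulate_target_fixture()` builds paired per-source mouse/human target
predictions over a one-to-one ortholog map, with a known
conserved-and-expressed truth set per miRNA. Human-only filler targets are
drawn outside the orthologs of that source's mouse targets, so the planted
conserved set is exact, not merely likely.

## Target consensus

`conserved_targets()` intersects, per prediction source, mouse targets
with human targets through the ortholog map (a mouse gene with several
human counterparts is kept if **any** counterpart is predicted — the
permissive reading, chosen because losing a true target to map ambiguity
is the worse error at screening stage; unmapped genes are counted in an
attribute). `pool_sources()` unions sources with provenance;
`expression_filter()` keeps Present-called genes (uncalled genes are
treated as Absent, counted); `target_consensus(order =)` exposes both
conserve-then-pool (default, per-source conservation — stricter) and
pool-then-conserve. `fisher_enrichment()` is the right-tailed
hypergeometric test via `stats::phyper(k − 1, K, N − K, n, lower.tail =
FALSE)`, i.e. one-sided Fisher.

## Numerical and testing conventions

- Welch and moderated tests, M values, OLS bands and enrichment are exact
  closed-form computations on doubles; no iterative fitting except the
  inverse-trigamma Newton solve described above.
- Degenerate-variance conventions (p = 1 / p = 0 with a flag) are
  documented at `welch_t()` and honored throughout.
- The test suite checks hand-derived examples, algebraic invariances
  (shift/monotone invariance, antisymmetry, scale equivariance,
  filter monotonicity, Venn partitioning), independent oracles
  (`stats::t.test`, `stats::p.adjust`, `stats::fisher.test`, textbook
  enumerations, and `limma` for the moderation fit), and seeded
  parameter-recovery runs against the simulators' truth tables.
- Statistical power at these problem sizes is finite by design: with
  n = 4 per group, the Welch test on ranks retains a small per-detector
  miss rate at p ≤ 0.01 even for |β| = 3, and a calibrated p ≤ 0.01
  filter over ~380 null detectors admits a few false positives per run in
  expectation. Recovery-style checks therefore bound pooled rates rather
  than demand per-run perfection.

## Limitations

- Censored wells enter normalized analyses at the clamped limit value,
  which biases fold changes toward zero for weakly expressed detectors;
  the `censored_any`/`censored_frac` columns keep this auditable.
- The rank statistic's floor/ceiling effect bounds detectable displacement
  for detectors near the extremes of the abundance distribution.
- The moderation moment estimator assumes a scaled-inverse-chi-square
  variance prior; heavy contamination of the variance pool is not handled
  robustly (no winsorization).
- The kinetics QC assumes background-subtracted, monotone-ish curves; it
  does not model baseline drift correction.
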