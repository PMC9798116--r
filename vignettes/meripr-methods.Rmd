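---
title: "Methods: MeRIP-array quantification, screening and evidence triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeRIP-array quantification, screening and evidence triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
library(dplyr)
```

## The measurement model

An m⁶A epitranscriptomic array splits each RNA sample by anti-m⁶A
immunoprecipitation into a modified fraction (IP) and an unmodified
supernatant (Sup), hybridised as the two channels of one array. For gene
$g$ in a sample from group $k$, write $T_{gk} > 0$ for the true transcript
abundance (arbitrary intensity units) and $m_{gk} \in (0,1)$ for the true
methylated fraction. The package's generative model, which the simulator
implements and the quantification stage inverts, is

$$
IP_{gs} = T_{gk}\, m_{gk}\, \varepsilon_{gs}, \qquad
Sup_{gs} = T_{gk}\,(1 - m_{gk})\, \varepsilon'_{gs},
$$

with independent multiplicative log-normal noise per channel
($\log_2 \varepsilon \sim N(0, \sigma^2)$). Multiplicative log-normal
noise is the standard error model for array intensities: it keeps
intensities positive and makes log2 intensities normal, which is what the
downstream t tests assume.

The three derived measures per gene and sample are

- methylation **level** $= 100 \cdot IP/(IP+Sup)$ (percent),
- m⁶A **quantity** $= IP$,
- **expression** $= IP + Sup$.

Under the noise-free model these recover $100\,m_{gk}$, $T_{gk} m_{gk}$
and $T_{gk}$ exactly, which the test suite asserts to machine precision.

### Linear vs log2 scales

Channel intensities are spike-in normalised and kept **linear**; the three
measures are formed on the linear scale, because a modification
*percentage* is only meaningful there. Log2 enters in exactly two places:
fold changes (ratios of geometric means, $2^{\overline{\log_2 A} -
\overline{\log_2 B}}$) and the two-sample tests, which run on log2 values.
This reconciles "normalise and log2-transform" bookkeeping with a
percentage-valued level without ever averaging percentages on a log scale.

## Preprocessing

**Spike-in normalisation** rescales each sample × channel by one scalar so
its median spike-in intensity equals a common target (by default the
median of the per-sample/channel spike-in medians, which preserves the
experiment's overall scale). A per-column scalar is the weakest correction
that makes arrays comparable; it is exactly scale-equivariant, so a
channel distorted by a constant factor normalises to the same table as an
undistorted one (a property test).

**QC retention** keeps probes flagged Present or Marginal in at least 3
samples (of 9 in the reference design) — the "All Targets Value" set.
Flags are per sample, not per channel: the scanner emits one
detection call per spot, and both channels of a spot share it. The rule is
monotone (upgrading a flag can only retain more probes) and commutes with
normalisation, since it reads only flags.

**Probe-to-gene aggregation** is channel-first: probe intensities are
combined per channel (median by default, robust and scale-preserving) and
the level is formed from aggregated channels. Averaging per-probe
percentages instead would weight probes nonlinearly and break the
$IP/(IP+Sup)$ identity; a unit test pins the documented order with a case
where the two differ (28.6% vs 37.5%).

## The differential screen

For a contrast A/B of one measure, the fold change is the geometric-mean
ratio on linear values and the p-value comes from a two-sample test on
log2 values: Welch's unequal-variance t by default, the Mann–Whitney U
test by configuration (exact null when the combined n ≤ 16 without ties,
tie-corrected normal approximation otherwise). With three replicates per
group an exact rank test cannot reach p < 0.05 two-sided (its smallest
two-sided p is 0.1), so a parametric test is the only workable per-gene
default at this design size; that is why Welch is the default even though
the group-level cohort statistics of such studies are nonparametric.

Significance is `p < alpha` **and**, for the intensity-scale screens
(quantity, expression), a fold change at or beyond the 2-fold cutoff.
Level contrasts use the test alone: the level is a bounded percentage and
published candidate tables carry no fold-change column for it. No
multiple-testing correction is applied by default, matching the raw
"p < 0.05" convention of the screen this package models; results carry raw
p-values so any correction can be applied downstream.

Degenerate inputs resolve deterministically rather than erroring: all
values tied across both groups give p = 1; two internally constant but
different groups give p = 0 (the zero-variance limit of the Welch
statistic). This makes the noise-free simulator usable end to end.

**Arrow coding**: single arrow for changes below 2-fold, double arrow at
or beyond (the same threshold as the screening cutoff — the field's tables
do not define the magnitude rule, so reusing the screen's own cutoff is
the least arbitrary choice), a star for significance.

**Tendency** across the severity order OA → HP → SOMA is `decreasing` when
the group means satisfy OA ≥ HP ≥ SOMA with OA > SOMA strictly —
non-strict in the interior, strict at the ends — `increasing`
symmetrically, otherwise `unordered`. The non-strict interior matters:
a gene whose HP/OA and SOMA/OA declines are of equal coded magnitude is
still a monotone decline, and the worked example contains such a case
(BDNF).

## The five-evidence classifier

Candidate genes are triaged by a mutually exclusive decision tree over the
feature tuple (levels, pooled-iNOA quantity verdict, two expression
contrasts, tendency), evaluated in order:

1. quantity up, not significant, iNOA level below OA level → **i**;
2. quantity significantly up → **ii**;
3. quantity down, not significant → **iii**;
4. quantity significantly down, both expression contrasts down, SOMA/OA
   significant, tendency decreasing → **v**;
5. quantity significantly down, both expression contrasts down, SOMA/OA
   not significant → **iv**;
6. anything else → **iii**.

Mechanism = "Yes" exactly for iv and v. The published description of the
five categories is prose and under-determined — for instance, one
worked-example gene carries a significant ↑\* expression change yet is
classified iii. Keying the tree on the quantity column's
direction/significance first is the unique reading consistent with all 14
worked-example rows, and the hierarchy "i to v" is realised by the tree's
mutual exclusivity rather than by any score. The classifier is total and
deterministic; a grid test sweeps the feature space and checks both
properties.

For pipeline data, `extract_features()` builds the tuple with the pooled
iNOA arm (HP + SOMA, six samples) against OA for the level and quantity
columns — candidate tables report a single iNOA level — and the two
separate expression contrasts. The worked-example fixture does not print a
tendency column; it is derived from the two arrow codes (both down with
the SOMA/OA magnitude at least the HP/OA magnitude → decreasing), which
reproduces all 14 verdicts.

```{r fixture}
ev <- classify_evidence(load_candidate_fixture())
glance(ev)
```

## The synthetic-data generator

The simulator emulates the reference study design: 3 groups × 3
replicates, one IP and one Sup channel each, spike-in controls, P/M/A
flags. Its defaults are the study conditions, not tuning knobs:

- `n_per_group = 3` (the array cohort's size per group);
- `noise_sigma = 0.15` log2 units — arrays of this class typically show
  replicate CVs in the 10–25% range, and 0.15 log2-sd (≈ 11% CV) sits in
  it; no distributional information is published for these arrays, so this
  is a stipulation, recorded once here;
- `null_fraction = 0.9`: nulls dominate so the screen's type-I behaviour
  is measurable;
- planted genes realise each evidence category at `effect_size = 4`
  (e.g. category v: m 0.6 → 0.3 → 0.15, T 100 → 45.5 → 20 across
  OA → HP → SOMA);
- QC flag A when a probe's total intensity falls below the 2% per-sample
  quantile, plus 1% random dropout — flag genesis is scanner-internal and
  undocumented, so this is a minimal plausible mechanism;
- spike-ins at a constant true level of 1000 in both channels.

What the simulator does **not** emulate: probe-sequence effects and
affinity differences, dye bias, spatial artifacts, correlated noise
between IP and Sup, and IP-efficiency variation between samples. Passing
tests therefore demonstrate correctness of the pipeline's arithmetic and
decision rules under the stated model, not robustness to every artifact of
real arrays.

## Calibration studies

Two simulation studies back the stochastic tests; both are recomputed by
`scripts/acceptance.R` at run time.

**Null calibration.** On 2000 null genes (3 per group, σ = 0.2), the
fraction of expression contrasts with p < 0.05 is ≈ 0.035. This is a
property of the Welch test itself at n = 3 + 3, not of the pipeline:
under exact normality the Welch test's true size at this design is 0.035
(direct Monte Carlo, 100k replicates), because the Welch–Satterthwaite
degrees-of-freedom estimate is noisy at tiny n and the test goes
conservative. The suite therefore checks the calibration invariant at
n = 6 per group, where the test holds its size (≈ 0.047), and also runs
the n = 3 check at its stated band, reporting whatever it measures.
A conservative screen loses power but does not inflate false positives.

**Planted-category recovery.** Noise-free, every planted profile
round-trips through the full pipeline to its category exactly (this is by
construction and asserted for all five categories). At σ = 0.15,
effect 4, n = 3, category-v recovery over seeds 1–200 was 200/200; the
regression threshold was then fixed at ≥ 90%, leaving headroom of ten
misses per 200 for sampling variation at other seeds.

## Problem sizes and numerical choices

The suites run at the sizes above (2000 null genes; 200 recovery
replicates; 14-gene worked example), chosen as the smallest sizes at which
the binomial error bars of the measured rates are informative. Tolerances:
exact identities are asserted to machine precision (`all.equal` default);
measured rates at 3-binomial-SE bands. Fold-change boundaries are
inclusive (fc = 2 is a double arrow and passes the cutoff). Ties in the
Mann–Whitney test switch it to the corrected normal approximation; zero
and negative intensities are excluded from log-scale contrasts and genes
missing a group are reported as missing rather than guessed.

## Limitations

- The evidence tree is a formalisation of an under-specified published
  rule system; it reproduces the complete worked example but other
  readings of the prose exist.
- The per-gene test at n = 3 has limited power and (for Welch) a
  conservative size; the screen's counts should be read accordingly.
- Aggregation assumes probes of a gene are exchangeable; probe-level
  affinity correction is out of scope.
- The ELISA percent-m⁶A formula is the kit-convention slope ratio; the
  positive-control input mass is kit-specific and must be supplied.
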