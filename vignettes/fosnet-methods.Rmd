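---
title: "Differential c-Fos coactivation networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential c-Fos coactivation networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fosnet)
```

## The scientific problem

Counts of cells expressing the immediate-early gene *c-fos* are a standard
proxy for recent neuronal activation. In a conditioned taste aversion (CTA)
study, animals experience an appetitive stimulus (a palatable nutritive
drink), an aversive visceral stimulus (LiCl injection), or their conditioned
combinations, and Fos is counted in a panel of brain regions. Region-level
mean comparisons miss *coactivation*: two regions whose Fos counts rise and
fall together across animals within a condition are plausibly acting as a
functional circuit even if neither shows a mean effect. fosnet implements
this coactivation analysis as a reusable, tested pipeline:

1. per-condition **correlation networks**: all pairwise Pearson correlations
   of per-subject regional Fos counts, thresholded at significance;
2. **differential (subtraction) networks**: the task network minus the
   control network on the Fisher-z scale, re-tested after back-transformation,
   isolating task-specific coupling;
3. the **behavioral scoring** conventions used alongside the imaging arm
   (D2/D1 intake ratio, ultrasonic-vocalization block percentages, ordinal
   nausea scoring);
4. a **synthetic generator** with planted correlation structure, because the
   per-subject raw data behind such studies are typically unpublished and the
   pipeline must be testable end to end.

The design constants are fixed by the study layout: 11 brain regions
(`region_registry()`), six conditions in two arms (`condition_registry()`,
acute AN/AB/AL and task COT/BOT/BLT), a 38 mg/kg LiCl conditioning dose, and
a 1 mL day-1 intake eligibility minimum.

## Per-condition networks

For a condition with $n$ animals (sexes pooled — single-sex cell sizes in
this design are 3–4, far too small to estimate 55 correlations), every pair
of regions $(i, j)$ gets the sample Pearson coefficient $r_{ij}$ over
complete cases, and a two-tailed p-value from

$$t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}}, \qquad df = n - 2.$$

Pairs with $p < \alpha$ (default $\alpha = 0.05$) become signed edges; all
other entries of the adjacency matrix are set to 0. "Independent
substructures" are the connected components of the retained graph, and
regions with no retained edges are reported as isolates. Centrality is
degree centrality by default — the simplest defensible formalization of a
region being "central" — with betweenness reported alongside for reference;
ranking ties break by registry order so output is deterministic.

No multiple-testing correction is applied by default, matching the per-pair
$p < 0.05$ convention of the source analysis; `threshold_network(...,
p_adjust = "BH")` gives a documented stricter mode.

```{r}
fos <- simulate_fos(synthetic_fos_config(
  n_per_group = 6,
  planted_edges = list(BOT = data.frame(
    region_a = "CeA", region_b = "VTA", target_r = 0.85))), seed = 7)
net <- threshold_network(condition_correlation_matrix(fos, "BOT"))
net
network_summary(net)$ranking[1:4, ]
```

## Differential networks

To isolate coupling specific to a task, the control condition's correlations
are subtracted on the variance-stabilized Fisher scale:

$$z = \tfrac{1}{2}\,[\ln(1+r) - \ln(1-r)], \qquad
  z_{\text{diff}} = z_{\text{task}} - z_{\text{control}},$$

then $z_{\text{diff}}$ is back-transformed to a correlation
$r_{\text{diff}}$ and re-tested with the same $t$ formula. Three choices in
this chain were genuinely open and are worth recording:

- **Which matrices enter the subtraction.** The full (unthresholded)
  correlation matrices are used. Zeroing non-significant control entries
  first would turn a sub-threshold control correlation of, say, 0.4 into a
  manufactured difference of 0.4; `subtract_thresholded = TRUE` reproduces
  that alternative reading for comparison.
- **Which n feeds the re-test.** The subtraction re-tests the *task*
  network, so the default is the task condition's per-pair complete-case n
  (`n_rule = "task_n"`); `control_n` and `min_n` are available and logged in
  every output.
- **Tail convention.** The re-test is two-tailed; a coupling present only in
  the control condition is as informative as one present only in the task.

A caveat that the package documents rather than hides: under the null of
equal correlations, $z_{\text{diff}}$ has variance $2/(n-3)$, while the
$t$ re-test implicitly assumes the variance of a single correlation. The
chain is therefore anticonservative — at $n = 15$ its empirical null
retention rate is about 0.165 rather than 0.05, measured by Monte-Carlo
simulation in the test suite. fosnet implements the published formula
faithfully and verifies it against an independent brute-force oracle;
users who want a calibrated differential test should treat retained edges
as a screening set.

Degenerate inputs are contained, not fatal: constant regions and pairs with
fewer than 3 complete cases are flagged missing and excluded pairwise;
$|r| = 1$ (possible at these small n) is clamped to $1 - 10^{-12}$ before
the z-transform, with the clamp recorded.

## Behavioral scoring

- **CTA ratio**: day-2 / day-1 intake of the conditioned drink; 1 means no
  aversion, values near 0 mean strong aversion. Animals drinking under 1 mL
  on day 1 were never conditioned and are excluded (recorded, not silently
  dropped). Intake comparisons across body sizes use mL/kg.
- **USV block scoring**: the 10-minute task-day recording is scored in ten
  1-minute blocks; a block is positive for the 55 kHz channel if it has
  *more than* 10 calls, and for the 22 kHz channel if it has *more than* 1
  call. The printed rule is taken literally (strict inequalities); a
  `strict = FALSE` flag relaxes both to at-least. Scores are percentages of
  positive blocks, hence multiples of 10. Animals are classed as
  none/only55/only22/both emitters, and `tally_emitters()` builds the
  condition-by-class-by-sex contingency table, excluding non-emitters from
  the cells but reporting their count separately — row totals then count
  emitting animals, which reproduces the published tally exactly on the
  bundled fixture.
- **Nausea scoring**: pica, lying-on-belly and ptosis are scored 0–3 in two
  consecutive 15-second blocks every 5 minutes for an hour (24 blocks, max
  total 72). Both the summed score and the per-block mean are returned; the
  sum is the default aggregate since "events" in such designs are most
  naturally read as accumulated score. Partial sessions are allowed, with
  the observed block count carried in the output.

## The synthetic generator

`simulate_fos()` draws each condition-by-sex group from a multivariate
Gaussian: per-region means and SDs come from a calibration table, and the
correlation matrix is a planted-edge target repaired to positive
definiteness. Draws are clamped at zero (counts cannot be negative).
Design choices:

- **Gaussian, not Poisson/negative-binomial.** The observed quantities are
  per-animal *averages* of counts over several images, i.e. real numbers,
  and the downstream statistic is the Pearson correlation, which depends on
  the first two moments. The clamp at 0 biases low-mean regions (the SON
  especially) upward; the generator reports the analytically expected
  post-clamp mean per cell (`E[max(0, X)]` for censored Gaussians) so
  calibration checks can account for it.
- **Calibration.** Defaults use the published group means and SEMs per
  region, condition and sex (`fos_reference_means()`), with
  `sd = sem * sqrt(sem_n)`. Exact per-cell group sizes were not published;
  figure legends give ranges, most commonly 3–4 per sex, so `sem_n = 4` and
  `n_per_group = 4` (pooled n = 8 per condition) are the defaults. Both are
  configurable, and `n_per_group` accepts per-sex sizes for unbalanced
  designs.
- **PD repair.** Infeasible planted sets (e.g. a frustrated
  +0.9/+0.9/−0.9 triangle, or any star with more than one 0.85 edge) are
  repaired by eigenvalue clipping with rescaling to unit diagonal, iterated
  until the smallest eigenvalue is at least 1e−8; a Higham
  alternating-projections option is available via the Matrix package.
  Achieved values are reported and deviations beyond 0.05 warn.
- **Behavior.** Expected D2/D1 follows a non-increasing dose curve
  (1.0, 0.65, 0.45, 0.30 at 0/19/38/80 mg/kg by default — a typical robust
  CTA profile with intact intake under saline), with lognormal subject
  noise. Day-1 intake is lognormal in mL/kg with females drinking more per
  kg than males. USV counts are zero-inflated negative-binomial per minute:
  the zero-inflation term models the substantial fraction of animals that
  never vocalize, and the defaults qualitatively reproduce the observed
  pattern (55 kHz calls peaking in anticipation of the un-devalued reward,
  22 kHz calls concentrated in the devalued condition, especially in
  females). Nausea block scores come from a dose-shifted latent Gaussian
  with a per-subject intercept, cut at fixed thresholds, so scores increase
  stochastically with dose.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: inter-regional covariance beyond the planted edges,
non-Gaussian tails and count discreteness, estrous-stage effects on Fos,
litter or batch structure, and the true (unpublished) effect sizes of the
USV and nausea differences. Tests against the generator validate the
*computational chain*, not the biology.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is byte-reproducible
given (config, seed); the pipeline writes a manifest with the seed and a
config hash so any artifact can be regenerated. The bundled checks use
problem sizes chosen to keep the whole suite in a few minutes on one core:
200 random small instances for exact oracle equivalence (tolerance 1e−10),
2000 replicates for null calibration of the thresholded network (the
Pearson t-test is exact under Gaussian independence, so the retained-edge
proportion is 0.05 up to Monte-Carlo error), and 400 pipeline replicates
against a 3000-replicate brute-force oracle for differential recovery
(sensitivity ≈ 0.96 at a planted task-only edge of r = 0.85 with pooled
n = 15).

## Known limitations

- The differential re-test is anticonservative by construction (above); it
  is reproduced, verified, and documented, not corrected by default.
- With pooled n near 8–15, correlation estimates are noisy; exact edge sets
  of any particular study are not recoverable, and analyses should lean on
  the calibration and recovery-rate guarantees, not on individual edges.
- Sexes are pooled by default for power; single-sex networks are available
  (`pool_sexes = FALSE`) but rarely estimable at realistic cell sizes.
- The scoring functions assume the fixed session geometries described above
  (10 one-minute USV blocks; up to 24 nausea blocks); other designs need
  explicit reshaping first.
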