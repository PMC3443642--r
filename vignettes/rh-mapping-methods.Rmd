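---
title: "Radiation hybrid mapping: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation hybrid mapping: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhmapper)
```

## The measurement model

A radiation hybrid (RH) panel for a single wheat chromosome is a set of
lines, each carrying a gamma-irradiated copy of the chromosome rescued by
crossing onto an aneuploid background.  Each marker is scored as retained
(1), deleted (0) or missing, so a panel is a binary lines-by-markers matrix
([`rh_genotypes`]).  Because radiation-induced deletions remove contiguous
stretches of chromatin, nearby loci are co-retained or co-deleted, and the
rate of *state differences* between two loci plays the role that
recombination fraction plays in genetic mapping.  One centiRay (cR) is
defined as one state difference between two adjacent loci per 100 lines
screened; `two_point()` estimates it as `100 * n_discordant /
n_informative` with missing calls excluded pairwise.

On top of this raw distance, the classical haploid retention model gives a
likelihood.  With pooled retention `r` for a pair of loci and breakage
probability `theta` (the chance of at least one effective break between
them), the cell probabilities are

```
P(1,1) = (1 - theta) r + theta r^2     P(1,0) = P(0,1) = theta r (1 - r)
P(0,0) = (1 - theta)(1 - r) + theta (1 - r)^2
```

with independence as the boundary `theta = 1`.  The moment estimator
`theta_hat = min(1, D / (2 r (1 - r)))` (with `D` the discordance fraction)
is also the maximiser of this likelihood, and the pair's LOD is the base-10
likelihood ratio of `theta_hat` against independence.  When `r` is 0 or 1
the pair carries no breakage information; such pairs are flagged degenerate
and carry LOD 0.

## Ordering objective

Framework ordering maximises a composite objective: the **sum of adjacent
two-point LODs** along the order (`multipoint_loglik()`).  A Markov-chain
likelihood across adjacent loci decomposes into per-edge joint likelihoods;
subtracting each edge's independence likelihood removes the marginal
entropy terms.  Those marginals depend on the pair's pooled retention, and
on real panels they differ enough between pairs to dominate raw
joint-likelihood comparisons — an edge between two high-retention loci
scores above an edge between genuinely linked loci simply because
concordant-retained cells are individually likely.  The LOD form cancels
this and leaves only linkage evidence; loci farther apart than the breakage
saturation distance contribute LOD near 0, so the objective is explicit
about what the data cannot order.

Two classes of lines are excluded from the *ordering* likelihood (never
from the reported distances, whose denominator is all lines screened):

* lines that retain or lack the whole chromosome witness no breakage;
* lines that lost more than a whole arm make loci hundreds of Mb apart
  look co-deleted, which the two-locus model misreads as tight linkage.

The default is therefore the classical informative-line window, retention
in `[0.5, 1)`, overridable via `likelihood_lines`.

## Map construction

`build_framework_map()` proceeds in stages:

1. **Collapse** markers with identical call vectors into loci
   (`collapse_cosegregating()`; by default the missing pattern is part of
   the identity, `missing_wildcard = TRUE` merges compatible patterns
   greedily in lexicographic order).
2. **Arm split.**  Interstitial deletions do not cross the centromere, so
   the two arms are separate linkage groups.  Loci are grouped into
   linkage components at the lowest LOD threshold of the schedule; each
   component takes the majority arm of its anchor loci and anchorless loci
   join the arm of their best-linked assigned locus.  Each arm is then
   ordered independently and the arms are concatenated short-distal to
   long-distal.  Without anchors or bin information the chromosome is
   ordered as a single chain.
3. **Seeding and LOD-gated insertion.**  Each arm's order is seeded with
   its anchor pair of maximal two-point LOD.  Every unplaced locus is then
   scored at every insertion slot; its placement LOD is the gap between
   its best and second-best slot.  The best-supported locus is inserted
   while its placement LOD meets the current threshold of the schedule
   (default 10, 8, 6, 3); when no locus qualifies the threshold is
   lowered, and loci that never qualify are attached at their best slot,
   flagged non-framework.
4. **Polish.**  Greedy insertion can leave a terminal segment attached in
   reverse orientation; a window-3 ripple cannot repair that, so the
   polish alternates 2-opt segment reversals, relocations of segments of
   up to three loci (in either orientation) and the ripple until none
   improves the objective.  All moves only ever increase the same
   objective, so the exhaustive-enumeration equivalence checked in the
   tests is preserved.
5. **Positions and orientation.**  Positions are cumulative adjacent
   two-point distances over *all* lines screened.  Orientation makes
   anchor bins run from the distal short arm to the distal long arm; ties
   fall back to lexicographic order, making the whole construction
   deterministic (every tie in the pipeline is broken lexicographically).

`assign_bins()` places bin boundaries at cR midpoints between adjacent
anchor loci of different bins, extrapolating bins to non-anchored loci.
On correctly ordered preset-scale panels this midpoint rule assigns at
least 95% of non-anchor markers to their true bin; end-to-end accuracy is
lower when the order itself is uncertain (see *Limits of order recovery*).

## Deletion calling and sizing

`call_deletions()` reports maximal runs of deleted loci per informative
line, bounded by retained loci or map ends; missing locus calls bridge a
run without extending it (a failed assay should not split one physical
deletion in two).  The true breakpoint lies between the last deleted and
first retained locus, so the reported size uses the midpoint convention
`(inner + outer) / 2` — unbiased when the breakpoint is uniform within the
flanking interval; both bounds are also reported.  Mb sizes multiply each
bin-segment of the midpoint interval by that bin's resolution (Mb per cR),
the same conversion exposed directly as `cr_to_mb()`.  Terminal runs count
as deletions; lines whose single run exceeds a whole arm are classified
`SUPRA_ARM_LOSS` by `classify_lines()` and are excluded from size
statistics, as are whole-chromosome losses and fully intact lines.

## Per-bin statistics and the correlation layer

`compute_bin_metrics()` derives, per deletion bin: saturation (Mb per
marker), RH and genetic resolution (Mb per cR, Mb per cM), break/repair
frequency `BR = (cR/2)/Mb` (a deletion between two loci reflects two
breaks, so half the cR span counts break/repair events), crossing-over
frequency `CO = cM/Mb`, and the cR/cM ratio.  Chromosome-level averages
are totals-based (total Mb over total span), never means of bin values.
Display rounding is half-up to one decimal (two for ratios of 10 or
more); raw values are always retained, and comparisons against printed
table cells in the tests are rounding-tolerant in both the cell and its
inputs, because several published genetic cells are only consistent with
unrounded centimorgan spans.

`pearson_cor()` implements the product-moment correlation with a
two-tailed t test at `n - 2` degrees of freedom; `correlation_suite()`
applies it to the BR/CO/deletion/centromere-distance panel, dropping bins
that lack a variable (the 4-Mb bin 3BS2 has no genetic span and leaves
n = 10 for the BR-CO test).  Computed from the packaged per-bin table the
BR-CO correlation is r = 0.879 (p = 0.0008): reproducing this requires
the *unrounded* derived frequencies, which is how the suite computes them.
The distance of a bin from the centromere is not defined in any standard
way; the package uses the fractional bin midpoint scaled by arm size, with
a `units = "fraction"` alternative, and asserts only sign and significance
class for centromere correlations.

## The panel simulator

`simulate_panel()` implements the chromatin-openness working hypothesis as
a generative model.  Each bin has an openness score `omega > 0`, the single
shared driver of both somatic break/repair and meiotic crossing over —
which is exactly what makes recovering the BR-CO correlation from
simulated panels a meaningful end-to-end test rather than a tautology.

* Per informative line and bin, the deletion count is Poisson with rate
  `lambda * omega * size_mb`.
* A deletion starts uniformly in its bin and extends in a random direction
  with hazard `omega(x) / mu` per Mb — its extent is Exponential(mean
  `mu`) in the cumulative-openness coordinate — truncated at the arm
  boundaries.  Within a homogeneous bin this is the familiar Exponential
  physical length of mean `mu / omega`; across bins it keeps the
  stationary per-marker deletion probability at `1 - exp(-lambda * mu)`
  *independent of openness* (count ~ omega and size ~ 1/omega cancel),
  which reproduces the evenly distributed deletion frequency observed in
  the real panel.  A fixed per-bin Exponential length would break this:
  long deletions from compact bins pile into open neighbours and inflate
  their frequencies by up to 60% in the wheat-3B geometry.
* Line classes (intact / whole-chromosome loss / supra-arm loss /
  informative) are drawn at configured proportions; supra-arm lines lose
  one arm plus a uniform extension past the centromere.
* Assay noise: per-call flips with probability `epsilon`, then missing
  with probability `missing_rate`.
* Genetic spans: `cM = rho * omega * size_mb` with Poisson counting noise
  over a notional F2.

The closed-form expected discordance between loci `d` Mb apart,
`2 (q - q^(2 - exp(-d omega / mu)))` with `q = exp(-lambda mu)`
(`expected_discordance()`), was verified against brute-force Monte-Carlo
simulation of the deletion field before the tests came to rely on it; the
popular first-order approximation `2 lambda mu (1 - exp(-d omega / mu))`
is biased upward at realistic rates and is provided only for reference.

### The wheat-3B preset

`wheat3b_preset()` fixes the study conditions: 92 lines in the
13:9:8:62 class mix, the 11 tabulated deletion bins with their physical
sizes and marker counts (541 markers, 24% anchors), openness proportional
to each bin's published BR frequency (normalised to a size-weighted mean
of 1), `mu = 26.4` Mb, and `rho` set so the simulated genetic map totals
179 cM.  `lambda` is calibrated 15% above the nominal `2.8 / 891` per Mb
because a fraction of generated deletions covers no marker at the panel's
density: with the calibration, the *observed* summaries over replicate
panels are a mean retention near 0.78, 2.7 observed deletions per
informative line and a 27 Mb mean deletion size, within the 15% bands
around the published 0.89 / 2.8 / 26.4 targets.  Assay flips default to 0
(the real panel was genotyped in duplicate with PCR-failure controls);
1% of calls are missing.

What the simulator does not emulate: genotyping error structure (DArT
hybridisation noise), segregation distortion, translocations beyond the
supra-arm caricature, or sub-marker breakpoint structure.  Passing tests
therefore validate the estimators and the pipeline's logic under the
stated generative model, not the wet-lab properties of any real panel.

## Limits of order recovery

At the calibrated deletion density the pairwise discordance between loci
saturates once they are more than about one mean deletion length apart:
such loci share no breakage events and *no* method can order them from
retention data alone.  Concretely, with 2.8 deletions of mean 26.4 Mb per
informative line, the saturation discordance is about 15% among
informative lines, and with 92 lines the sampling noise of a pairwise
estimate (about 4-5 cR) is of the same order as the usable dynamic range.
Measured consequence: on preset panels the likelihood itself ranks some
block-permuted orders above the true order, perfect recovery of even the
well-separated (5 cR+) locus subsequence essentially never happens, and
the corresponding end-to-end acceptance check is expected to fail — the
distance *estimates* along the true order are unbiased and within 3
binomial standard errors of the closed form 99%+ of the time, so it is the
block-scale ordering information, not the estimator, that the panel lacks.
It is worth noting that the published map's own numbers are in tension
here: a 1871.9 cR total at the stated cR definition implies roughly nine
state flips per line, three times what 2.8 deletions per line can produce,
suggesting the real map length carries a large assay-noise component that
a noise-free generator calibrated to the deletion statistics cannot and
should not reproduce.

When the information is present the machinery does recover order: on
panels with 90+ lines, evenly spaced loci at 40% of the mean deletion
length and a deletion rate of `lambda * mu = 0.5` (adjacent expected
discordance about 18%, far above the 5% floor), the exact true order is
recovered in at least 95% of seeded replicates, and on 5-8 locus panels
the builder attains the exhaustive-enumeration optimum of its objective in
every tested instance.

## Numerical and edge-case conventions

* All ties (seeding, insertion, orientation, group representatives) break
  lexicographically; a fixed seed makes every pipeline product
  byte-identical across runs.
* Missing calls are pairwise-excluded in every frequency and two-point
  computation; a locus state for deletion calling is the majority call of
  its member markers, `NA` on ties.
* Degenerate two-point pairs (pooled retention 0 or 1) return their raw
  distance with LOD 0 and a flag.
* `cr_interval_to_mb()` refuses intervals overlapping bins with no
  defined resolution (anchor-less bins); deletion calls touching such
  bins carry `NA` Mb sizes rather than a guess.
* Bin boundaries on the cR axis are clipped to be non-decreasing when
  anchors interleave, with a warning and median-position ordering.
* Simulation problem sizes used by the test-suite: 50 preset panels for
  calibration and recovery, 2 x 50 ten-bin panels for the openness
  detection and its null, 25 panels of 5-8 loci for the enumeration
  oracle.
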