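---
title: "Methods: metric definitions, the synthetic benchmark, and design choices"
author: "alphadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metric definitions, the synthetic benchmark, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadiv)
```

## The four-category model of alpha diversity

`alphadiv` treats within-sample diversity as four complementary, partly
independent aspects, each with its own metric family:

* **Richness** — how many taxa are present. Includes the raw observed
  count and estimators that extrapolate to unseen taxa from the
  rare-class structure (Chao1, ACE), a parametric abundance model
  (Fisher's log-series α), read-depth-corrected counts (Margalef,
  Menhinick), and the Robbins estimator of the probability that the next
  read is a new taxon.
* **Dominance (evenness)** — how concentrated the reads are.
  Berger–Parker is the reference metric of the category: it is the single
  most interpretable quantity (share of reads in the top taxon), and the
  other dominance metrics are dominated by the top one or two taxa anyway
  (`topTwoRatio()` exposes that driver directly).
* **Information** — entropy-based syntheses of richness and evenness
  (Shannon and its finite-population and normalised variants).
* **Phylogenetics** — Faith's PD, the branch-length sum of the subtree
  spanning the observed taxa; presence/absence only.

The registry (`metricRegistry()`) encodes this taxonomy: 7 + 7 + 4 + 1 =
19 metrics. The recommended reporting panel draws one metric from each
category — observed features, Robbins, Berger–Parker, Faith PD, Shannon —
so that a reported "diversity difference" can be attributed to an aspect.

## Metric conventions

Count vectors are non-negative; zeros are absences, so every metric is
invariant under zero-padding and permutation (property-tested). Metrics
built on singleton/doubleton tallies or factorials (Chao1, ACE, Robbins,
Brillouin, observed/singleton/doubleton counts) reject fractional counts:
averaged or rarefied-and-scaled tables have no well-defined rare classes.

Several of these indices circulate in mutually inconsistent printed forms
that confuse the number of taxa $S$ with the number of reads $N$. We
implement the standard, literature-consistent forms used by the major
amplicon toolchains, which keep each metric inside its documented range:

* Berger–Parker $n_{max}/N$ (not $n_{max}/S$), so the value is a read
  share in $(0, 1]$;
* McIntosh $(N-U)/(N-\sqrt N)$ with $U = \sqrt{\sum n_i^2}$, 0 when one
  taxon holds all reads, 1 when every read is its own taxon; undefined at
  $N<2$;
* Brillouin $(\ln N! - \sum \ln n_i!)/N$ via log-gamma (no factorial
  overflow);
* Strong $\max_i(b_i/N - i/S)$ with $b_i$ the descending cumulative
  counts: 0 for a perfectly even sample;
* Gini as the normalised mean absolute difference
  $\sum_i\sum_j |x_i-x_j| / (2S^2\bar x)$ (computed through the sorted
  identity), which is 0 at perfect evenness and bounded by $1 - 1/S$ —
  some rank-weighted transcriptions instead evaluate to 1 on an even
  sample, contradicting the definition of the index.

Other conventions, each exposed rather than hard-coded:

* **Robbins** has two denominators in circulation. The default `reads`
  variant $F_1/(N+1)$ is Robbins' original estimator (and what the common
  toolchains compute); the `features` variant $F_1/(S+1)$ expresses
  singletons relative to observed taxa. One flag switches.
* **Chao1** uses the classic $S + F_1^2/2F_2$ when doubletons exist and
  the bias-corrected $S + F_1(F_1-1)/(2(F_2+1))$ when $F_2 = 0$, where
  the classic form would divide by zero. Both collapse to $S$ at
  $F_1 = 0$.
* **ACE** uses the conventional rare/abundant threshold of $k = 10$ reads
  and the Chao–Lee coefficient-of-variation correction
  $\gamma^2$, floored at 0. Two guarded degeneracies: if every rare taxon
  is a singleton the rare-group coverage $C_{rare}$ is 0 and ACE is
  reported as an explicit "undefined" error (a missing value at table
  level); if the rare group is a single taxon, the CV term's
  $N_{rare}(N_{rare}-1)$ denominator would vanish and $\gamma^2$ is 0.
* **Shannon** is reported in bits (base 2) by default, the toolchain
  convention; the base is a parameter. Heip is defined on the natural-log
  entropy so that $e^H$ is an effective species number, and Pielou is
  base-invariant, so neither depends on that choice.
* **$S = 1$ samples**: Pielou and Heip are 0/0 and return a missing value
  (serialised as an empty cell, never `"NA"` text); Margalef, Gini and
  Strong return 0 by convention. At table level
  (`computeAlphaDiversity()`) any per-sample metric failure becomes a
  missing cell with the reason summarised in one warning — batch runs
  never abort on one degenerate sample.
* **Fisher's α** solves $S = \alpha\ln(1+N/\alpha)$ by bracketed root
  search on $[10^{-8}, 10^{8}]$ and enforces a residual below $10^{-10}$;
  all-singleton samples ($S = N$) are rejected as divergent.
* **Faith PD** runs root-inclusive by default (a single observed tip
  contributes its full root path), matching the common toolchain; the
  `includeRoot = FALSE` flag restricts to the subtree below the MRCA of
  the observed set. Observed features missing from the tree are a hard
  error: silently dropping them would bias PD downward invisibly.

## The synthetic benchmark

The generator emulates the statistical skeleton of denoised stool-sample
ASV tables, controlling exactly the two factors that drive metric
behaviour:

* richness levels 50–500 in steps of 10;
* singleton targets 0, 3, 6, … capped at min(100, 40% of richness);
* doubletons at 40% of singletons (rounded);
* the remaining taxa drawn from one of five abundance families —
  Poisson(λ = 50), negative binomial (mean 50, dispersion 0.5),
  uniform(0, 100), exponential(mean 50), normal(50, 15, truncated at 0).
  The families and the rare-class schedule are the study conditions; the
  family parameters are plausible per-taxon read scales chosen once (mean
  ≈ 50 reads per non-rare taxon) — the benchmark's conclusions are about
  rank behaviour, which is insensitive to the scale;
* non-rare counts are generated as $3 + \mathrm{round}(\text{draw})$.
  The offset guarantees a non-rare draw can never collide with counts 1
  or 2, so realized singleton/doubleton counts equal their targets in
  100% of samples (asserted for every family);
* optional unevenness: the most abundant taxon is rescaled to
  $\mathrm{round}(r \times \text{second most abundant})$, for
  $r \in \{2, 10, 100\}$. We implement the ratio as max/second, so that
  larger $r$ means stronger dominance; the realized fold ratio is exact
  for integer $r$, the operation is idempotent, and it never touches the
  rare classes (it refuses if the second-largest count is below 3).
  The negative-binomial baseline's natural top-two ratio is whatever the
  draws produce; it is recorded per sample in the design table, not
  enforced.

The full default grid yields 1,284 designs (the per-richness singleton
schedules sum to that; e.g. 7 designs at $S=50$, 34 at $S\ge250$); a
replicate multiplier scales it. Features are sample-private (no taxon is
shared between samples) because every quantity here is within-sample;
the union table is stored sparsely.

What the generator does **not** emulate: sequencing error, chimeras,
compositional coupling between samples, amplicon-region effects, or
rarefaction. Random phylogenies (`generateRandomTree()`: random binary
topology, exponential branch lengths) make Faith PD testable on synthetic
data, but they carry no biological signal — passing tests demonstrate
algorithmic correctness and metric behaviour under controlled abundance
structure, not performance on real communities.

## The comparison pipeline

* Min-max normalisation maps each metric to $[0,1]$; constant columns go
  to 0 with a warning.
* Correlations are pairwise-complete (not listwise): evenness metrics are
  missing for $S=1$ samples and listwise deletion would bias the other
  pairs. Per-pair sample counts are recorded.
* Dominance metrics are regressed on Berger–Parker by OLS; for ENSPIE an
  exponential transform (OLS on $\log$ response) fits better, and the fit
  is reported on that scale. OLS results are verified against the
  closed-form normal equations to $10^{-10}$.
* LOESS (tricube local polynomial, span 0.75, degree 2 — the statistical
  environment's defaults, both exposed) reports
  $R^2 = 1 - SS_{res}/SS_{tot}$ on fitted values; LOESS has no canonical
  $R^2$, and this mirrors the linear-fit definition.
* Kruskal–Wallis uses the tie-corrected $H$ with a chi-square
  approximation on $g-1$ degrees of freedom (no exact small-sample
  enumeration); all-equal inputs are rejected explicitly since the tie
  correction annihilates $H$. Its type-I error is calibration-tested at
  the 5% level over 500 null replicates of generator output. No
  multiple-testing correction is applied by default.

## Problem sizes in the test suite

The suite's heavy checks run on: the full 1,284-sample default grid for
the correlation-structure and unevenness-series checks (one dataset per
needed family/ratio); 1,000 random count vectors ($S \le 50$, counts
$\le 1000$) for the dual-route oracle equivalence of all 18 abundance
metrics; 100 random 20-tip trees for Faith PD against a brute-force
edge-marking oracle; 500 null replicates for the Kruskal–Wallis
calibration; and a 5-level grid for the byte-determinism check of the
full pipeline. These sizes were chosen to exercise the full design ranges
while keeping a complete run in a couple of minutes.

## Known limitations

* **Menhinick on the synthetic grid.** Because the grid varies singletons
  orthogonally to richness, the read total $N$ varies substantially at
  fixed $S$, and Menhinick ($S/\sqrt N$) picks that variation up: its
  rank correlation with observed richness on the default grid sits just
  below 0.9 (≈0.87 under Poisson, computed by the acceptance checks),
  while every other non-Robbins richness pair is ≥0.93. On real cohorts,
  where $S$ and $N$ co-vary strongly, richness metrics correlate more
  tightly. This is a property of the deliberately orthogonal benchmark
  design, not of the metric implementation (which is oracle-verified);
  the corresponding acceptance assertion is left failing rather than
  weakening the benchmark's orthogonality.
* ACE is undefined on samples whose rare class is all singletons — common
  in sparse, low-depth samples; at table level these become missing
  values, so column summaries of ACE silently condition on definedness.
* Faith PD on synthetic data uses random trees (see above).
* Confidence intervals / variance estimators for Chao1 and ACE,
  rarefaction, and abundance-weighted PD variants are out of scope.
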