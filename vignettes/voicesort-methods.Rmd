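---
title: "Methods: scoring, inference and simulation of voice identity sorting tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, inference and simulation of voice identity sorting tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicesort)
```

## The task and its measures

In a free identity sorting task, listeners group short voice recordings into
clusters by perceived speaker identity, choosing the number of clusters
freely. The canonical design analysed here uses two talkers with 15 naturally
varying recordings each, plus one synthetic vigilance clip presented twice:
32 items, of which 30 are test items. Cluster labels are meaningless — only
the induced partition matters — and all voicesort scores are invariant under
relabeling and item reordering.

Scoring goes through the pairwise **response matrix**: with vigilance items
removed, entry $(i, j)$ is 1 iff items $i$ and $j$ share a cluster. Because
the matrix comes from a partition, the induced relation is an equivalence;
the diagonal is trivial and excluded from every average. Three measures
follow:

* **number of clusters** $k$ over test items (clusters containing only
  vigilance items never count; if a vigilance item strays into a test
  cluster, that cluster's test items still count);
* **telling together** $= \frac{1}{|W|}\sum_{(i,j) \in W} M_{ij}$ over the
  set $W$ of unique same-talker pairs ($|W| = 2\binom{15}{2} = 210$ in the
  default design);
* **telling apart** $= \frac{1}{|B|}\sum_{(i,j) \in B} M_{ij}$ over the
  unique cross-talker pairs ($|B| = 15 \times 15 = 225$). With more than two
  talkers the average simply runs over all cross-talker pairs; this is an
  extension beyond the two-talker design, kept because it degenerates to the
  standard definition at two talkers.

Telling-together is 1 with telling-apart 0 exactly when the partition equals
the true talker partition. Both scores are monotone under coarsening: merging
two clusters can only raise them. Degenerate designs are refused loudly —
telling-together is undefined if no talker contributes two items,
telling-apart if there are fewer than two talkers.

## Participant quality control

Four exclusion rules are applied in a fixed order: (1) failed vigilance
check — the duplicated clip must sit alone in its own cluster; (2) prior
familiarity with the talkers (questionnaire flag); (3) insufficient exposure
(questionnaire flag); (4) single-cluster anomaly — all test items in one
cluster. The rules are independent predicates, so the order affects only
which rule a multiply-matching participant is attributed to in the ledger,
never the retained set; the order chosen mirrors the sequence in which such
screens are usually reported. The single-cluster rule is implemented on
partition shape alone: response-time information is not part of the data
model, and no time threshold is defined for it. Missing questionnaire
metadata is an error, not silent retention.

## Group inference

Scores from sorting tasks are bounded, discrete and typically far from
normal, so the four planned pairwise contrasts per measure (two talker-
familiarity, two accent-familiarity) use the two-sample Mann–Whitney test.
Twelve tests in all are judged at the Bonferroni-adjusted alpha
$0.05/4 = 0.0125$ — alpha adjustment, not p-value adjustment, is the primary
output.

Reporting conventions are fixed and documented because published W values
rarely state theirs: the statistic is $U$ for the first-named group (its
midrank sum minus $n_a(n_a+1)/2$); $Z$ standardises $U$ with the
tie-corrected null variance and **no continuity correction**, so the effect
size $r = |Z|/\sqrt{N}$ is on the same footing whether the p-value was exact
or asymptotic. Bands for $r$: below 0.1 negligible, 0.1–0.3 small, 0.3–0.5
medium, 0.5 and above large. The exact method computes the permutation null
of the rank sum by a subset-sum count recursion over doubled midranks
(ties handled exactly) and defines the two-sided p as
$P(|S - \mathbb{E}S| \ge |s_{obs} - \mathbb{E}S|)$; in the tie-free case
this coincides with the classical doubled-tail convention. By default the
exact method is used for $n_a + n_b \le 20$ without ties and the asymptotic
otherwise; both samples constant is reported as degenerate ($Z = 0$,
$p = 1$, flagged). No interaction test is offered: with familiarity groups
defined at recruitment the design does not support one, and rank methods do
not combine the two factors cleanly — effect sizes are compared
qualitatively instead.

## The synthetic cohort generator

No raw sorting data ship with the package, so a generative model makes the
pipeline testable end to end. It is deliberately minimal — two parameters
per listener group:

* `split_rate` $s \ge 1$: each talker's items are split into
  $k \sim 1 + \text{Poisson}(s - 1)$ sub-clusters (truncated to the item
  count), the simplest one-parameter family on $\{1, 2, \dots\}$; the items
  are then partitioned **uniformly at random** into $k$ non-empty blocks,
  sampled exactly via the Stirling-number recurrence
  $S(n,k) = S(n-1,k-1) + k\,S(n-1,k)$ rather than by rejection (which
  degenerates for $k$ near $n$).
* `merge_prob` $p$: sub-clusters of different talkers are matched one-to-one
  at random ($\min(k_1, k_2)$ pairs for two talkers) and each matched pair
  merges independently with probability $p$ — one pass, no cascades, keeping
  $p$ interpretable and bounding coarsening, since real listeners rarely
  build mega-clusters.

Splitting only lowers telling-together; merging only raises telling-apart
and lowers the cluster count — the two knobs map almost orthogonally onto
the two error types. Vigilance items go into their own cluster unless a
violation is planted.

`simulate_cohort()` additionally conditions non-planted participants on
QC-clean behaviour: if a merge pass happens to produce the all-items
mega-cluster, the response is re-drawn (up to 100 attempts). The anomalous
pattern is reserved for explicitly planted violations, so the ground-truth
ledger is exhaustive and retention accounting is exact — `simulate_response()`
itself is unconditioned, so degenerate presets such as $(s=1, p=1)$ still
produce the mega-cluster deterministically. Planted violations are spread
deterministically across groups (round-robin over the interleaved group
order). All randomness flows through R's seeded generator; a cohort is a
pure function of its config, and replicate studies perturb the seed by the
replicate index.

### Calibration of the default presets

The default presets emulate a four-group cohort (talker × accent
familiarity, sizes 32/29/32/33) whose group-level medians in this design are
approximately 3/4/5.5/5 clusters, telling-together .82/.50/.34/.23 and
telling-apart .01/.16/.11/.16 for THI_AHI/THI_ALO/TLO_AHI/TLO_ALO. Only
medians and the qualitative group ordering are available as targets — no
per-participant distributions — so calibration was run by Monte-Carlo over a
`(split_rate, merge_prob)` grid (≥ 800 draws per cell, 30 test items) and
the defaults frozen at

| group | split_rate | merge_prob | median clusters | median TT | median TA |
|---|---|---|---|---|---|
| THI_AHI | 1.40 | 0.08 | 3 | .76 | .00 |
| THI_ALO | 2.30 | 0.55 | 4 | .51 | .16 |
| TLO_AHI | 3.30 | 0.45 | 5 | .34 | .09 |
| TLO_ALO | 4.60 | 0.85 | 6 | .24 | .16 |

Two compromises are inherent to a two-parameter model and accepted: the
telling-together median near the top of the scale is lumpy (the achievable
medians jump from ~.79 to 1.0 as `split_rate` crosses the point where most
draws keep both talkers whole), and the worst group's cluster-count median
(6) overshoots the target (5) because the split rate needed for
telling-together ≈ .23 produces more sub-clusters than the merges can absorb.
The ordering THI_AHI best / TLO_ALO worst holds on all three measures, and
the telling-together median ordering across all four groups held in 200/200
replicate cohorts at n = 30 per group.

### What passing tests do and do not show

The generator treats items as exchangeable within talker: it reproduces the
partition-level statistics of sorting behaviour but none of the
stimulus-level structure of real data — no acoustic similarity, no
item-specific confusability, no correlation between a listener's split and
merge tendencies, and no heavy-tailed individual differences beyond what the
truncated Poisson provides. Tests that pass on simulated cohorts therefore
validate the *analysis machinery* (scores, QC, tests, aggregation) and the
generator's own calibration, not claims about real listeners.

## Numerical and design choices

* Exact scores: matrix entries are 0/1 integers and score means are exact
  binary-fraction sums, so oracle tests assert identity, not tolerance.
* The exact Mann–Whitney path refuses sample sizes where subset counts would
  exceed the double-precision integer range (`choose(N, n_a) > 2^52`).
* Monte-Carlo suite sizes: type-I calibration uses 2 000 null contrasts at
  n = 30 per group on telling-together (fine-grained, multiples of 1/210, so
  the tie-corrected asymptotic reference applies cleanly; the cluster count
  is heavily tied and intentionally not used there), judged against the
  binomial 99% interval at alpha .0125; the preset-ordering property uses
  200 replicate cohorts; oracle equivalence enumerates all partitions of up
  to 8 items (4 140 at n = 8) and all group reassignments up to
  $n_1 + n_2 = 12$.
* CSV exports fix floats at 6 decimal places so identical seeds produce
  byte-identical bundles.
* Empty groups in a planned contrast are reported and skipped, not silently
  dropped; an all-excluded cohort halts the pipeline after QC with an
  explicit message.

## Limitations

The package analyses partitions, not audio: digitising circled clusters into
item → cluster CSVs is upstream of it, and the CSV dialects are this
package's convention. The generalisation of telling-apart to more than two
talkers and the exclusion-attribution order are package conventions chosen
where the task literature leaves them unstated. Reported W statistics in the
literature may follow either the rank-sum or the U convention and either
exact or asymptotic p-values; voicesort's outputs state theirs, but numerical
comparison with published statistics requires knowing the other side's
convention.
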