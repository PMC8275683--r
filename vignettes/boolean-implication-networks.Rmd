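---
title: "Boolean implication networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean implication networks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implinet)
```

## The model

`implinet` models a disease as a continuum of transcriptional states. The
pipeline has five layers, each with an explicit, testable contract.

### Step-function binarization

Expression is assumed log2-scale and normalized. For each gene the values
are sorted ascending and a one-step function is fitted: over every split
point $k \in \{1, \dots, n-1\}$ the summed squared residuals around the
left and right means are minimized, and the threshold is the midpoint
$t = (\bar{x}_\text{left} + \bar{x}_\text{right})/2$. Ties in the residual
sum break toward the smaller $k$, so the fit is deterministic. The fit is
equivariant under affine transforms ($a x + b \mapsto a t + b$ for
$a > 0$) and invariant to sample order — both are tested properties.

Samples in the closed interval $[t - m, t + m]$ are labeled
*intermediate* (1); below, *low* (0); above, *high* (2). The margin
$m$ models measurement noise around the threshold: samples there carry no
reliable Boolean state and are excluded from pair counting. The default
$m = 0.5$ log2 units follows the cited step-fitting framework's
convention; the source publication does not print its constant, so $m$ is
surfaced as a parameter rather than claimed to match the original run.

Degenerate genes (constant, or with an empty low or high arm) are flagged
`bimodal = FALSE` and excluded from pairwise analysis by the dynamic-range
filter, which requires at least $\max(3, \lceil 0.05\,n \rceil)$ samples
in *each* of the low and high states.

### The sparse-quadrant statistic

For a gene pair, decisive samples fall into a $2 \times 2$ table with
counts $a_{ij}$ (first index: gene A's state; 0 = low, 1 = high). With
row/column margins and total $n$, each quadrant has expectation
$e_{ij} = \text{row}_i \cdot \text{col}_j / n$, statistic

$$S_{ij} = \frac{e_{ij} - a_{ij}}{\sqrt{e_{ij}}}, \qquad
  p_{ij} = \frac{1}{2}\left(\frac{a_{ij}}{\text{row}_i} +
  \frac{a_{ij}}{\text{col}_j}\right),$$

and is *sparse* when $S_{ij} > S_\text{Thr}$ and $p_{ij} < p_\text{Thr}$
(defaults 3 and 0.1, the published operating point). $S$ measures how far
below independence the quadrant sits in units of its Poisson scale; $p$ is
a symmetrized error rate that guards against calling sparsity when the
count is small only because a margin is.

Exactly six sparse patterns are admissible: one sparse quadrant gives the
four asymmetric implications (only $a_{01}$ sparse means "A low ⇒ B low",
etc.), and the two disjoint diagonal pairs give *Equivalent*
($a_{01}, a_{10}$) and *Opposite* ($a_{00}, a_{11}$). Patterns that
contradict a single implication reading — adjacent pairs sharing a row or
column, or three or more sparse quadrants (possible at extreme imbalance)
— are classified `NONE`, since no relation class is defined for them.
Swapping the genes maps each relation to its converse
(`LOW_LOW` ↔ `HIGH_HIGH`; the others self-converse), a property the test
suite checks on $10^4$ random tables.

### Clustering and the cluster network

Genes "sharing at least half of the equivalences" are grouped by a greedy
rule: genes are visited in descending equivalence-degree order (ties by
id), and a gene joins an existing cluster iff it has equivalence edges to
at least 50% of the cluster's current members, preferring the
best-connected cluster, else it seeds a new one. The source describes the
fraction but not the algorithm; this rule was chosen because it is
deterministic, order-stable, and directly testable — whether the original
tool seeds from hubs or cliques is unknown, so the rule is a declared,
configurable substitute. Clusters below 3 members are discarded (they
cannot support path statistics) and survivors are labeled `C1, C2, ...`
by decreasing size.

For every ordered cluster pair, all cross gene-pair relations are tallied;
the majority relation becomes a directed edge iff its support — its share
of *all* cross pairs, missing pairs counting as `NONE` — reaches
`edge_support_min`. The default 0.5 is the weakest faithful reading of an
"overwhelming" between-cluster relationship; ties break by higher mean
implication statistic. Clusters are oriented by comparing the mean
threshold-centered expression ($x - t$, so genes on different scales
contribute comparably) between healthy and disease samples; an exact tie
or a missing class leaves the cluster unassigned.

### Continuum paths and sample scores

Simple directed paths of 2–`max_len` clusters are enumerated
depth-first over edges whose relation is admissible (default: `OPPOSITE`,
`LOW_HIGH`, `HIGH_LOW`, and `EQUIVALENT` only between same-side clusters —
a cross-side equivalence cannot encode progression). Enumeration is
deterministic (lexicographic) and capped at $10^5$ paths with a warning.

Expression is normalized per gene to $(x - t)/s$ ($s$ = SD across
samples, 1 for constant genes), mapping every threshold to 0. A sample's
path score is $\sum_i w_i \cdot \text{mean}_{g \in C_i} \tilde{x}_{gs}$.
The default weights are side-signed $\pm 1$ (healthy +, disease −), so
healthy samples score high; the source describes score-based ordering but
not its weight scheme, so the signed-mean composite is the package's own
minimal choice, and explicit weights can be supplied per path. Scores are
linear in the weights, and zero-weight clusters are no-ops (tested
properties).

Path selection regresses the 0/1 class label on the score by ordinary
least squares — matching the published "linear regression" selection — and
picks the smallest coefficient p-value (ties: larger absolute
coefficient); logistic selection is deliberately not the default.
Signature evaluation reports the rank-based (Mann–Whitney) ROC-AUC with
ties counted ½ and a two-sided Fisher exact test on the confusion table of
the thresholded score (score > 0 predicts the positive class). The Fisher
p-value sums hypergeometric probabilities no greater than the observed
table's (the classical two-sided convention, numerically matched to
`stats::fisher.test` in tests).

### Target vetting and organoid response

A candidate target is `predicted_success` iff (i) it lies on the
epithelial–mesenchymal-transition path, (ii) it lies on the
inflammation–fibrosis path, and (iii) it carries a strong
"anchor high ⇒ target low" implication at the same $S/p$ thresholds. The
published caption offering an "or" reading conflicts with the operative
description of a conjunction; the conjunction is the default and the
disjunctive reading is available via `rule = "disjunctive"`. The symmetric
relations entail the asymmetric readings, so `OPPOSITE` satisfies the
success criterion and `EQUIVALENT`, like `HIGH_HIGH`, contraindicates
antagonism — in a two-class cohort a healthy-anchored target relation
typically *is* symmetric, so restricting to the strictly asymmetric
classes would make the rule vacuous there. Path membership is interpreted
as membership in the path's cluster gene lists (the alternative — a direct
Boolean relation to path genes — is noted as an open reading).

Associations *among* targets use `EQUIVALENT` only: for a set of
same-direction (anti-inflammatory) targets, high/low or opposite
relations would be misleading.

Organoid barrier response is binned by percent TEER increase over
untreated: ≤ 25 nonresponder, (25, 75] responder, > 75 high responder.
The response criterion is strictly "> 25": the prose's "≥ 25%" is
inconsistent with the published per-line values and bin counts, which the
shipped 18-line fixture reproduces exactly (3/7/4 over the 14 diseased
lines).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `margin` | 0.5 | log2 | intermediate zone half-width; unprinted in the source, surfaced in config |
| `SThr` | 3 | SD of quadrant count | published operating point |
| `pThr` | 0.1 | error rate | published operating point |
| `min_frac`, `min_count` | 0.05, 3 | fraction / samples | both Boolean states must be visited |
| `edge_support_min` | 0.5 | fraction of cross pairs | weakest faithful reading of "overwhelming" |
| `min_cluster_size` | 3 | genes | smaller clusters cannot support path statistics |
| `max_len` | 5 | clusters | path enumeration depth; capped at $10^5$ paths |
| `teer_cutoffs` | 25, 75 | % TEER increase | published bins |

## The synthetic world

`generate_cohort()` draws a two-class cohort in which each module gene is
$N(\text{baseline} \pm \delta/2, \sigma)$ with the sign set by class ×
module side, noise genes are $N(\text{baseline}, \sigma)$, and 5% of
module-gene values are nudged into the threshold zone to exercise ternary
handling. Defaults — $n = 200$ samples split 50/50, $\delta = 4\sigma$,
$\sigma = 1$ log2 unit, baseline 8 — are the regime the acceptance
criteria state ($\delta$ and $n$) plus what a bulk-cohort scientist would
call realistic for a strong disease module on a log2 array scale
(two-fold-per-SD noise, mid-range baseline). A `partial` module is
elevated in only a seeded subset of its class, which plants asymmetric
(subset) implications; the generator emits the full truth — memberships,
elevated-sample sets, expected relation per module pair, and the planted
discriminative chain.

What the generator does *not* emulate: probe effects, batch structure,
heavy-tailed noise, correlated noise between modules, dropout. A green
synthetic test therefore establishes algorithmic correctness in a
Gaussian two-component world, not robustness to platform artifacts.

Two stated-world behaviors are worth knowing:

- **Skewed mixtures bias the step threshold.** For a half-penetrant
  module (high in 25% of samples), the SSE-optimal split is pulled toward
  the larger mode, inflating high calls for ~2% of such genes enough to
  break their equivalences ($p_{01}$ crosses $p_\text{Thr}$). Exact
  cluster recovery is therefore asserted only for fully penetrant
  modules; half-penetrant worlds are held to zero *mis*assignment and
  ≥ 0.95 pooled relation sensitivity.
- **Clusters shed noisy genes at moderate effect.** At $\delta = 3\sigma$,
  $n = 100$, a module member occasionally loses half its equivalences and
  drops out; the continuum path is unchanged. Path recovery is therefore
  judged at module resolution: every cluster on the chosen path must be
  pure, and the traversed modules must equal the planted chain.

## Numerical choices

- Step-fit ties break toward the smaller split index; the intermediate
  interval is closed on both ends (no double counting at the boundary).
- A quadrant with an empty row or column margin has no defined statistic:
  $S$ and $p$ are `NA` and the quadrant is never sparse.
- Constant genes normalize to all-zeros ($s := 1$); an exactly separating
  path score reports $p = 0$ (zero residual variance).
- All-pairs counting uses indicator-matrix cross products — exact integer
  counts, no sampling, $O(G^2)$ memory.
- Cohort percentages are rounded to two decimals (the published
  nonresponder share, 21.42%, is a truncation of $3/14 = 21.43\%$).

## Limitations

- Gene-level matrices only; probe collapse and alias resolution are out
  of scope, and identifiers match case-sensitively.
- The clustering rule and path-score weights are declared substitutes for
  unpublished algorithmic details; both are config-exposed.
- The optional FDR machinery for relation calls (permutation nulls) is not
  implemented; fixed $S/p$ thresholds are used throughout, as published.
- External cohort reproduction (GEO/ArrayExpress accessions) requires
  data the package does not download.
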