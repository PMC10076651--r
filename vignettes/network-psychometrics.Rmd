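---
title: "Estimating and probing burnout-depression symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and probing burnout-depression symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`symptomnet` treats each questionnaire item as a node of a Gaussian graphical
model (GGM). An edge between two items is their *partial correlation*: the
association that remains after conditioning on every other item,

$$ w_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}, $$

where $\Theta$ is the precision (inverse covariance) matrix. A zero entry in
$\Theta$ means conditional independence, so the support of $\Theta$ *is* the
network. Because item-level data are far too noisy to estimate all
$p(p-1)/2$ free parameters stably, $\Theta$ is estimated with the graphical
lasso: maximize

$$ \log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j} |\Theta_{ij}| $$

over positive-definite $\Theta$, with the diagonal unpenalized. The L1
penalty sets weak entries to exactly zero, which is what makes reported edge
counts (for example, how many of the 595 possible edges among 35 items
survive) meaningful rather than an artifact of float noise: the solver
propagates exact zeros from the lasso coefficients, and any residual entry
below `zero_tol = 1e-8` is treated as an absent edge.

The penalty is chosen by the extended Bayesian information criterion,

$$ \mathrm{EBIC}_\gamma = -2\,\ell(\Theta) + E \log n + 4\gamma E \log p, $$

with $E$ the number of nonzero edges. The solver walks 100 log-spaced
penalties from $\lambda_{\max}$ (the largest absolute off-diagonal
correlation, where the network is empty) down to $0.01\lambda_{\max}$, warm
starting each fit from the previous one, and keeps the minimizer. The
default $\gamma = 0.5$ is the conventional conservative choice for symptom
networks; $\gamma = 0$ recovers the ordinary BIC and never yields a sparser
model. Convergence of each fit is declared when the largest coefficient
update falls below $10^{-4}$ times the average absolute off-diagonal of $S$.

## Marginals: the nonparanormal transform

Likert responses are ordinal and typically right-skewed, so the Gaussian
assumption is imposed on transformed margins rather than raw codes. Each
column is mapped through its empirical CDF (mid-ranks, so ties stay tied)
and then the standard-normal quantile function. Ranks are winsorized to
$[\delta_n, 1 - \delta_n]$ with

$$ \delta_n = \frac{1}{4 n^{1/4} \sqrt{\pi \log n}}, $$

the shrunken-ECDF bound that keeps the extreme quantiles from exploding,
and each transformed column is rescaled to unit variance. The transform is
monotone and depends only on ranks, hence idempotent; applying it twice
reproduces the same values. Constant columns are rejected by name:
a GGM has nothing to say about an item nobody varies on.

Correlations of the transformed columns are ordinary product-moment
correlations. Polychoric correlations are a defensible alternative for
4-point items, but the rank-based transform feeding Pearson correlations is
the mainstream pipeline for this instrument pair and is what the estimator
expects; a polychoric front end can be substituted by passing your own
correlation matrix to `ebic_glasso()`.

## Redundancy screening

Before estimation, `find_redundant_pairs()` screens for item pairs that are
so interchangeable they would distort the topology (two wordings of one
symptom act as a spurious two-node community). For each candidate pair
(zero-order correlation at least `cor_min = 0.5`), every third item supplies
a test of whether the pair correlates with it differently — Steiger's z for
dependent overlapping correlations, using the back-transformed mean of the
two Fisher z's. If fewer than `threshold = 0.25` of those contrasts are
significant at `alpha = 0.05`, the pair is flagged. Screening runs on raw
responses, matching the usual usage of this screen ahead of any
transformation. Flagged pairs are *reported, not removed*: whether to merge
or drop items is a content decision about the instruments, not something the
statistics alone should decide, so the pipeline default keeps all nodes.

## Node-level indices

* **Expected influence** $EI_i = \sum_{j \ne i} w_{ij}$ — the signed
  one-step impact of a node. Preferred over strength when negative edges
  are present, because cancelling edges should cancel.
* **Bridge expected influence** $BEI_i = \sum_{j:\,g(j) \ne g(i)} w_{ij}$ —
  the part of $EI$ crossing group boundaries. The default grouping is the
  fixed two-construct split (burnout items vs depression items), which is
  the question actually asked of bridge symptoms in comorbidity studies;
  empirical Walktrap communities can be passed instead. The identity
  $EI_i = BEI_i + \text{(within-group sum)}_i$ holds to machine precision
  and is enforced by tests.
* **Predictability** — the $R^2$ of regressing each (transformed) node on
  its estimated neighbours, floored at zero; a node with no neighbours gets
  0. This follows the verbatim definition "variance explained by the
  neighbours". A nodewise mode (`neighbors = "all"`) regressing on all
  other items is available for comparison with mixed-graphical-model
  implementations of the same idea.

Centrality tables carry z-scored $EI$ and $BEI$ (mean 0, SD 1 across
nodes), the scale on which centrality plots are conventionally drawn.

## Community detection

Walktrap agglomerates nodes using short random-walk profiles as distances
(walk length 4, the method's standard default) and cuts the dendrogram at
maximum modularity. Random walks are undefined on signed graphs, so the
walk runs on absolute edge weights; the choice is recorded in the result
(`weights_used = "absolute"`). Isolated nodes become singleton communities
with a warning. On every test graph small enough to enumerate all
partitions exhaustively (up to 8 nodes, Bell number 4140), the selected
partition is required to reach at least 95% of the true modularity optimum.

## Stability and accuracy

Two bootstraps quantify how much of an estimated network to believe:

* **Edge accuracy** — nonparametric resampling of respondents with full
  re-estimation (transform included) per resample; percentile 95% intervals
  per edge. Percentile rather than BCa intervals: the tool convention for
  this workflow, and the regularized point estimates are biased toward zero
  anyway, so the interval is read for width, not coverage. The bootstrapped
  difference test declares two edges (or two nodes' expected influences)
  different when the percentile interval of their pairwise difference
  excludes zero.
* **Case-dropping stability** — for each drop proportion on the grid 0.1,
  …, 0.9, the network is re-estimated on retained subsamples and the subset
  centralities are correlated (Pearson; Spearman behind a flag) with the
  full-sample ones. The CS coefficient is the largest proportion at which
  at least 95% of those correlations stay ≥ 0.70; 0.25 is the conventional
  floor of acceptability and 0.50 the preferred line. Degenerate resamples
  (a constant column) are redrawn and counted, capped at 25 per draw.

Default bootstrap sizes are 2000 for case-dropping and 1000 for edge
intervals. The validation suite runs reduced profiles (nboot 200, and
27-36 for the smallest property checks) on 8- and 35-node synthetic
datasets so the whole suite stays within a desk-scale budget; the CS
behaviour it asserts (strong structure ≥ 0.5, pure noise ≤ 0.25) is scale
free.

## Comparing two groups

The permutation network comparison test re-estimates both groups' networks
from scratch and reports

* $M = \max_{i<j} |w^A_{ij} - w^B_{ij}|$ (network structure),
* $S = |\,GS(A) - GS(B)\,|$ with $GS = \sum_{i<j} |w_{ij}|$ (global
  strength),

against a null built by pooling respondents and permuting group labels at
the original group sizes, re-running the *entire* estimation — including the
nonparanormal transform — inside every permutation so the resampled
statistic sees exactly the pipeline the observed one did. P-values use the
add-one rule $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so they are
never exactly zero. Per-edge invariance tests are two-sided permutation
tests corrected with Holm's step-down procedure. Two implementation
choices worth noting: the pooled rows are put in a canonical sort order and
the permuted subsample always has the smaller group's size, which makes the
null distribution — and therefore every p-value — exactly invariant to which
group is passed first; and the default 1000 permutations follows the
standard convention for this test. Group definitions (gender, an age
split, education, professional title, length of service…) are supplied as a
two-level vector, not hard-coded.

## The synthetic generator

Real item-level data for this instrument pair are rarely deposited, so the
generator plants a known truth and the validation suite measures recovery.
The latent layer is a multivariate normal with precision matrix built from

* five blocks mirroring the construct structure — the three burnout
  subscales (5, 4, 6 items) and two depression clusters (10 + 10 items,
  the negative/positive wording split),
* equicorrelated within-block partial correlations (0.15 in the small
  burnout blocks, 0.09 in the 10-node depression blocks — the strongest
  equicorrelated values a diagonally dominant precision matrix admits once
  bridges are added),
* three weak bridge edges between the constructs with partial correlations
  0.10, 0.07 and 0.07, the magnitude cross-construct edges actually take in
  published burnout-depression networks (D17 with MBI-14, D14 with MBI-13,
  D1 with MBI-7).

Latent draws are discretized at the standard-normal quantiles of per-item
category probabilities: right-skewed defaults (7 categories for MBI-style
items, 4 for SDS-style) matching the low item means these instruments
produce in practice. Reverse-keying is available but off by default in the
generator, since networks are estimated on recorded responses and the SDS
key is applied at scoring time. Positive definiteness is enforced by a
strict diagonal-dominance check with a diagnostic naming the worst node.

What the generator does *not* emulate: heterogeneous edge weights within a
block (real subscales are not equicorrelated), item-specific residual
dependence (method factors, wording effects), demographic covariate shift,
and missing data (the motivating survey designs force complete responses).
Passing recovery tests therefore shows the estimator recovers the kind of
sparse community-plus-bridge topology these instruments produce at realistic
sample sizes — not that any particular empirical dataset would be recovered
edge for edge.

## Instrument scoring conventions

MBI-GS subscale severities use the standard cutoffs (emotional exhaustion
>15 / 11–15 / <11; depersonalization >12 / 8–12 / <8; reduced professional
efficacy >22 / 18–22 / <18, all boundary-inclusive for the middle band).
The SDS standard score is computed as $\lfloor 1.25 \times \text{raw}
\rfloor$ — the unique simple rule consistent with all four published
raw/standard anchor pairs (20→25, 40→50, 48→60, 56→70) — and banded 25–49
normal, 50–59 mild-to-moderate, 60–69 moderate-to-severe, ≥70 severe.
Descriptive cohort tables additionally report exceedances of the reporting
thresholds EE>10, DP>7, RPE>17 and SDS standard >62 / >52; these reporting
thresholds and the severity bands are distinct schemes that cannot be
reconciled into one, so both are exposed and neither silently replaces the
other.

## Validation problem sizes

The shipped test suite validates the pipeline at: 35 nodes × n = 1322 (20
replicates) for edge recovery, community recovery and bridge ranking; 8
nodes × 300 per group × 100 permutations × 200 replicates for the null
calibration of the comparison test; n = 2000 with nboot = 200 for the CS
contrast between planted structure and pure noise; and exhaustive
enumeration up to 8 nodes for the community-detection oracle. These sizes
were chosen so each property is measured with useful precision while the
whole suite runs on a laptop.

## Known limitations

* The GGM is cross-sectional and undirected; nothing here supports causal
  or temporal claims.
* Pearson-on-transformed-margins slightly attenuates associations for
  4-point items relative to polychoric input.
* Walktrap on absolute weights discards sign information in community
  detection (signed community detection is a different problem).
* EBIC with $\gamma = 0.5$ is deliberately conservative: at small n it
  trades sensitivity for specificity, and very weak bridges (|w| ≈ 0.05)
  may be missed. A related consequence, visible in the validation suite: with
  several planted bridges of near-equal weak magnitude (partial correlations
  0.07–0.10), lasso shrinkage compresses their estimated weights enough that
  an occasional false-positive cross-construct edge can displace one of them
  from the very top of the bridge-EI ranking. At n = 1322 the top-ranked BEI
  node is a planted bridge endpoint in essentially every replicate and at
  least two of the top three always are, but all three top slots are bridge
  endpoints in only roughly two-thirds to three-quarters of replicates.
  Exact top-k bridge rankings among near-tied weak bridges should therefore
  be read together with the bootstrapped difference test, not as point facts.
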