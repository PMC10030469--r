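---
title: "Methods: iterative K-Means and Lasso segmentation of couple surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative K-Means and Lasso segmentation of couple surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupleseg)
```

## The problem

Direct-to-beneficiary (D2B) mobile health programmes — outbound voice
calls, WhatsApp messages, video content — reach households whose digital
access and skills vary enormously. A programme evaluated on a whole
study population can hide strong effects in one segment and none in
another. `coupleseg` implements a population-segmentation procedure for
couple-level survey data: it looks for a small number of homogeneous
clusters of husbands and wives, characterised by *strong signals* —
survey indicators that are near-universal in one cluster and rare in
another — and then tabulates a programme's apparent impact separately by
cluster and exposure arm.

Couple surveys of this kind are short on rows and long on columns: a few
thousand couples but, after one-hot encoding, a four-digit number of
mostly binary indicator columns, most of them irrelevant to any cluster
structure. The procedure therefore alternates between unsupervised
clustering and supervised feature selection to find the subspace in
which the clusters are well separated.

## The procedure

1. **Step 1 — initial clustering.** K-Means is run on a predefined
   subset of columns: the men's sociodemographic and phone access/use
   variables. The number of clusters K is chosen by the elbow method on
   the within-cluster sum of squares (WCSS) curve and held fixed
   afterwards. Strong signals are then identified.
2. **Step 2 — feature selection.** Each respondent's *signal strength*
   — the count of strong-signal indicators they possess — becomes the
   target of an L1-regularised (Lasso) linear regression on the full
   merged couples' matrix (health knowledge/practice variables
   excluded). The Lasso's soft-thresholding drives unhelpful
   coefficients exactly to zero; the surviving features are kept.
3. **Step 3 — re-clustering.** K-Means is rerun on the selected
   features, strong signals are re-detected, and steps 2–3 repeat until
   there is no gain in strong signals.

The exposed/not-exposed impact tables are purely descriptive: percent,
numerator count and binomial standard error per (outcome, cluster, arm)
cell, with exposed-minus-unexposed differences per cluster.

### The strong-signal rule

An indicator variable carries a strong signal when some cluster has
prevalence at least `p_min` = 70% **and** that same cluster sits at
least `d_min` = 50 percentage points above some other cluster. Both
thresholds are inclusive. The gap is measured in percentage points, on
the prevalence of the indicator's 1-level, and both conditions are
anchored to the same high-prevalence cluster, which is how the rule's
canonical worked example (men's smartphone ownership of 6%, 88% and 75%
across three clusters, qualifying through the 88% cluster) applies it.
Continuous variables have no prevalence semantics and are excluded from
signal detection. Thresholds are arguments (`p_min`, `d_min`)
everywhere they are used.

### The signal-strength target

The source procedure names "signal strength" as the regression target
without constructing it. We define it as the per-respondent count of
possessed strong-signal indicators — the simplest additive construction
consistent with the name, an integer in `0..S` for `S` current signals.
Because the count is itself a linear combination of candidate columns,
the Lasso recovers those columns (plus whatever else predicts them),
which is exactly the refinement the loop needs: columns that co-vary
with the current cluster-defining set are pulled in, and pure noise is
dropped.

### Stopping and tie-breaking

The loop continues only while the strong-signal count strictly
increases. A tie or decrease, a repeated signal set, an empty Lasso
selection, or the `max_iterations = 20` safety bound stops it. The
returned model is the iteration with the maximal signal count; on ties
we return the *latest* such iteration — the model refined on selected
features — rather than the earlier one, since the procedure's final
model is by construction the re-clustered one. Reruns with the same
master seed reproduce the full trace exactly: every K-Means restart and
CV fold assignment uses a seed derived deterministically from it.

## K-Means and the validity criteria

`kmeans_fit()` is Lloyd's algorithm: assign each observation to the
nearest centroid by squared Euclidean distance (ties to the lowest
cluster index), recompute centroids as cluster means, repeat until no
assignment changes or the centroid shift drops below `tol = 1e-6`, with
`max_iter = 300`. Clusters that empty out are re-seeded from the point
farthest from its assigned centroid. Because random initialisation can
converge to poor local optima, the fit uses `n_init = 10` restarts with
distance-weighted (k-means++-style) seeding by default — uniform-random
seeding is available via `init = "random"` — and keeps the restart with
the lowest inertia. On small instances (n ≤ 10) the test suite checks
the best restart against exhaustive enumeration of all partitions.

Four validity criteria support the choice of K:

* **WCSS / elbow.** `elbow_select()` picks the K maximising the second
  difference w(K−1) − 2w(K) + w(K+1) of the WCSS curve — the sharpest
  bend — and returns the curve for visual confirmation. An exactly flat
  curvature ties toward the smallest K with a warning.
* **Silhouette.** s(i) = (b(i) − a(i)) / max(a(i), b(i)) per point, in
  [−1, 1]; singletons score 0.
* **Calinski-Harabasz.** C(k) = Trace(B)(n − k) / (Trace(W)(k − 1)),
  higher better.
* **Ray-Turi.** Mean within-cluster squared distance to centroid divided
  by the minimum squared distance between two centroids, lower better.
  The criterion is sometimes written loosely as distance(W)/distance(B);
  we implement the published Ray & Turi form stated above, so on the
  6-point toy instance used in the tests (two tight clusters of three
  points) it evaluates to ((8/3)/6) / 200 = 1/450.

## The Lasso

`lasso_fit()` minimises (1/(2n)) Σ(yᵢ − ŷᵢ)² + α Σ|ωᵢ| by cyclic
coordinate descent with soft-thresholding (the inner loop is compiled,
operating on the Gram matrix of the standardised design, with warm
starts along the penalty path). "Error(y, ŷ)" is instantiated as mean
squared error with the 1/(2n) convention, which makes
α_max = max|Xᵀy|/n and the orthonormal-design closed form standard.
Predictors are standardised internally so the penalty treats indicator
and continuous columns evenly; coefficients are reported on the
original scale. `select_alpha()` runs 5-fold cross-validation over a
50-point log-spaced grid from α_max down to α_max/1000. The default
rule takes the α minimising mean held-out error, with exact ties broken
toward the larger (sparser) α; `rule = "1se"` instead takes the largest
α within one standard error of the minimum. The CV-minimum is known to
over-select — on a planted 5-of-100 support at n = 500 it typically
keeps 10–20 noise columns, while the one-SE rule keeps 0–2 — but
over-selection is harmless inside the loop (extra columns carry little
weight in the re-clustering), so the plain minimum remains the default.

## The synthetic couple survey

The study data this package targets are available only on request, so
the generator stands in for them and defines the conditions every test
runs under:

* **Planted clusters.** Three clusters with proportions (0.40, 0.19,
  0.41), echoing the published cluster shares, over 3000 couples by
  default (a desk-scale stand-in for 3484 couples and 1725 encoded
  columns).
* **Signal variables.** Twelve binary phone-access/use indicators (six
  per spouse), Bernoulli given cluster. Every profile satisfies the
  70/50 rule with sampling margin; one of them is the canonical
  (6%, 88%, 75%) smartphone profile. The men's six profiles were chosen
  with two structural constraints: (a) the planted between-cluster
  variance on the men-only step-1 subset (~0.76 per point) exceeds the
  ~0.67 per point that a single uniform 3-level categorical noise
  variable offers a 3-way partition, so the planted structure — not a
  one-hot noise block — is the dominant clustering; and (b) the three
  pairwise centroid separations, weighted by the unequal cluster sizes,
  are comparable, so the WCSS drops from K=1→2 and 2→3 are similar and
  the curve flattens after 3, putting the elbow's second-difference
  maximum at K = 3.
* **Noise.** 150 binary variables with per-variable prevalence drawn
  uniformly from (0.1, 0.9) and 50 categorical variables with 3–5
  uniform levels, all independent of the cluster, split between spouses
  and across sociodemographic/phone/health domains (health-domain noise
  exercises the filtering stage).
* **Missingness** is completely at random at 2% — the mechanism is a
  modelling choice, not an estimate; nothing in the source describes
  its missingness.
* **Outcomes.** Binary outcomes with per-cluster baselines and additive
  exposure effects echoing the published impact table (the middle
  cluster carries the largest planted effect, +8 points on reversible
  contraception), under 50% exposure.

What the generator does **not** emulate: dependence among the signal
variables within a cluster (they are conditionally independent given
the cluster), informative missingness, survey weights, ordinal
structure, and any real-world correlation between sociodemographics and
phone access. Passing tests therefore show the machinery recovers
planted structure of the stated shape and strength — they say nothing
about whether real survey data contain such structure.

## Numerical choices and degenerate inputs

* Encoding: full one-hot for categoricals (no reference level dropped;
  the strong-signal rule needs a column per level), single 0/1 columns
  for binaries, z-scores for continuous columns; zero-variance columns
  removed and logged. Missing values are imputed per column (mode for
  indicators, mean for continuous) by default to keep n stable;
  `missing_policy = "drop_incomplete"` is the alternative.
* Couples are inner-joined: only complete couples are analysed.
* Assignment ties in K-Means go to the lowest cluster index; exact CV
  ties to the sparser model; flat elbow curvature to the smallest K —
  all for determinism.
* Degenerate inputs fail loudly: k exceeding distinct rows, single
  cluster silhouettes, Trace(W) = 0 in Calinski-Harabasz, coincident
  centroids in Ray-Turi, empty strong-signal sets, constant responses
  in the Lasso (which short-circuit to the null model).

## Problem sizes

The packaged checks run the full loop at n = 3000 couples with ~300
encoded columns across ten seeds, K-Means-versus-enumeration
comparisons at n ≤ 10, Lasso recovery at n = 500 with 100 features, and
impact-table recovery at n = 15000 — sizes chosen so the whole suite
completes in minutes on one core while keeping sampling error well
inside the asserted tolerances.

## Known limitations

* K is fixed after step 1 (re-election each iteration is available via
  the `k` argument of each call but is not the default), mirroring the
  source procedure's reuse of K = 3.
* Signal detection is restricted to indicator columns.
* The impact tables are descriptive; no significance testing or causal
  adjustment is attempted, and arms are compared as observed.
* Silhouette computation materialises the full distance matrix, which
  is fine at survey scale (thousands of rows) but not beyond.
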