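---
title: "Methods: estimating comorbidity networks from ICD-10 records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating comorbidity networks from ICD-10 records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The model

`comorbnet` treats a cross-section of diagnosis records as draws from a
pairwise binary Markov random field (an Ising model) over diseases. With
`x_i` the 0/1 indicator that a patient carries disease `i`, the model is
fully specified by a symmetric weight matrix `w` (zero diagonal) and node
thresholds `b` through the conditional

\[
P(x_i = 1 \mid x_{-i}) =
  \mathrm{logistic}\Big(b_i + \sum_{j \ne i} w_{ij} x_j\Big).
\]

`w_ij > 0` means diseases `i` and `j` co-occur more often than the rest of
the network explains (a comorbidity signal); `w_ij < 0`, less often. The
thresholds absorb baseline prevalence, so edges are conditional
associations, not marginal correlations.

Estimation is by eLasso: each node's conditional is a logistic regression
of its column on all other columns, penalized by an l1 term on the slopes
(the intercept is unpenalized, and binary predictors are not standardized —
they already share the 0/1 scale). Each node is fit along a regularization
path of 100 log-spaced penalties from \(\lambda_{\max}\) (the smallest
penalty that zeroes every slope) down to \(0.01\,\lambda_{\max}\), and the
path point minimizing the extended BIC,

\[
\mathrm{EBIC} = -2\ell + \mathrm{df}\,\log n + 2\gamma\,\mathrm{df}\,\log(p-1),
\]

is selected, with `df` the number of nonzero slopes and `gamma = 0.25` by
default. Setting `gamma = 0` recovers the ordinary BIC. The two directed
coefficients of a pair are then symmetrized: under the default AND rule an
edge exists only if both regressions selected it (weight = mean of the two
coefficients); under OR, if either did. AND is the sparser, more
conservative convention and the default of the estimator this package
follows; every AND edge is by construction also an OR edge.

The penalized path itself is computed by `glmnet`; the path construction,
EBIC evaluation, selection and symmetrization are this package's code, and
the test suite checks the penalized objective at the returned coefficients
against an independently written coordinate-descent optimizer.

Two numerical details matter. Coefficients returned exactly at the path
boundary can be numerical dust (~1e-16); anything below 1e-7 in absolute
value is treated as zero before support counting, which protects the
AND/OR rules and the EBIC's `df`. A column with fewer than two
observations in either class cannot be regressed and is returned
degenerate: all-zero slopes and an intercept at the Haldane-corrected
empirical log-odds.

## The ETL stage

Raw visit records (patient id, sex, age, raw ICD-10 string) pass through a
fixed cascade, each stage logged in an exclusion report
(`stage, n_in, n_out, n_dropped` with `n_out = n_in - n_dropped` always):

1. **age** — keep ages in [60, 99] (the study window of the motivating
   population);
2. **invalid_code** — keep codes matching the ICD-10 shape
   (`A01`, `A01.001`) or the lowercase merged-code shape (`ii2520`);
   garbled strings drop here;
3. **duplicate** — one record per (patient, code) pair, first occurrence
   kept;
4. **recode_merge** — raw codes are mapped to merged disease categories by
   exact or prefix match (longest prefix wins; overlapping rule sources are
   rejected at load time), and records re-deduplicated, so a patient with
   two source codes of one merged disease contributes one record;
5. **non_chronic** — codes outside the chronic allowlist drop;
6. **low_prevalence** — diseases carried by fewer than `min_prevalence`
   (default 1%) of patients drop; prevalence is computed once, on the
   post-recoding population, not iteratively re-evaluated after each drop;
7. **single_disease** — patients left with one disease carry no
   co-occurrence information and drop.

The single-disease exclusion runs on the full recoded disease set, before
restriction to the analysis panel; rows that become single-positive within
the panel are kept, since the matrix reflects panel restriction only. The
panel itself is built the way the motivating study describes: take the
`n_top = 5` most prevalent diseases, rank all others by comorbidity rate
with each — defined here as the conditional prevalence
P(other | index) = co-occurring patients / index-disease patients, with
Jaccard available as an alternative — keep the `n_comorbid = 40` best per
index disease, and union. Ties anywhere break lexicographically by code,
so the pipeline is deterministic. The shipped `panel38.yaml` carries the
38 merged codes of the motivating study; its source-code sets beyond the
two documented examples are reconstructed from the merged-code names and
are configuration, not data.

Two ambiguities in the source description are resolved as switches: the
1% prevalence denominator is distinct patients by default (records
optionally), and the per-sex subsample of 150,000 draws matrix rows
(patients), uniformly without replacement under one named seed
(default 20230601).

## Centrality conventions

Strength is \(\sum_j |w_{ij}|\). Absolute values are used for all three
indices: published strength values are nonnegative even for nodes whose
only associations are negative, and path lengths must be positive. For
closeness and betweenness an edge of weight `w` has length `1/|w|` — a
stronger association is a shorter distance; a zero weight is no edge, not
a zero-length one. Closeness is the unnormalized `1/sum(d(i,j))` over
reachable nodes only (consistent with the 0.004–0.008 range published at
38 nodes; the normalized form would be two orders larger), and an isolated
node has no closeness (printed `-`). Betweenness uses Brandes-style
accumulation with fractional splitting of tied geodesics and endpoints
excluded, and is reported both raw and rounded to integer as published.
The shortest-path machinery is igraph's; the tests compare every index
against brute-force Dijkstra and exhaustive geodesic enumeration on small
graphs.

## Community detection

Clustering targets comorbidity patterns, i.e. positive associations, and
the modularity null model is undefined for negative strengths, so negative
edges are dropped (and counted) before clustering. Modularity is evaluated
exactly as

\[
Q = \frac{1}{2m} \sum_{i,j}
  \Big(A_{ij} - \gamma \frac{k_i k_j}{2m}\Big) \delta(c_i, c_j),
\]

with `m` the total edge weight, `k_i` the node strengths and resolution
`gamma = 1` by default; an edgeless graph has `Q = 0` by convention. The
fast-greedy agglomeration starts from singletons and repeatedly merges the
community pair with the largest modularity gain
\(\Delta Q = 2(e_{uv} - \gamma a_u a_v)\), recording the full merge
history. Ties take the lexicographically lowest community-id pair, making
the result deterministic. The returned partition is the cut at the maximum
of Q along the merge path, at its earliest occurrence on ties — so
zero-gain merges (e.g. absorbing an isolated node) are not taken and
isolated nodes end as singletons. This implementation is the package's own
because the published formula carries a resolution parameter and the
algorithm needs specified tie-breaking; igraph's fast-greedy and
modularity routines serve as independent cross-checks in the tests, and on
graphs of up to 8 nodes the greedy result is verified against exhaustive
search over all partitions (greedy Q never exceeds the optimum, and
attains it on the planted fixtures).

## The synthetic-data generator

Real registry data for this problem is access-restricted, so validation
runs on synthetic data with known ground truth, in two forms.

**Ising samples.** `make_planted_network()` builds block ground truths
(k near-equal blocks, within-block weight `w_in` at configurable density,
default 1 so the planted structure is unambiguous; between-block weight
`w_out`; common threshold `b`). `gibbs_sample()` draws binary rows by
systematic-scan Gibbs sampling from the model's exact conditional. The
default layout runs n independent chains — one per output row, burn-in 500
full sweeps each — so rows are independent draws; this vectorizes across
rows and is the variant used throughout. A literal single-chain mode with
thinning (default 10) is retained for when a Markov trace is wanted. The
sampler is validated against exact enumeration of all 2^p configurations
at small p (total-variation distance below 0.02 at n = 50,000).

**Raw record files.** `make_record_file()` emits claims-like CSVs: a core
cohort of multi-disease patients (disease sets drawn from configured
prevalences, at least two diseases each), with injected duplicates,
garbled codes, valid-but-non-chronic codes, out-of-range-age patients,
single-disease patients, rare diseases below the prevalence cutoff, and
"recode twins" (a second raw source code of a merged disease already
held). Every injection is counted in a ledger, and the injections are
constructed not to interact (duplicates copy valid core rows; rare
diseases are hosted only on patients with two or more core diseases, so
the prevalence filter cannot cascade into new single-disease patients) —
which is what makes exact ledger/report agreement a meaningful test. Age
bands default to the motivating population's distribution
(47.28 / 33.99 / 14.37 / 4.36 percent across 60–69 … 90–99) and the sex
mix to 45.9% male; within bands, ages are uniform. The generator emulates
marginal structure only: real claims data have visit dates, coding drift,
age-dependent prevalence and richer dependence than a pairwise Ising
model, so passing tests demonstrate correctness of the pipeline's logic,
not calibration to any real registry.

## Problem sizes, defaults and degenerate cases

Routine tests use cohorts of 80–400 synthetic patients, networks of 2–38
nodes, and Gibbs samples of 4,000–50,000 rows; estimator-recovery checks
average over 10 seeds at n = 10,000. These sizes were chosen so each check
is sharp (binomial tolerances of a few sigma, exact enumeration where
feasible) while the full suite stays comfortably interactive.

One planted configuration deserves a caveat recorded here deliberately: a
38-node, 6-block network with complete blocks, `w_in = 1.5` and `b = -1`
is a *saturated* Ising model — exact enumeration puts 99.1% of a 6-clique's
mass on the all-ones configuration, so sampled columns are near-constant
(marginal activation 0.9985) and no estimator can recover edges from such
samples (measured edge-set F1 is about 0.02). The acceptance checks run
this configuration as specified and report the measured value honestly;
the same estimator recovers non-saturated planted structure (two triangles
at `b = 0`, marginal ≈ 0.90) exactly in 10 of 10 seeds. The general rule:
with complete blocks of size s, thresholds near `-w_in (s-1)/2` keep
activation balanced and the recovery problem informative, which is how the
property-style tests (recovery monotone in n, community recovery with
adjusted Rand ≥ 0.9) choose their fixtures.

Other deliberate conventions: percentages print with half-away-from-zero
rounding to two decimals (matching the published tables' arithmetic on
every derivable cell but one, where the source table itself slips by
0.01); all RNG flows from named seeds and the pipeline's outputs are
byte-identical on reruns; and one estimator-argument note — the motivating
study cites its estimator with an "α = 0.05" argument that the estimator
does not have, so the package exposes only the EBIC hyperparameter `gamma`
(default 0.25) and documents the discrepancy rather than guessing at it.

## Limitations

No covariate adjustment (the design stratifies by sex instead), no edge
stability or bootstrap intervals, no signed-community detection, no
ICD-9 mapping, and no figure rendering — networks and partitions export as
edge-list TSV and GraphML for downstream tools.
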