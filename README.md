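# comorbnet

Comorbidity network analysis of ICD-10 medical records in R.

Multimorbidity — several chronic conditions in the same patient — is the
norm rather than the exception in ageing populations, and which diseases
travel together is a question registries can answer at scale. `comorbnet`
turns raw diagnosis records (one row per visit: patient id, sex, age,
ICD-10 code) into a weighted disease network and its community structure,
for epidemiologists and health-services researchers working with claims or
registry extracts. Because such registries are typically access-restricted,
the package also ships a first-class synthetic-data module, so the whole
pipeline is testable end to end without the real data.

## What it computes

**ETL.** Records are validated against ICD-10 coding rules
(letter + two digits, optional decimal subcode), repeat visits for the same
disease are collapsed to one patient–disease record, related codes are
merged into recoded disease categories (e.g. I25 chronic ischaemic heart
disease + I20 angina → `ii2520`), and non-chronic, low-prevalence
(< 1% by default) and single-disease records are excluded — with the record
count logged at every stage in a machine-readable exclusion report. The
result is a binary patient × disease matrix, stratified by sex.

**Network estimation (eLasso).** Diseases are nodes of a pairwise binary
Markov random field (Ising model) in which the conditional probability of
carrying disease *i* given all others is

P(x_i = 1 | x_−i) = logistic(b_i + Σ_{j≠i} w_ij x_j).

Each node's conditional is fit by l1-regularized logistic regression over a
log-spaced penalty path, the penalty is selected per node by the extended
BIC, EBIC = −2ℓ + df·log n + 2γ·df·log(p−1) with γ = 0.25, and the two
directed coefficients of each pair are combined by the AND rule (mean if
both nonzero, else no edge). A positive weight w_ij means the two diseases
co-occur more often than the rest of the network explains — a comorbidity
signal; a negative weight, less often.

**Centrality.** Strength (Σ|w_ij|), closeness (inverse total shortest-path
distance with edge lengths 1/|w|, unnormalized) and betweenness (fractional
geodesic counting, endpoints excluded) per disease and sex stratum.

**Communities.** Fast-greedy agglomerative maximization of modularity
Q = 1/(2m) Σ_ij (A_ij − γ k_i k_j / 2m) δ(c_i, c_j) on the positive
subgraph, with a resolution parameter γ, deterministic tie-breaking, the
full merge dendrogram, and the partition cut at maximum Q.

**Synthetic data.** Planted block Ising networks, a systematic-scan Gibbs
sampler checked against exact 2^p enumeration, and messy raw record files
(duplicates, garbled codes, non-chronic codes, out-of-range ages,
single-disease patients) with an exact injection ledger.

## Worked example

Estimate a network from a known ground truth and recover its communities:

```r
library(comorbnet)

gt  <- make_planted_network(6, 2, w_in = 1.5, w_out = 0, b = 0)
m   <- gibbs_sample(gt, n = 10000, seed = 1)
net <- fit_ising(m, gamma = 0.25, rule = "AND")
net
#> Ising network: 6 nodes, 6 edges (AND rule, EBIC gamma=0.25, n=10000)
edge_list(net)
#>   from  to   weight
#> 1  d01 d02 1.277491
#> 2  d01 d03 1.487486
#> 3  d02 d03 1.304213
#> 4  d04 d05 1.462024
#> 5  d04 d06 1.475968
#> 6  d05 d06 1.360645
```

All six planted edges (true weight 1.5) are recovered with no false
positives. Communities and the merge dendrogram:

```r
part <- fast_greedy(positive_subgraph(net))
part
#> community partition: 2 communities, Q = 0.4996 (gamma = 1)
merge_newick(part)
#> (((d01,d03),d02),((d04,d06),d05));
```

The two planted triangles come back exactly; Q ≈ 0.5 is the exact
modularity of two disconnected equal triangles. Descriptive tables work
directly from published aggregate counts — here the top-five diseases of
the Shanghai 60–99 study population (3,779,756 processed records):

```r
top10 <- read.delim(system.file("extdata", "top10_visits.tsv", package = "comorbnet"))
prevalence_table(top10, top_k = 5, n_total = 3779756)
#>                            disease   total   pct    male  female
#> 1                     Hypertension 2448548 64.78 1142288 1306260
#> 2  Chronic ischaemic heart disease 1476396 39.06  637315  839081
#> 3         Type 2 diabetes mellitus  943812 24.97  465184  478628
#> 4 Lipoprotein metabolism disorders  823572 21.79  329847  493725
#> 5                        Gastritis  744880 19.71  311084  433796
```

64.78% of processed records are hypertension, and male + female counts add
to the totals on every row. For raw record files, `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell) chains everything — ETL,
per-sex sampling, estimation, centrality, communities — and writes the
TSV/GraphML bundle plus exclusion report, run log and JSON manifest.

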