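# acupairs

Association mining between traditional Korean-medicine **diagnosis patterns**
and the **acupoints** prescribed for them.

In pattern-identification practice, a clinician synthesizes a patient's signs
and symptoms into a named diagnosis pattern (coded with the ICD-10
Korean-medicine extension codes U20–U99, or an R symptom code) and prescribes
a small combination of acupoints — typically three to five points drawn from
the 361 WHO-standard points on the 14 meridians. Given a table of such
prescription records, two complementary questions arise:

* **Which acupoints are used everywhere?** Answered with a diagnosis–acupoint
  co-occurrence network and eigenvector centrality: points such as ST36 or
  LI4 that co-occur with many patterns sit at the centre of the network.
* **Which acupoints are specific to one pattern?** Answered with tf-idf
  weighting (acupoints as *terms*, diagnosis patterns as *documents*) and a
  marginal-preserving permutation test of the resulting weights.

`acupairs` implements the full pipeline: controlled-vocabulary normalization
of free-text terms, a seeded generator of virtual-diagnosis cohorts for
validation studies, preprocessing into diagnosis–acupoint pair instances,
the thresholded bipartite network with eigenvector centrality, L2-normalized
tf-idf association weights, and the permutation significance test.

## The statistics

Let `n(d, a)` be the number of pair instances of diagnosis `d` with acupoint
`a` (one instance per record × point). Then:

* **Network.** Directed edges `d → a` with weight `n(d, a)` are kept when
  `n(d, a) > 10` (strict, configurable). Eigenvector centrality is the
  Perron eigenvector of the symmetrized weighted adjacency matrix, computed
  by power iteration and scaled so the maximal node scores 1.
* **tf-idf.** With `N` documents and `df_a` the number of documents
  containing `a`,
  `w(d, a) = n(d, a) · ln(N / df_a)`, followed by L2 normalization of each
  document row: `w(d, ·) ← w(d, ·) / ‖w(d, ·)‖₂`. Associations are reported
  when `w > 0.1`. An acupoint present under every pattern has `idf = 0` and
  drops out — exactly the behaviour wanted for ubiquitous points.
* **Permutation test.** The acupoint column of the pair list is randomly
  permuted against the fixed diagnosis column (both marginal frequency
  vectors are preserved exactly), tf-idf is recomputed after each of `B =
  10,000` permutations, and each cell's one-sided p-value is the add-one
  estimator `p = (1 + #\{w_perm ≥ w_obs\}) / (1 + B)`.

## Worked example

The study's raw records are not public, so the example runs on a seeded
virtual cohort with the same design (80 doctors × 10 cases, 3–5 points per
prescription):

```r
library(acupairs)

records <- generate_cohort(cohort_config(seed = 1))
cleaned <- clean_records(degrade_to_raw_text(records, noise_rate = 0, seed = 1))
cleaned$report
#> Cleaning report:
#>   records in/kept/dropped: 800 / 800 / 0
#>   points dropped: none
#>   pair instances: 3178  unique pairs: 155

pairs <- extract_pairs(cleaned$records)
mat   <- build_matrix(pairs)
frequency_table(mat, top_k = 3)[1:3, ]
#>   diagnosis row_total  rank acupoint count percent
#> 1 R10             148     1 GB30        30    20.3
#> 2 R10             148     2 GB34        26    17.6
#> 3 R10             148     3 ST36        19    12.8
```

`percent` is the share of the diagnosis's pair instances carried by the
point (rounded half-up to one decimal): pelvic pain (R10) was prescribed
GB30 in 20.3% of its pairs. The network view shows the shared points — the
six common-pool points top the acupoint centrality ranking:

```r
net  <- build_network(mat, min_cooccurrence = 10)
cent <- eigenvector_centrality(net)
round(head(sort(cent[!grepl("^[UR][0-9]", names(cent))], decreasing = TRUE), 6), 3)
#>  LR3  ST36  LI4  CV12  PC6  SP6
#> 0.535 0.507 0.506 0.502 0.497 0.483
```

while the permutation test isolates the pattern-specific points (at `B =
10,000` the smallest attainable p-value is `1/10001 ≈ 1e-4`):

```r
perm <- null_distribution(pairs, n_perm = 10000, seed = 1)
significant_associations(perm)[1:3, ]
#>   diagnosis acupoint weight p_value
#> 1 R10       GB30      0.756  0.0001
#> 2 U63       ST40      0.804  0.0001
#> 3 U60       CV6       0.700  0.0001
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages and writes the
full report bundle (cleaning report, pair list, frequency tables,
Gephi-compatible GEXF network with centrality, tf-idf heatmap CSV,
association and p-value tables, run metadata). A subcommand CLI wrapper
lives at `inst/cli/acupairs.R`.

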