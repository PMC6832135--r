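---
title: "Mining diagnosis-pattern / acupoint associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining diagnosis-pattern / acupoint associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acupairs)
```

# The problem and the data model

A prescription record pairs one clinician's diagnosis of one case — a
pattern-identification code from the ICD-10 Korean-medicine extension block
(U20–U99) or an ICD-10 symptom code (R00–R99) — with a *set* of three to
five distinct acupoints from the 361 WHO-standard points on the 14
meridians. The atomic unit of all downstream statistics is the **pair
instance**: one (diagnosis, acupoint) occurrence from one record. A cohort
of `n_doctors × n_cases` records therefore yields roughly 3–5× as many pair
instances, summarized in a diagnosis × acupoint contingency matrix
`n(d, a)`.

Two complementary summaries are computed from that matrix:

* a thresholded bipartite **co-occurrence network** with eigenvector
  centrality, which surfaces the acupoints shared across many patterns, and
* **tf-idf association weights** with a **permutation test**, which surface
  the acupoints specific to single patterns.

# Vocabulary normalization

Raw survey data are free text. The registry module fixes the two controlled
vocabularies and maps raw terms onto them:

* Acupoints: meridian prefix + point number, validated against each
  meridian's maximum (LU 11, LI 20, ST 45, SP 21, HT 9, SI 19, BL 67, KI
  27, PC 9, TE 23, GB 44, LR 14, CV 24, GV 28; 361 codes in total). The
  `SJ` alias for the TE (San Jiao) meridian is accepted on input and
  rewritten to the WHO-standard `TE`, since Korean sources use both.
* Diagnoses: `U20`–`U99` (pattern codes) and `R00`–`R99` (symptom codes).

Anything else — auricular points, anatomical trigger points, Ashi points,
unmapped free text — is *rejected with a reason tag* rather than raising an
error, so preprocessing can count and log every drop; the cleaning report
makes data loss auditable. Synonym tables are user-supplied CSV
(`raw_term,code,kind`); the package ships a small demonstration lexicon,
not a complete Korean one, because real-world coding of free-text
diagnoses is an adjudicated human task that a lookup table only
approximates. Within-record duplicate points are collapsed by default (a
prescription is a set; double-counting would inflate tf), with a flag to
keep multiplicities.

# The synthetic cohort generator

The study data this package is designed around are not deposited, so the
generator produces seeded virtual cohorts with the same design and
first-order statistical structure:

* **80 doctors × 10 cases** by default, one record per (doctor, case), 3–5
  distinct points per record.
* **Per-case diagnosis profiles**: each case has a modal diagnosis whose
  probability matches the per-case modal prevalences reported for this
  study design (0.199–0.406), with four alternative diagnoses splitting the
  remainder 4:3:2:1. This yields 19 distinct diagnosis codes overall.
* **Per-diagnosis acupoint profiles**: a common pool {ST36, LI4, LR3, SP6,
  CV12, PC6} carries `common_weight = 0.5` of the probability mass (split
  equally, 1/12 per point); the rest goes to pattern-specific points (e.g.
  ST35 and SP10 for blood disorder U61, CV17 and GV20 for liver excess U65,
  ST40 for the fluid-and-humour pattern U63, KI3/KI7/BL23/BL31/BL32/LU8 for
  kidney disease U71). Most patterns have two specific points at weight
  0.25 each — three times the per-point common weight — so the planted
  signal is recoverable; the kidney pattern deliberately spreads its mass
  over six specific points at common-pool weight, emulating a diffuse
  multi-point pattern that frequency ranking alone should *not* be expected
  to recover.
* Points are drawn **without replacement** with probability proportional to
  profile weight (sequential renormalized draws), so records are true sets.

A degradation step re-expresses coded records as free-text-style rows
(synonym substitution at a configurable rate, plus optional injection of
off-meridian terms) so that the normalization and filtering path can be
exercised and round-tripped.

What the generator does *not* emulate: doctor-level effects (experience,
style), correlation between a doctor's answers across cases, multi-pattern
diagnoses (available behind a `multi_pattern` flag, off by default), and
free-text narrative noise beyond exact synonym substitution. Passing the
suite therefore demonstrates correctness of the statistical machinery on
data with planted known structure — not robustness to every artefact of
real survey text.

# Network analysis

Edges run from diagnosis to acupoint with weight `n(d, a)` and are kept
when the count **strictly exceeds** `min_cooccurrence = 10` (the
conventional cut for this analysis; an inclusive mode is available).
Isolated nodes are removed. Raw counts are used as weights because no
better-defined correlation measure is available for this design.

**Eigenvector centrality** is computed on the symmetrized graph: in the
directed graph acupoints have zero out-degree, so directed eigenvector
centrality is degenerate; treating edges as undirected is the only reading
under which both node types receive meaningful scores. Numerically:

* Bipartite adjacency spectra are symmetric about zero, so plain power
  iteration on `A` oscillates. The package iterates on `A / max(A) + I`,
  which has the same eigenvectors, a strictly dominant Perron eigenvalue,
  and is invariant to uniform weight scaling.
* The stopping rule bounds the *estimated distance to the limit*: with
  successive step sizes contracting at observed ratio `r`, iteration stops
  when `δ · r / (1 − r) < 10⁻¹⁰` (at most 10,000 iterations). A raw
  step-size criterion can stop an order of magnitude short of the limit on
  slowly converging graphs; the contraction-based estimate keeps scores
  within 10⁻⁸ of a dense eigen-decomposition on every graph the suite
  generates.
* On a disconnected network the Perron vector is computed per connected
  component; each component's vector is weighted by the ratio of its
  spectral radius to the largest one, and the whole score vector is then
  divided by its maximum. Satellite components (a pattern whose common-pool
  edges fall below the threshold while its specific points cross it) are
  thus down-weighted rather than artificially tied with the global hubs at
  1.0 (per-component max-normalization) or zeroed (the dominant dense
  eigenvector). The maximum score is 1 whenever the network has an edge.

Exports are GEXF (written directly; the Gephi exchange format) and GraphML
(via igraph), both carrying node type, centrality and edge weight, and both
re-importable losslessly.

# tf-idf association weights

Acupoints are terms, diagnosis patterns are documents, `tf` is the raw pair
count. The default idf is the classic `ln(N / df)`; `df = N` annihilates a
term, which is the desired treatment of ubiquitous points. Because each
document row is subsequently L2-normalized, the `log10` variant is exactly
equivalent to the classic one; the `smoothed` variant `ln(N / df) + 1`
keeps ubiquitous terms at positive weight and therefore changes which
associations survive the reporting threshold — the variant is recorded in
all output metadata. "Normalized by document length" is implemented as
division of each document's weight vector by its Euclidean norm; all-zero
rows are left untouched. Associations are reported when the weight
strictly exceeds 0.1 (configurable), sorted by weight with ties broken by
canonical code order (meridian alphabetical, then point number — the
ordering used everywhere in the package).

# Permutation significance

The null hypothesis is exchangeability of acupoint labels across pair
instances. Each permutation draws a uniform random permutation of the
acupoint column against the fixed diagnosis column, which preserves both
marginal frequency vectors *exactly*; the contingency matrix and tf-idf
weights are recomputed and per-cell exceedance counters updated in a
streaming fashion (memory is independent of `B`). Choices that matter:

* **Cell-specific null**: each observed weight is compared against that
  same cell's permuted weights (a pooled-null mode exists for sensitivity
  analysis).
* **One-sided, upper tail**: specificity claims concern unusually *high*
  weights.
* **Add-one estimator** `p = (1 + exceed) / (1 + B)`, bounded below by
  `1/(1+B)`, with ties counted as exceedances; this never reports p = 0 and
  is conservative by construction.
* **Determinism**: results are a function of the pair multiset, the seed
  and `B` only — instances are canonically sorted before shuffling, so the
  input row order cannot change p-values. R's Mersenne-Twister generator is
  fixed for the draws.
* `alpha = 0.05` by default; no multiplicity correction by default (the
  analysis is descriptive), with Benjamini–Hochberg available.

**Calibration and its limits.** The suite checks type-I error on null
cohorts in which every diagnosis shares one near-uniform 60-point acupoint
distribution spread over 40 diagnosis codes. That sparse regime is chosen
deliberately: the per-cell permutation distribution is then essentially
atomless away from zero, where the empirical rejection rate at
`alpha = 0.05` is measured to be close to 0.05. In dense regimes
calibration is impossible to assess this way — when every point reaches
every document, classic idf collapses all weights to zero and every
p-value is 1 by construction. Two further sources of conservatism are
inherent to the method as specified: the tie-counting add-one estimator,
and the fact that prescriptions are *sets* — records hold distinct points,
while the permuted column can stack duplicates inside a record, making the
null slightly over-dispersed relative to the observed statistic. The
calibration study in the acceptance suite is sensitive enough to detect
this small conservative bias; exact exchangeability (and with it exact
calibration) is restored by the record-level permutation mode
(`unit = "record"`), which reassigns diagnosis labels among whole records
and never splits a prescription.

* **Pair-level vs record-level**: pair-level shuffling is the default
  because it is the literal reading of the method; record-level
  reassignment is provided as the documented alternative with the exact
  exchangeability property above.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_cooccurrence` | 10 (strict `>`) | network edge threshold, in pair counts |
| `tfidf_threshold` | 0.1 (strict `>`) | association reporting cut, on L2-normalized weights |
| `idf_variant` | `classic` (`ln(N/df)`) | idf flavour; `smoothed` keeps ubiquitous terms |
| `n_perm` | 10,000 | permutations; smallest attainable p is `1/(1+B)` |
| `alpha` | 0.05 | significance level (not stated by convention sources; configurable) |
| `correction` | none | multiplicity handling; BH available |
| `common_weight` | 0.5 | generator: probability mass on the common pool |
| `points_min..points_max` | 3..5 | generator: points per prescription |

# Problem sizes used by the test suite

The suite validates the statistical properties at sizes chosen to give
stable Monte-Carlo estimates: the calibration study uses 30 replicate null
cohorts of 800 records at `B = 500` with the rejection fraction compared to
`alpha` within three empirical standard errors across cohorts; the
recovery study uses 50 default cohorts at `B = 1000`, requiring the
elevated planted associations to be flagged and the common pool to top the
acupoint centrality ranks in at least 90% of cohorts; the centrality oracle
compares power iteration against dense eigen-decomposition on 100 random
bipartite graphs of up to 50 nodes at 10⁻⁸.

# Known limitations

* Synonym lookup is exact (case-insensitive); there is no spelling
  correction or fuzzy matching, and the shipped lexicon is a small
  demonstration table.
* The co-occurrence edge weight is the raw count; no association measure
  corrects for diagnosis prevalence in the network view (that is precisely
  the role of the tf-idf branch).
* Eigenvector centrality scores across disconnected components depend on
  the spectral-radius weighting convention described above; component
  structure should be inspected before comparing scores across components.
* The pair-level permutation null is mildly conservative for set-valued
  prescriptions (see above); use `unit = "record"` when exact calibration
  matters more than the literal pair-shuffling definition.
* One diagnosis per record by default; the `multi_pattern` flag emulates
  doctors reporting two patterns for a case but no claim is made about the
  realism of its frequency parameter.
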