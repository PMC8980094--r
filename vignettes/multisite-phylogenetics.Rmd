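---
title: "Multi-site tumor phylogenetics, SCNA integration and pathway prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site tumor phylogenetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncophylo)
```

This vignette documents the models and procedures implemented by
**oncophylo**, the assumptions behind them, the tunable parameters with
their defaults and units, what the synthetic cohort generator does and does
not emulate, and the design decisions taken where the methodology was
genuinely open.

## 1. Relatedness of multi-site tumors

### Binary matrix and trunk/branch/private classification

Per patient, the detected somatic mutations of all sampled tumor sites are
collected into a binary matrix: rows are the union of canonical variant keys
(`chrom:pos:ref:alt`), columns are sites, and an entry is 1 iff the mutation
was detected in that site. A mutation enters the union only if it is
detected in at least one site, so no row is all-zero. The category of a
mutation is a pure function of its row:

* **trunk** — present in every site;
* **branch** — present in more than one but not all sites;
* **private** — present in exactly one site.

The per-patient *trunk fraction* is the proportion of trunk rows. The
cohort summary reports both the mean of per-patient fractions (the headline
quantity) and the pooled fraction over all mutations; the two differ when
mutation counts vary across patients.

### Variant quality control

Calls are filtered to high-quality somatic variants with tumor depth ≥ 30,
matched-normal depth ≥ 15, tumor VAF ≥ 0.05 and normal VAF ≤ 0.01, all
bounds inclusive (`qc_thresholds()`). A normal sample with zero depth
contributes normal VAF 0 — there is no normal evidence of the allele.
Driver candidates additionally require population MAF strictly below 0.01
in *both* ESP6500 and 1000 Genomes (a missing MAF is treated as 0: a
variant absent from the databases is novel), a non-silent consequence
(nonsynonymous, stopgain, stoploss, splicing) and membership in a
cancer-gene list. Indels and SNVs share one filter set. The filter is
idempotent and monotone in its thresholds, and the driver set is nested in
the non-silent set, which is nested in the high-quality set; all three
properties are tested.

### Deep-coverage rescue

WES at a few hundredfold coverage misses low-VAF presences, which inflates
the apparent branch/private compartments. Every cell of the matrix is
therefore re-genotyped with deep targeted counts, and an absent cell flips
to present iff

* deep alternate reads ≥ `min_alt` (default 5), **and**
* deep VAF ≥ `min_vaf` (default 0.01).

Present cells never flip back, so rescue is monotone: the presence set only
grows and the trunk fraction never decreases. The rule's defaults are a
design choice, not a published threshold: at ~3700X a VAF-0.01 mutation
yields ~37 alternate reads while a 0.1–0.5% sequencing-error process yields
~4–18, so the joint rule is permissive for real presences and essentially
never triggered by error alone at the packaged error rate of 0.1%. Both
knobs are exposed (`rescue_rule()`); cells without deep coverage are warned
about and left unchanged rather than guessed.

### Distances, neighbor joining and the germline root

The genetic distance between two sites is the hamming distance between
their matrix columns — the number of rows where they differ. A germline
ancestor with no somatic alterations is represented as an all-zero column
appended before the distance computation, so the distance from any site to
germline is its alteration count. Trees are built with the classical
Saitou–Nei neighbor-joining agglomeration (Q-criterion, standard
branch-length formulas) implemented in the package itself so that its
numeric conventions are explicit:

* ties in Q are broken by lexicographic order of the joined label pair,
  making the topology deterministic;
* negative branch-length estimates are clamped to 0, preserving the
  count interpretation of lengths;
* with two taxa the single edge is returned.

The result is an `ape::phylo` object rooted at the germline leaf;
`ape` handles Newick serialization and plotting. Tests verify exact
recovery of random additive distance matrices (topology and path lengths to
1e-9) and topological agreement with `ape::nj` on shared inputs. Both the
NJ-estimated branch lengths and the raw mismatch-count distance matrix are
reported, since either reading of "branch length" is defensible; the raw
counts are what the distances literally are, the NJ lengths are the
tree-additive estimates. Clonal deconvolution is deliberately out of scope:
with low mutation burden, clone-aware reconstruction is unstable, and the
presence/absence analysis answers the relatedness question directly.

### Mean VAF by category

Per patient, the mean tumor VAF is computed over all (mutation, site) cells
where the mutation is present, within each category. Trunk mutations are
clonal, so their expected VAF is `0.5 × purity`; branch and private
mutations are subclonal and sit lower. A category with no present cells is
reported as missing, never as 0.

## 2. Copy-number profiles

### Encoding and SCNA trees

Integer total copy number is encoded on five levels: 0 → −2, 1 → −1,
2 → 0, 3 → +1, ≥4 → +2. The encoding is total and monotone on
non-negative integers. Per patient, the encoded segments of all sites are
aligned on the breakpoint union — the disjoint intervals induced by every
segment boundary of every site — giving a site-by-sample matrix whose rows
are intervals. The hamming distance counts intervals with *differing*
encoded levels (a −1 versus +1 difference contributes 1, not 2: hamming is
categorical; an absolute-difference variant is intentionally not the
default). The germline ancestor has no SCNAs (all-zero encoded column), and
tree construction reuses the mutation machinery. Intervals not covered in a
sample are treated as diploid (encoded 0) for distances: exome copy-number
output conventionally omits neutral regions, and the germline reference
state is "no SCNAs".

### Merging within patients and gene-level recurrence

For cohort-level recurrence the per-sample profiles of one patient are
merged: each breakpoint-union interval takes the *unweighted* mean of the
log2 ratios of the samples covering it, and sample-specific intervals keep
their value unchanged. The mean is unweighted across samples (not
length-weighted) — the merge operates interval-by-interval, and within one
interval every covering sample covers it entirely. Genes are assigned the
merged value of the segment containing their midpoint (midpoint assignment
avoids double-counting boundary-spanning genes; an any-overlap mode is
available). A gene is a recurrent gain if its log2 score is ≥ 0.25 in at
least 4 patients, a recurrent loss if ≤ −0.25 in at least 4; a gene
crossing both thresholds in disjoint patient sets is reported in both lists
and flagged. Recurrent genes are then intersected with differential
expression, keeping only direction-concordant classes: gains with p < 0.05
and linear fold change > 1.5 up, losses with the same bounds down. The
fold-change cut is applied on the linear scale (log2FC > log2 1.5); this
interpretation is a documented choice since "fold change > 1.5" is
ambiguous between scales.

Coordinates are 1-based inclusive throughout (SEG convention), in every
reader and writer.

## 3. Enrichment statistics

### GSEA and ssGSEA

`gsea_enrichment()` computes the weighted Kolmogorov–Smirnov running-sum
enrichment score of a gene set in a ranked list: walking the list from most
to least associated, hits accumulate `|score|^w` (normalized over the set,
weight exponent `w` default 1; 0 gives the classic unweighted statistic)
and misses accumulate uniformly; the ES is the signed maximum deviation.
Significance is by *gene-label permutation* — random sets of the same size —
two-sided on |ES| with a +1 pseudocount in numerator and denominator.
Phenotype permutation is not possible here because the input is a single
ranked association list, not a sample-by-gene expression matrix with
phenotype labels; gene-label permutation is the appropriate null for that
input. Permutation p-values are verified to be uniform under simulated
nulls (Kolmogorov–Smirnov test over 2,000 replicates at 499 permutations;
the +1 pseudocount makes p-values at coarse permutation resolutions
slightly conservative by construction, which is visible if the permutation
count is very small).

`ssgsea_scores()` scores one signature in one sample as the summed
difference between the weighted in-set empirical CDF (expression ranks
raised to α, default 0.25) and the uniform out-of-set CDF. Scores are
rank-based, hence invariant under strictly monotone transforms of a
sample's expression values; optional min–max normalization rescales each
signature across samples.

### Truncated product combination

Association p-values (is the pathway enriched near the top of the fusion
association ranking?) and deregulation p-values (is it enriched in the
expression fold-change ranking?) are combined per pathway by the truncated
product method: W is the product of the p-values at or below the truncation
point τ (default 0.05, the method's canonical choice; the combination is
deliberately insensitive to clearly null inputs), and the combined p is
P(W* ≤ W) under independent uniform nulls, evaluated with Zaykin's
closed-form sum. The sum is computed in log space via the Poisson CDF for
numerical stability. An empty product (no p ≤ τ) gives combined p = 1; at
τ = 1 the method reduces exactly to Fisher's method (χ² with 2L df), which
is tested to 1e-10, and the closed form is cross-checked against 10⁶-draw
Monte Carlo. The combination is monotone: decreasing any input p never
increases the combined p.

### ROC/AUC, rank-shift tests and drug targets

Benchmark gene sets are evaluated by ROC curves over the ranking with the
Mann–Whitney tie convention (tied positive–negative pairs count ½), so that
AUC × n_pos × n_neg equals the U statistic exactly — an identity the tests
assert on every input. The one-sided rank-shift test is the
Mann–Whitney–Wilcoxon test that set genes rank higher than the rest, exact
for small untied samples, normal approximation with tie correction
otherwise. Percentile ranks lie in [0, 100] with 0 the most associated
gene and average ranks for ties. Drug-target prioritization retains genes
in the top 15% of the ranking (inclusive at the boundary — the boundary
convention is stated because it is not standardized), mapped to at least
one drug, and significantly upregulated (p < 0.05, linear FC > 1.5),
sorted by percentile rank.

## 4. The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) produces patients with
known clonal truth so that every downstream stage can be tested against a
ground truth. Its defaults are the packaged *deep-validation scenario*:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 20 | cohort size |
| `site_range` | [2, 5] | sites per patient, uniform |
| `n_mutations` | 80 | per-patient union of somatic mutations |
| `clone_fractions` | 0.60 / 0.25 / 0.15 | trunk / branch / private proportions |
| `purity` | 0.4 | tumor purity; trunk VAF = 0.5 × purity = 0.20 |
| `ccf_range` | U(0.3, 0.8) | subclone cancer-cell fractions |
| `depth_wes` | 228 | mean WES coverage (reads) |
| `depth_deep` | 3700 | mean deep targeted coverage (reads) |
| `sequencing_error` | 1e-3 | per-base error rate |
| `scna_rates` | 0.20 / 0.15 / 0.10 | per-arm shared gain / shared loss / private event probabilities |
| `expression_cn_slope` | 1.0 | log2FC per encoded copy-number unit |
| `expression_noise_sd` | 0.5 | expression noise (log2FC units) |

Rationale for the calibrated values: trunk clones are fully clonal
(CCF 1), so purity 0.4 puts the expected trunk VAF at 0.20, matching the
0.16–0.23 range of observed trunk means in multi-site sarcoma cohorts;
subclone CCFs on U(0.3, 0.8) reproduce branch means near 0.12 without a
tree-structured clone model, which the analysis does not require. The
per-patient union of 80 mutations reflects a low-burden tumor once deep
validation augments the WES calls. Depth is Poisson around the tier mean
(the standard coverage model) rather than fixed. Where the mutation is
present the alt count is Binomial(depth, VAF); where absent,
Binomial(depth, error). Matched-normal counts are Binomial at the error
rate. Two-site patients cannot host a branch clone (more-than-one but
not-all is empty at two sites), so branch-assigned mutations collapse to
private there; the trunk proportion is unaffected, which is what the
trunk-recovery check depends on.

SCNA events are arm-level on a packaged toy genome: the 22 hg19 autosomes
as 39 arms (acrocentric chromosomes carry no usable p arm), with a
2,000-gene synthetic annotation allocated to arms proportionally to arm
length. Shared events (tCN 3 gains, tCN 1 losses) apply to every site,
private events to one site. Expression fold changes are linear in the mean
encoded status of a gene's arm across patients plus Gaussian noise, and the
DE p-value is the deterministic monotone map `p = 2Φ(−|log2FC|/σ)` — small
p for large fold changes, exactly reproducible.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mutational signatures and indels; tree-structured
multi-level subclonality; non-uniform capture efficiency and mapping
artifacts (strand bias, FFPE damage); focal SCNAs and allele-specific copy
number; batch structure in expression. In particular, real WES exhibits
far more site-dropout than a Poisson-depth model at 228X, which is why
observed WES-only trunk fractions in real cohorts sit far below the truth
that deep re-genotyping recovers; in the simulator the WES tier already
detects most presences, and rescue corrects only the borderline-VAF tail.

Determinism: all randomness flows from the config seed; identical config
and seed give byte-identical cohorts and fixture files (checksummed in the
run manifest).

## 5. Problem sizes and numerical choices

The test suite runs the trunk-recovery check on 20 patients × 80 mutations,
the NJ oracle on 100 random 4–6-taxon additive matrices, permutation
calibration on 2,000 replicates at 499 permutations, Monte Carlo
cross-checks at 10⁶ draws, and property scans (rescue monotonicity, filter
idempotence) on 100 simulated patients — sizes chosen so the full suite
completes in about a minute and a half on one CPU while keeping every check
statistically meaningful. Distance ties in NJ are resolved
lexicographically; branch lengths are clamped at 0; the truncated-product
sum is evaluated in log space; merged-interval arithmetic is exact integer
arithmetic on 1-based inclusive coordinates.

## 6. Known limitations

* Trunk/branch/private classification is presence/absence-based; it does
  not estimate cancer-cell fractions or mutation timing.
* The hamming distance weights every locus equally; no attempt is made to
  model back-mutation or convergent loss (reasonable for point mutations,
  cruder for SCNAs, where a shared-then-reverted arm would be miscounted).
* The SCNA missing-as-diploid convention can understate distances if a
  caller truly dropped (rather than omitted-as-neutral) a region.
* GSEA p-values use gene-label permutation; inter-gene correlation is not
  modeled, so p-values on strongly co-regulated sets are anti-conservative
  — the combined analysis is a screening tool, not a confirmatory test.
* The exome capture size for mutation-per-Mb rates is a required user
  input; no default is assumed because the rate is meaningless without the
  denominator actually used.
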