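---
title: "Methods: comparing soil bacterial communities after pollutant spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing soil bacterial communities after pollutant spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistics the package implements, the
assumptions behind them, the choices that were genuinely open, and what
the synthetic-data validation does and does not demonstrate.

## The data model

The unit of analysis is an **OTU report**: one row per species-level OTU
(sequences clustered upstream at >97% similarity), a six-rank lineage
(domain, phylum, class, order, family, genus; `"unclassified"` below the
deepest rank the classifier could assign), and one integer read count per
sample. Reads that are classified only coarsely are never discarded: at
any aggregation rank they form their own `unclassified_<parent>` bins, so
sample depths are conserved while named-taxon tests stay clean. A flag
(`drop_unclassified`) removes those bins for users who prefer the
alternative reading. The canonical file dialect is tab-separated with a
leading `otu_id` column; files without that column are accepted, with ids
assigned in row order.

## Community structure: Pearson similarity, UPGMA, d, permutation test

Two samples are compared by the Pearson correlation of their count
profiles, reported in percent. Correlation is invariant to multiplying a
profile by a positive constant, which is exactly why it suits samples
with different sequencing depths — counts and relative abundances give
the same answer. The same engine accepts densitometric gel-fingerprint
lanes (position × lane intensity curves).

UPGMA (average linkage with cluster-size weights) clusters on the
dissimilarity `100 − similarity`. Node heights are ultrametric
leaf-to-node distances, i.e. half the merge dissimilarity. Ties are
broken by the lexicographically smallest member-label set so results are
identical across platforms. Cluster reliability is assessed by resampling
**features** (OTUs or gel positions) with replacement: the support of a
node is the percentage of replicates in which exactly its sample set
reappears as a cluster. Feature resampling is the standard fingerprint
bootstrap; resampling reads instead would mix sampling noise into a
question about which features carry the grouping. A replicate whose
resampled profile is constant cannot be correlated; it is discarded and
counted, and the denominator stays at the requested replicate number.

The treatment effect is the percent dissimilarity

$$d = \overline{s}_{\text{within}} - \overline{s}_{\text{between}},$$

with within-group pairs of both groups pooled into one mean (the
`groupwise` option averages per-group means instead; with equal group
sizes the two differ only when within-group variances differ). Its null
distribution comes from reassigning samples to two groups of the original
sizes. All distinct unordered partitions are enumerated when there are at
most 10,000 of them — 4 vs 4 gives 35, 6 vs 6 gives 462 — otherwise
Monte-Carlo draws are used with the observed partition added to both
numerator and denominator. The test is one-sided (large d = group
effect), and p can never be zero. With 3 replicates per group the floor
is p = 0.1, so significance at 0.05 is structurally unattainable; the
report prints this rather than letting a non-significant p pass silently
as evidence of no effect. Sequencing designs with triplicates simply
cannot clear 0.05 by a two-group permutation test, which is why the
fingerprint experiments that feed this test are usually run with four
replicates.

## Diversity

Rarefaction uses the analytic hypergeometric form
$E[S(k)] = \sum_i 1 - \binom{N-N_i}{k}\big/\binom{N}{k}$, evaluated via
`lchoose` in log space so deep samples do not overflow. Chao1 defaults to
the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which is
defined even without doubletons; the classic form is available and falls
back (with a warning) when $F_2 = 0$. Shannon uses the natural log (a
`base` argument covers log2 conventions); Pielou's evenness is
$H/\ln S_{obs}$ and is reported as `NA` with an explicit reason for
single-OTU samples rather than a silent `NaN`. Rarefied indices subsample
without replacement `n_iter` times (default 100) and report mean ± sd; in
richness mode the mean agrees with the analytic formula, which the tests
verify against a Monte-Carlo oracle.

The diversity comparison between treatments is the percent reduction in
rarefied richness at a fixed depth, default 400 reads — deep enough to be
informative, shallow enough that taxon subsets (classes) can be compared
too. Rarefaction is computed per sample and averaged within groups;
pooling replicates first is possible in principle but mixes
between-replicate variation into the richness estimate, so the per-sample
mode is the default and the one the tests exercise.

## Responder tests

For each taxon at each rank (phylum … genus, plus raw OTUs) the
per-sample counts $y_s$ out of depths $n_s$ enter a one-factor binomial
logistic GLM, followed by all pairwise group contrasts with unadjusted
and single-step (Tukey-style) adjusted p-values. Enrichment in a spiked
soil is called from the spiked-vs-control contrast of that soil at
unadjusted p < 0.05 — the permissive choice is deliberate for a
screening analysis, and Benjamini–Hochberg q-values are emitted alongside
for stricter use.

Replicate soil communities are **overdispersed**: the variance of a
taxon's count exceeds binomial sampling noise, and under a
Dirichlet-multinomial model the inflation factor is $1 + (n_s - 1)\rho$,
which grows with depth. Ignoring this roughly triples-to-quintuples the
nominal false-positive rate in our simulations, and a constant
quasi-likelihood scale factor cannot absorb it when depths span an order
of magnitude. The default model therefore (i) estimates the read
intraclass correlation $\rho$ once per table by a moment estimator (the
within-group Pearson chi-square per cell, normalized by the chi-square
median so the median over cells is unbiased), (ii) downweights each
sample by $1 + (n_s-1)\hat\rho$, (iii) estimates the usual quasi
dispersion on top, and (iv) uses t contrasts with the residual degrees of
freedom and single-step adjustment through the multivariate t. When a
group has no reads at all for a taxon (complete separation — common for
rare responders), Wald statistics are meaningless and the pair is tested
by a Fisher exact test on pooled counts deflated by the same weights,
with a Haldane 0.5 log-odds estimate, flagged `method = "fisher"` and
Bonferroni-adjusted. Setting `family = "binomial"` (and hence ρ = 0)
reproduces the plain unweighted logistic model for comparison with
analyses that used it.

Diminished OTUs are called per soil by two explicit rules, with the
"average detection" read as the mean OTU share of the control community,
$1/S_{\text{control}}$ (a read-weighted alternative gives the same
value): **rule 1**, control share ≥ 5× average and zero reads in every
corresponding spiked sample; **rule 2**, control share ≥ 4× average and
control significantly higher than spiked (p < 0.05) by the OTU-level
contrast. Rule 1 is reported when both fire. Prevalence-based readings of
"more often detected than average" are possible; the share-based reading
is the default and is stated prominently because the distinction matters
for sparse tables.

## Responder phylogeny

Distances from an aligned FASTA use pairwise deletion of gap/N columns —
complete deletion would discard most sites for short amplicon fragments —
with either the raw mismatch fraction or the Jukes–Cantor correction
$d = -\tfrac34\ln(1-\tfrac43 p)$ (undefined at p ≥ 0.75, reported as an
error naming the pair; no substitution model is implied by the data, so
the simplest correction is the default). Trees are neighbor-joining
(`ape::nj`), with negative estimated branch lengths clamped to zero and
the clamped total recorded; supports come from column bootstrap. For
display, trees are midpoint-rooted and **compressed**: every maximal
clade whose leaves all lie within a path-length threshold of the clade
root collapses to one leaf at that root, labelled
`representative (+k)` with the lexicographically smallest member as
representative. Collapsing on the leaf-to-clade-root path length is one
defensible criterion among several (cophenetic diameter would be
another); it is exposed as a parameter, and total leaf membership is
always conserved.

## The synthetic experiment

`community_spec()` encodes the study conditions the analysis assumes:

* **Design**: 2 soils (Cambisol, Luvisol) × {control, spiked} × 3
  sequenced replicates; gel fingerprints use 4 replicate lanes per group,
  matching the usual fingerprinting design.
* **Community**: 2000 species-level OTUs under a lognormal abundance law
  (sdlog 1.5, a typical long-tailed species-abundance shape), nested
  random taxonomy (15 phyla … 180 genera), 30% of lineages truncated to
  `"unclassified"` below some rank, mostly at genus — echoing tables
  where >40% of reads are unclassified at genus level.
* **Depths**: truncated normal, mean 2500, sd 800, floor 200 reads —
  the uneven-depth regime of early pyrosequencing runs (group means of
  roughly 1700–4400 ± up to ~2000 reads).
* **Between-soil divergence**: 80% of OTU abundances are redrawn per
  soil. This value was calibrated so the control-vs-control percent
  dissimilarity lands in the mid-30s, the magnitude reported for two
  contrasting real soils; smaller values let the control communities of
  the two soils intermix in the UPGMA tree, which real soil communities
  of different texture do not do.
* **Replicate overdispersion**: one Dirichlet precision θ = 300
  (ρ = 1/301). Calibrated from published replicate standard deviations of
  relative abundances in control soils (entries like 3.4 ± 1, 7.8 ± 1
  imply 1+θ ≈ 300–700); the two strongest responders show more spread
  (23.4 ± 4, 4.1 ± 2, implying 1+θ ≈ 100), which is treatment-growth
  variability that a single community-wide θ deliberately does not chase.
* **Planted effects**: two responder genera common to both soils at
  target relative abundances 20% and 5% in spiked groups (the scale of a
  dominant *Sphingomonas*-like and a *Polaromonas*-like responder), and
  ten OTUs at 2% control share each with probability exactly zero after
  spiking. The 2% share keeps the planted OTUs comfortably above the
  5×-average detection bar (≈ 0.5% when ~1000 OTUs are detected in a
  control), so recovery measures the rule, not replicate noise.

What the generator does **not** emulate: chimeras and sequencing error,
classifier confidence, phylogenetic correlation of responders, broad
sublethal abundance shifts across the whole community, and
treatment-specific growth variability. Consequently, passing tests show
that the statistics recover effects of the planted kind and size under
realistic noise; they do not show that a real spiked soil would yield
richness reductions of any particular size — the generator's reductions
(a few percent at depth 400) come only from planted absences plus
responder dominance, whereas real toxicity also suppresses many taxa
mildly.

## Numerical choices and degenerate inputs

Randomness always flows through a single integer seed per operation and
restores the caller's RNG state. UPGMA and compression ties break
lexicographically. Constant profiles are errors that name the offending
sample; zero-depth samples are errors in normalization and exclusions
(with warnings) in rarefaction at depth; all-zero taxa are skipped, not
tested; single-step adjusted p-values are clamped to be at least the
unadjusted p (the integration is stochastic, with a fixed internal seed).
Exhaustive permutation uses a 1e-12 tolerance when counting null d values
at least as large as the observed one, so exact ties are not lost to
floating-point noise.

## Problem sizes used by the tests

The test-suite simulations use the full 2000-OTU design for end-to-end
recovery checks and 200–400-OTU variants for unit-level properties; the
permutation-test calibration runs 500 null datasets (divergence 0, no
planted effects, 6-vs-6 exhaustive enumeration of 462 partitions), and
rarefaction is validated against 1000-replicate Monte-Carlo subsampling.
These sizes were chosen as the smallest at which the studied effects are
clearly identified; all are the package's own validation choices.

## Known limitations

* With triplicate groups the permutation test cannot reach p ≤ 0.05;
  interpret d descriptively there and rely on the bootstrap supports.
* The ρ estimator pools one intraclass correlation across all taxa;
  taxon-specific overdispersion (e.g. responders during active growth) is
  absorbed by the per-taxon quasi scale factor only approximately.
* Fisher-fallback contrasts are conservative for very rare taxa; power
  for taxa observed in only a handful of reads is limited by design.
* Compression assumes a rooted tree with meaningful branch lengths;
  midpoint rooting is a display convention, not an inference.
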