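# soilresponders

Statistical analysis of bacterial community responses to pollutant spiking
in soil, built around 16S rRNA gene amplicon OTU tables and community
fingerprints. The package is aimed at microbial ecologists comparing
treated and control soil microcosms with few replicates and uneven
sequencing depths, and asking three questions: did the community structure
change, did diversity drop, and which taxa responded?

## What it computes

**Community structure.** Samples are compared by the pairwise Pearson
correlation *r* of their OTU count profiles (in percent, *r* × 100), which
is insensitive to unequal read depths. Samples are clustered by UPGMA with
feature-bootstrap support (the percentage of bootstrap replicates in which
a node's exact sample set reappears as a cluster). The treatment effect is
the **percent dissimilarity**

> *d* = mean within-group pairwise similarity − mean between-group pairwise similarity,

tested by permuting the sample-to-group assignment: exhaustively over all
distinct partitions when feasible (4 vs 4 replicates gives 35 partitions,
so the smallest attainable *p* is 1/35 ≈ 0.029; 3 vs 3 gives 10, floor
0.1 — the report says so explicitly), or by Monte-Carlo draws otherwise.

**Diversity.** Analytic (hypergeometric) rarefaction curves,
E[S(k)] = Σᵢ [1 − C(N−Nᵢ, k)/C(N, k)], plus rarefaction-normalized Chao1,
Shannon and Pielou indices, and the percent reduction in rarefied richness
between control and treated groups at a fixed depth (default 400 reads).

**Responders.** Every taxon from phylum to genus plus each species-level
OTU is tested with a binomial logistic GLM on per-sample counts out of
sample depths, with all pairwise group contrasts and Tukey-style
single-step adjustment. Because replicate soil communities are more
variable than binomial sampling alone (Dirichlet-multinomial
overdispersion that grows with depth), the default model estimates the
read intraclass correlation from the whole table, downweights samples by
1 + (n−1)ρ̂ and applies a quasi-likelihood scale factor; groups entirely
without a taxon (complete separation) fall back to a Fisher exact test on
effective pooled counts. `family = "binomial"` gives the plain unweighted
logistic model. Diminished OTUs are called by two explicit rules: control
share ≥ 5× the average detection (1/S of the control community) and never
detected after spiking, or ≥ 4× the average and significantly higher in
the control.

**Responder phylogeny.** Jukes-Cantor or p-distances from an aligned
FASTA (pairwise gap deletion), neighbor-joining with column-bootstrap
supports, and branch compression: every maximal clade whose leaves all lie
within a path-length threshold of the clade root collapses to one node
labelled `representative (+k)`.

**Synthetic experiments.** `community_spec()` describes a two-soil
spiking study (2 soils × {control, spiked} × 3 replicates, 2000 OTUs with
a lognormal abundance distribution, truncated-normal depths around 2500
reads, Dirichlet-multinomial replicate noise, planted responder genera at
20% and 5% relative abundance and ten OTUs absent after spiking);
`simulate_community()` generates the OTU table, gel-fingerprint lanes and
the ground truth, so every stage of the analysis can be validated without
any external data.

## Worked example

```r
library(soilresponders)

sim  <- simulate_community(community_spec(), seed = 1)
simm <- pearson_similarity(sim$otu)
glab <- sim$groups$group[match(sim$otu$sample_ids, sim$groups$sample_id)]
spiked  <- sim$otu$sample_ids[glab == "Cambisol.spiked"]
control <- sim$otu$sample_ids[glab == "Cambisol.control"]

dissimilarity_d(simm, list(spiked, control))
#> Percent dissimilarity d = 56.06 (within 74.59 - between 18.54; n = 3 vs 3)

permutation_test_d(simm, list(spiked, control))
#> Permutation test for percent dissimilarity d
#>   d = 56.06, p = 0.1 (exhaustive over 10 partitions)
#>   note: smallest attainable p with this design is 0.100; significance at 0.05 is unattainable
```

Running the full workflow:

```r
rep <- run_pipeline(pipeline_config(seed = 1))
print(rep)
```

prints (abridged):

```
Community-response pipeline report
  Bacteria : Cambisol d=56.1 (p=0.1); Luvisol d=60.1 (p=0.1)
  Class_001 : Cambisol d=36.4 (p=0.1); Luvisol d=29.3 (p=0.1)
  Class_010 : Cambisol d=28.6 (p=0.1); Luvisol d=27.7 (p=0.1)
  Class_006 : Cambisol d=38.8 (p=0.1); Luvisol d=44.6 (p=0.1)
  Cambisol: richness reduction 6.3% at depth 400
  Luvisol: richness reduction 3.9% at depth 400
  enriched taxon x soil hits: 56 | common: 14
  diminished OTU x soil hits: 22
```

Read: the spiked Cambisol community differs from its control by d = 56
percent points of Pearson similarity (with 3 replicates per group the
permutation floor is p = 0.1, and the report notes that 0.05 is
unattainable); rarefied richness at 400 reads dropped in both spiked
soils; the planted responder genera are recovered among the enriched taxa
common to both soils, and the planted absent OTUs among the diminished
calls.

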