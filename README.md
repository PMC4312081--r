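# lemmingdiet

Tools for DNA-metabarcoding diet analysis of sympatric herbivores, built
around the winter diets of the two High-Arctic lemmings — the collared
lemming (*Dicrostonyx groenlandicus*) and the brown lemming (*Lemmus
trimucronatus*). The package takes per-sample trnL P6-loop sequence-variant
counts from fecal pellets all the way to diet profiles, niche statistics and
food-selection ratios, and ships a ground-truth synthetic-data generator so
that every stage can be tested by parameter recovery.

It is aimed at molecular ecologists running diet metabarcoding studies who
want the analysis chain — not just the final numbers — to be reproducible
and testable.

## What it computes

* **Reference library handling** — lineage-tagged FASTA I/O and in-silico
  PCR: ungapped, IUPAC-aware primer matching with a per-primer mismatch
  budget extracts each record's amplicon into an index
  (`read_reference_fasta()`, `in_silico_pcr()`, `trnl_primers()`), plus a
  scan for species-diagnostic dinucleotide site pairs on aligned consumer
  sequences (`find_diagnostic_site_pairs()`).
* **Taxonomic assignment** — exact then best-identity matching of sequence
  variants to the amplicon index, resolved to the lowest common ancestor
  over family/genus/species; local-flora cleaning (removal of taxa absent
  from the site, congener reassignment) and rank aggregation
  (`assign_variants()`, `filter_by_local_flora()`, `aggregate_to_rank()`).
* **Consumer species ID** — classification of pellet samples by measured
  amplicon length and concordance with field identification
  (`classify_by_amplicon_length()`, `concordance_table()`).
* **Diet composition** — fusion of the vascular-biased g-h marker with the
  universal c-h marker: g-h vascular family proportions are scaled by the
  c-h vascular read fraction V, and c-h moss family proportions fill 1 − V
  (`fuse_markers()`, `diet_profiles()`, `population_mean_diet()`).
* **Niche statistics** — Schoener overlap
  O(p, q) = 1 − ½ Σⱼ |pⱼ − qⱼ|, Shannon trophic niche width
  TNW = −Σⱼ qⱼ ln qⱼ, Bolnick-style individual specialization
  IS = mean overlap of each individual with the population mean diet, with
  subsample resampling for unequal group sizes; rank-transform one-way
  ANOVA and the aligned rank transform for interactions
  (`schoener_overlap()`, `trophic_niche_width()`,
  `individual_specialization()`, `resampled_is()`, `rank_anova()`,
  `aligned_rank_anova()`).
* **Food selection** — quadrat biomass to availability proportions with
  exclusion rules, Manly selection ratios ŵᵢ = ōᵢ/π̄ᵢ with delta-method
  variances for sampled use *and* availability,
  Var(ŵᵢ) = s²ₒ/(nₒπ̄ᵢ²) + ō²ᵢ s²_π/(n_π π̄ᵢ⁴), and significance classes
  (`availability_proportions()`, `manly_selection()`,
  `classify_selection()`).
* **Synthetic data** — Dirichlet-multinomial sample counts with marker
  bias and negative-binomial depths, a synthetic reference library with
  nested primer systems, and Dirichlet-composition × lognormal-total
  availability quadrats, all with recorded ground truth
  (`generate_truth()`, `generate_sample_counts()`,
  `generate_reference_library()`, `generate_availability_quadrats()`).

## Worked example

Simulate a study at the published sample sizes (22 collared, 54 brown
lemming pellet samples), fuse markers, and compute the headline statistics:

```r
library(lemmingdiet)

tr <- generate_truth("bylot-like", seed = 1)
sim <- generate_sample_counts(tr, c(Dicrostonyx = 22, Lemmus = 54))
prof <- diet_profiles(sim$family_counts, tr$groups)

species <- sim$metadata$species[match(rownames(prof), sim$metadata$sample_id)]
qD <- population_mean_diet(prof[species == "Dicrostonyx", ])
qL <- population_mean_diet(prof[species == "Lemmus", ])

schoener_overlap(aggregate_profile(qD$population_mean, tr$clades),
                 aggregate_profile(qL$population_mean, tr$clades))
#> [1] 0.734

c(TNW_collared = trophic_niche_width(qD$population_mean),
  TNW_brown = trophic_niche_width(qL$population_mean))
#> TNW_collared    TNW_brown
#>        0.809        1.671

c(IS_collared = individual_specialization(qD),
  IS_brown = individual_specialization(qL))
#> IS_collared    IS_brown
#>       0.869       0.752
```

The broad-group overlap of 0.734 recovers the generator's truth value of
0.75 (collared 85/14/1 vs brown 65/9/26 across dicots/monocots/mosses)
within sampling error; the brown lemming's wider niche (higher TNW) and
the moderate individual specialization of both species mirror the
structure the preset encodes.

Selection of vascular plants by brown lemmings against quadrat-sampled
availability, excluding the abundant-but-uneaten Ericaceae and
wetland-collected samples:

```r
quad <- generate_availability_quadrats(tr, 16)
av <- availability_proportions(quad, tr$groups, "vascular",
                               exclude = "Ericaceae")
keep <- sim$metadata$sample_id[sim$metadata$habitat != "wetland" &
                                 sim$metadata$species == "Lemmus"]
use <- restrict_profiles(prof[keep, ], tr$groups, "vascular",
                         exclude = "Ericaceae")
manly_selection(use, av)
#>           family    pi   use    w     se cls
#>       Salicaceae 0.703 0.691  1.0  0.052   0
#>          Poaceae 0.086 0.105  1.2  0.370   0
#>     Polygonaceae 0.005 0.054 11.2  5.500 (+)
#>    Saxifragaceae 0.004 0.053 12.6 13.000   0
#>        Juncaceae 0.114 0.042  0.4  0.130   -
#>         Rosaceae 0.048 0.039  0.8  0.290   0
#>  Caryophyllaceae 0.012 0.000  0.0  0.000   -
#>       Cyperaceae 0.023 0.000  0.0  0.000   -
#>     Equisetaceae 0.002 0.000  0.0  0.000   -
#>         Fabaceae 0.003 0.015  4.5  2.700 (+)
```

Read: Salicaceae (willow) is eaten in proportion to its availability
(w = 1.0, class 0), Juncaceae is avoided (w = 0.4, class −), and rare
families such as Polygonaceae show large but uncertain ratios — exactly
the qualitative pattern of the study system this emulates.

See the vignette `vignettes/lemming-winter-diet.Rmd` for the models,
parameter choices and known limitations.

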