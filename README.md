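# clonetrace

Clonal lineage tracking for genetically barcoded hematopoietic stem cells
(HSCs) after transplantation.

In a cellular-barcoding experiment, each transplanted HSC carries a unique
heritable DNA barcode; sequencing sorted blood populations (granulocytes, B
cells, CD4 T and CD8 T cells) at successive time points reveals how much of
each lineage every clone produced. `clonetrace` implements the full analysis
for such an experiment, comparing mice transplanted with HSCs alone against
mice co-transplanted with multipotent progenitors (MPPs):

1. **Quantification** — barcode read counts are combined with three
   flow-cytometry fractions into absolute clonal abundance:

   `abundance = 100% × (population %WBC) × (donor %) × (GFP %) × reads / total reads`

   so every clone's output is expressed as a percentage of all white blood
   cells (%WBC).
2. **Artifact filtering** — clones above 0.5 %WBC in exactly one sample and
   absent (< 0.01 %WBC) everywhere else in the mouse are removed as
   PCR/sorting artifacts.
3. **Classification** — per clone: produced cell-type combination;
   myeloid/lymphoid lineage bias with the fold rule *biased ⇔ relative copy
   number > cot 22.5° = 2.4142 × the other lineage* and specialization
   precedence at the 0.01 %WBC measurability floor; B-vs-T bias;
   high-abundance flags (> 0.05 %WBC); temporal classes
   (early / late / persisted between 2.5 and 6.5 months); and
   expansion dynamics (late:early ratio above/below 1) for persisted
   T-cell-producing clones.
4. **Clustering** — log2 trajectory features → PCA → shared-nearest-neighbor
   graph → Louvain communities, categorised into long-/middle-/short-term
   reconstitution; UMAP embedding for display.
5. **Statistics** — one-tailed unequal-variance (Welch) t tests between the
   two mouse groups (mouse = unit of replication, mean ± SEM, `*` p ≤ 0.05,
   `**` p < 0.01) and Shannon clonal diversity per sample (vegan, nats).
6. **Synthetic data** — a generator with eight clone archetypes, lognormal
   clone noise, multinomial read sampling, Beta flow noise, injected spike
   artifacts and a built-in 2-fold late T-cell effect in the HSC+MPP group,
   with per-clone ground truth for end-to-end validation.

## Worked example

```r
library(clonetrace)

sim <- generate_dataset(simulation_config(sigma = 0.3), seed = 7)
ab  <- compute_clonal_abundance(sim$counts, sim$flow)
flt <- filter_spurious_clones(ab)

# how well are the generator's planted classes recovered?
label_recovery(sim, flt$abundance)
#> lineage_bias     temporal     dynamics
#>    0.9912500    0.9979167    0.9769921

# cluster clone trajectories and categorise by reconstitution timing
cr <- cluster_clones(flt$abundance, embed = FALSE)
table(cr$clones$term_category)
#>   long_term middle_term  short_term
#>        1636         238         526

# group comparison: donor-derived CD4 T output at 6.5 months
compare_groups(celltype_totals(flt$abundance, "CD4T", 6.5),
               "donor CD4T %WBC at 6.5 months", "greater")
#> Group comparison: donor CD4T %WBC at 6.5 months (HSC_MPP vs HSC, one-tailed 'greater')
#>   HSC_MPP  n = 7  mean = 17.35 +/- 0.753 (SEM)
#>   HSC      n = 5  mean = 6.871 +/- 0.3348 (SEM)
#>   Welch t = 12.72, df = 8.13, p = 5.961e-07 **
```

The recovery fractions say that ≥ 97% of the ~2,400 simulated clones get
their true lineage-bias, temporal and expansion labels back through the full
counts → abundance → filter → classify chain; the t test detects the planted
2-fold late T-cell increase of the MPP co-transplantation group.

A command-line wrapper over the same functions ships in
`inst/scripts/clonetrace.R` (subcommands `simulate`, `quantify`, `classify`,
`cluster`, `compare`, `diversity`).

## Documentation

The methods vignette (`vignettes/clonal-lineage-tracking.Rmd`) describes the
model, every threshold and its boundary convention, the open design
decisions taken (relative copy numbers, absence cutoff, cluster majority
rule, recovery-experiment clustering parameters), what the generator does
and does not emulate, and known limitations.
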