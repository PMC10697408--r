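# nukasv

Shared-ASV source tracking for paired fermented-food and skin microbiomes.

## The problem

*Nukadoko* is a Japanese fermented rice-bran bed, maintained by stirring with
bare hands, that pickles vegetables with lactic-acid bacteria. Daily hand
contact raises a concrete question for both food safety and skin-microbiome
research: do bacteria from the bed transfer onto the caretaker's palm, and if
so, how quickly are they shed once contact stops?

`nukasv` implements the full analysis for a paired source/sink 16S rRNA
amplicon design: each subject's bed (source) and palm (sink) are sampled as
pairs over a contact phase (days 0–14, daily stirring; the day-0 palm is
swabbed both before and 6 h after the first stir) and a no-contact phase
(days 15–29). The transmission signal is the **shared ASV** statistic: an
amplicon sequence variant counts as shared when its relative abundance
exceeds a threshold *t* (default 1 %) in **both** members of a pair,

```
shared(pair) = { f : p_source(f) > t  and  p_sink(f) > t }
S(pair)      = 100 · Σ_{f ∈ shared} p_sink(f)      (shared proportion, %)
```

with same-day pairing during contact and pairing against a fixed source day
(default 14, the last stirred day) afterwards. The package covers every
stage around the statistic — validated feature-table/taxonomy/metadata I/O,
chloroplast/mitochondria/unassigned filtering with exact read accounting,
genus-level top-N composition summaries, Shannon/observed-features alpha
diversity with exact without-replacement rarefaction, taxonomic breakdown
and persistence of the shared fraction — plus reference-sequence curation
filters (degenerate-base and homopolymer culling, domain-conditional length
filters, uniq-mode dereplication) for building a taxonomy database, and a
ground-truthed simulator of the whole study so every stage is testable
without downloading sequence data.

## Worked example

Simulate a study-shaped dataset (3 subjects, one dominant source genus at
75 %, transfer fraction 0.10, shedding half-life 0.5 d) and run the
shared-ASV timecourse:

```r
library(nukasv)

study <- generate_study(simulation_params(dominant_mass = 0.75, master_seed = 7))
filt  <- filter_organelle_unassigned(study$table, study$tax)
rel   <- to_relative(filt$table)
tc    <- shared_timecourse(rel, study$meta, threshold = 0.01)
subset(as.data.frame(tc), subject == "1",
       c(timepoint, phase, n_shared, shared_proportion_percent))
#>    timepoint      phase n_shared shared_proportion_percent
#> 1          0    contact        0                      0.00
#> 2         0'    contact        1                      5.13
#> 3          3    contact        1                      5.19
#> 4          6    contact        1                      4.96
#> 5          9    contact        1                      4.93
#> 6         12    contact        1                      4.89
#> 7         14    contact        1                      4.97
#> 8         15 no_contact        1                      1.08
#> 9         18 no_contact        0                      0.00
#> ...
persistence_summary(tc)
#>   subject last_detected_day detected
#> 1       1                15     TRUE
#> 2       2                15     TRUE
#> 3       3                15     TRUE
```

Reading the output: nothing is shared before the first stir (timepoint `0`),
about 5 % of the palm community is attributable to the bed 6 h after each
stir (the dominant source ASV at 75 % × an effective transfer of ~7 %), and
once stirring stops the transferred fraction halves every 12 h — still
detectable on day 15, gone by day 18. `shared_taxa_breakdown(tc, rel,
study$tax)` attributes the shared percentage to genera (here the dominant
lactic-acid bacterium), and `rarefaction_curve(filt$table, "shannon")`
checks that diversity comparisons are not depth artefacts.

The same pipeline runs on real exported tables via a YAML config:

```r
run_pipeline("config.yaml")   # or: Rscript inst/cli/nukasv.R run --config config.yaml
```

which writes the filter report, genus composition, diversity tables,
shared-ASV timecourse, breakdown and persistence summary as TSV.

Note on reference curation: the culling rule for ambiguous bases follows the
upstream curation tool's behaviour and rejects at **≥ 5** degenerate bases
(and ≥ 8-base homopolymers); both cut-offs are parameters of `cull_seqs()`.

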