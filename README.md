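# crisprleader

Comparative analysis of **type II-A CRISPR-Cas loci**: mine complete
cas9–cas1–cas2–csn2 operons from annotated bacterial genomes, locate the
repeat-spacer array downstream of *csn2*, extract the **leader-repeat
junction**, and classify each locus by its conserved 3' leader-end motif.

New spacers are integrated at the leader-repeat junction during CRISPR
adaptation, and the last nucleotides of the leader are required for that
step. Across type II-A loci the leader 3' end is conserved as one of three
motifs:

| Group | Leader 3' end | Junction |
|-------|---------------|----------|
| 1     | `ATTTGAG`     | `GAG`/`GTTT` |
| 2     | `CTRCGAG` (R = A/G) | `GAG`/`GTTT` |
| 3     | `..CG` (A-rich upstream) | `CG`/`GTTT` |

The repeat unit is typically 36 nt, starts `GTTT`, and ends in a conserved
`C`. Trees built from the four subtype-defining Cas proteins and from the
first repeat cluster loci into clades that mirror these groups — the
coevolution signal this package quantifies as clade purity and adjusted
Rand index. For who it's for: microbial genomicists surveying CRISPR
adaptation modules, and anyone needing a self-contained, deterministic
reimplementation of the locus-mining/classification chain (detector,
aligner, neighbor joining, sequence-logo matrices) with planted-truth
validation.

The package is pure R and self-contained: the tandem-repeat detector
(seed-and-extend with consensus boundary extension), affine-gap global and
progressive alignment, alignment-free k-mer distances, classical neighbor
joining with clade cutting, position-frequency profiles with information
content (`R = log2 4 − H − e(n)` bits) and IUPAC consensus, and a seeded
synthetic-genome simulator that plants loci with known truth for
end-to-end testing. See the methods vignette
(`vignettes/typeIIA-leader-analysis.Rmd`) for the model, parameter
defaults, and design decisions.

## Worked example

Simulate ten genomes with planted loci, run the full pipeline, inspect the
report:

```r
library(crisprleader)

ds  <- generate_synthetic_dataset(sim_config(n_loci = 10, seed = 7))
rpt <- run_pipeline(ds$records,
                    genus_map = setNames(ds$truth$genus, ds$truth$locus_id))
rpt
#> <crispr_report>
#>   candidate operons: 10; loci reported: 10; dropped: 0
#> <dataset_stats>
#>   loci: 10
#>   group counts: Group1=5, Group2=3, Group3=2, unclassified=0
#>   genera per group: Group1=5, Group2=3, Group3=2, unclassified=0
#>   GAG/GTTT junctions (Groups 1+2): 8
#>   modal repeat length: 36 with 0 exception(s)
#>   first repeats lacking 5' GTTT: 0 ; lacking 3' C: 0
#>   mean Csn2 length per clade: 1=320, 2=224, 3=224, 4=224
#>   Cas1 clade/motif concordance: purity 1.000, ARI 0.648

head(rpt$junctions[, c("locus_id", "leader_end7", "junction_repeat4",
                       "repeat_length")], 4)
#>    locus_id leader_end7 junction_repeat4 repeat_length
#> 1 locus_001     ATTTGAG             GTTT            36
#> 2 locus_002     ATTTGAG             GTTT            36
#> 3 locus_003     ATTTGAG             GTTT            36
#> 4 locus_004     ATTTGAG             GTTT            36
```

Reading the numbers: all 10 planted operons were found and none dropped;
motif classification recovers the planted 5/3/2 group split; 8 of the 8
Group 1+2 loci carry the canonical `GAG`/`GTTT` junction; every first
repeat is 36 nt with the `GTTT` start and `C` end; the Cas1 tree's four
clades are pure with respect to the motif groups (ARI < 1 only because
Group 1 legitimately spans two clades, ancestral long-Csn2 at 320 aa and
derived short at 224 aa). The per-group consensus of the aligned junction
region (`rpt$profiles$Group1$consensus`) reads `...ATTTGAGGTTT...` at full
2-bit conservation.

`write_report(rpt, "out/")` writes the loci/junction/assignment tables,
per-locus FASTA, Newick trees, PHYLIP distances, logo matrices and a JSON
summary. Real genomes enter via `parse_genome_record("file.gb")` (GenBank
with CDS features, or FASTA plus a coordinate table). A thin CLI wraps the
same functions: `Rscript inst/scripts/crispr-leader.R simulate|run ...`.

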