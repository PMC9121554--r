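# atacreg

Integrative analysis of two-condition ATAC-seq experiments, from replicated
peak sets to a transcription-factor → target-gene regulatory network.

The package is written for regulatory-genomics analysts comparing open
chromatin between two related conditions — e.g. an oncohistone-mutant tumor
line against its isogenic wild-type revertant — who need the full chain of
desk analyses that follows peak calling:

1. **Condition-unique peaks** — occupancy mode partitions the merged union
   of per-sample peak sets by presence/absence across replicates; affinity
   mode tests consensus-peak counts with a negative-binomial
   likelihood-ratio test using a common method-of-moments dispersion
   (variance = μ + αμ²), median-of-ratios size factors as offsets, and
   Benjamini–Hochberg q-values.
2. **Genomic annotation** — each peak is classified
   promoter > exon > intron > intergenic, with promoters defined as the
   strand-aware window −2 kb…+1 kb around the TSS.
3. **Expression concordance** — condition-specific peaks are linked to gene
   bodies (≥ 1 bp overlap) and intersected with an expression table to
   select genes upregulated (padj < α, log2FC > 0) in the same condition.
4. **Enhancers and super-enhancers** — enhancers are H3K27ac regions minus
   promoters; regions are associated to genes by the basal-plus-extension
   rule (5 kb/1 kb basal around the TSS, ≤ 1 Mb extension truncated at
   neighbouring basal domains); super-enhancers containing unique peaks are
   reported with their associated genes and upregulation flags.
5. **Motif enrichment** — PWM scanning on both strands with exact tail
   p-values (dynamic programming over a 10⁻³-bit score lattice; verified
   against exhaustive 4^w enumeration), and fold enrichment
   `observed / mean(hits on scrambled sequences)` against
   composition-preserving shuffles, calling motifs enriched at fold ≥ 2.
6. **Gene-set enrichment** — exact hypergeometric over-representation with
   per-category (BP/CC/MF/KEGG) Benjamini–Hochberg correction.
7. **Regulatory network** — a bipartite graph connecting each enriched
   motif's TF to the upregulated genes whose linked condition-specific
   peaks carry a hit, exported as GraphML/SIF/TSV with hub ranking and
   pairwise TF target-overlap (Jaccard) statistics.

Because the sequencing data behind such studies is often unavailable, the
package ships a first-class synthetic-data generator (`simulate_dataset()`)
that produces a genome, gene models, replicated peak sets, NB count
matrices, an expression table, H3K27ac/super-enhancer tracks and a ground
truth table from a single seed, so the entire pipeline is testable end to
end.

## Worked example

```r
library(atacreg)

ds <- simulate_dataset(sim_config(seed = 42))
ds
#> synthetic_dataset: 6000000 bp genome, 150 genes, 300 true peaks (50 A-unique, 50 B-unique), 4 samples

res <- run_pipeline(ds)
res
#> pipeline_result:
#>   unique peaks: A = 50 , B = 50 , shared = 200
#>   concordant upregulated genes: 30
#>   SE hits: 5
#>   enriched motifs (A): AP1_syn
#>   network: 1 TFs -> 16 genes, 16 edges
#>   truth-recovery metrics:
#>     unique_peak_recall_a         1.000
#>     unique_peak_recall_b         1.000
#>     concordant_gene_precision    1.000
#>     concordant_gene_recall       1.000
#>     implanted_motif_fold_a       90.000
#>     implanted_motif_fold_b       1.429
#>     edge_precision               1.000
#>     edge_recall                  1.000
#>     se_gene_recovery             1.000

res$motif_enrichment$A
#>   motif_id tf_name observed background_mean fold n_shuffles enriched
#> 1  AP1_syn   Ap1TF       27             0.3   90         10     TRUE
```

Reading the output: the generator placed 50 condition-A-unique peaks (30 of
them inside bodies of genes it marked upregulated) and implanted the
consensus of a synthetic AP-1-like motif into half of the A-unique peaks.
The pipeline recovered every unique peak by occupancy, selected exactly the
30 truth-coupled genes as concordantly upregulated, found the implanted
motif 27 times in A-unique peaks against 0.3 expected on scrambled
sequence (fold 90, far above the ≥ 2 enrichment call) while the same motif
stayed near background in condition B (fold 1.4), and reconstructed the
TF→gene network with perfect precision and recall against the implanted
truth.  The annotation table, enhancer set, super-enhancer hits,
differential-test table and TF overlap statistics are all available on the
result object (`res$annotation`, `res$enhancers`, `res$se_hits`,
`res$differential`, `res$tf_overlap`).

Individual steps are exported for real data: `read_bed()` /
`read_bed12()` / `read_expression()` / `read_jaspar()` / `read_meme()` /
`read_gmt()` bring in standard formats, and the module functions
(`call_unique_peaks()`, `category_proportions()`,
`select_concordant_genes()`, `define_enhancers()`,
`overlap_super_enhancers()`, `scan_pwm()`, `fold_enrichment()`,
`enrich()`, `build_network()`, `export_network()`) compose freely.

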