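# nucwrap

Fragment-level analysis of nucleosome unwrapping states from paired-end
MNase ChIP-seq data.

## The problem

When micrococcal nuclease digests crosslinked chromatin, the length of
each immunoprecipitated, paired-end-sequenced DNA fragment reports how
much of it a protein particle protected: ~147 bp for an intact
nucleosome core, ~120–140 bp for a hexasome, ~80 bp for a tetrasome,
shorter stretches for further unwrapped intermediates and
transcription-factor footprints. The fragment's *center* reports where
the particle sat — and a nucleosome that has unwrapped from one side
keeps one edge of its original 147-bp footprint, so its center shifts
off the dyad by ±(73 − ⌈L/2⌉) bp for protected length L.

`nucwrap` turns these observations into a reusable pipeline for anyone
analyzing nucleosome structure from fragment-level chromatin data
(MNase ChIP-seq, CUT&RUN and related assays):

* **Fragment length profiles (FLPs)**: per-base-pair length histograms
  over 0–200 bp, with prominence-based summit/sub-peak calling.
* **V-plots**: strand-oriented fragment-center density matrices
  (length × offset from a reference point) normalized to centers per
  billion read pairs, CPB = count × 10⁹ / library pairs; plus
  difference-V-plots between conditions and per-group meta-profiles.
* **Five fragment groups**: G80 (30–80 bp), G100 (81–100),
  G120 (101–120), G140 (121–140), G168 (141–168); per-window group
  counts/ratios, +1-nucleosome selection 50–200 bp downstream of TSSs,
  and RPM genome tracks per group.
* **Unwrapping-state classes**: median/MAD scaling of per-nucleosome
  group ratios, hierarchical clustering into five classes labelled A–E
  after the group each over-represents, and Spearman correlation of
  ratios with gene expression.
* **CTCF binding site orientation** on the consensus motif
  5′-CCACNAGGTGGCAG-3′ (strand-aware site centering for footprint
  geometry analysis).
* **A synthetic-data generator** with planted ground truth (unwrapping
  mixtures, phased promoter/CTCF-site arrays, footprints,
  expression-linked unwrapping, knockdown pairs) so the whole pipeline
  is testable without sequencing data.

Inputs are plain formats: fragment BED/BEDPE, BED6 reference points,
TSV expression tables, FASTA genomes; outputs are TSV matrices,
bedGraph tracks and BED6 files.

## Worked example

Simulate a promoter landscape with planted unwrapping classes, then
run the analysis end to end:

```r
library(nucwrap)

land <- simulate_tss_landscape(n_genes = 500, seed = 42)
land$fragments
#> FragmentSet 'synthetic_tss': 400000 fragments
#>   chromosomes: chrS
#>   length range: 26-171 bp (median 95)

# 1. Fragment length profile: the five planted length modes
find_peaks(compute_flp(land$fragments))
#>   length    height prominence is_summit
#> 1     60 0.0180785  0.0180785      TRUE
#> 2     91 0.0147415  0.0133540     FALSE
#> 3    150 0.0121375  0.0085875     FALSE
#> 4    110 0.0120635  0.0082785     FALSE
#> 5    130 0.0120555  0.0081890     FALSE

# 2. Group ratios in +1-nucleosome windows, scaled and clustered
centers <- reference_points(land$truth$chrom, land$truth$plus1_dyad,
                            kind = "NUC_CENTER", name = land$truth$gene_id)
tab <- window_group_ratios(land$fragments, windows_around(centers, 100))
m <- scale_ratios(tab)
res <- label_clusters(hcluster(m, k = 5), m)
res
#> ClusterResult: 500 rows in 5 clusters
#>   cluster 1 (C): 100 rows
#>   cluster 2 (E): 97 rows
#>   cluster 3 (B): 100 rows
#>   cluster 4 (D): 100 rows
#>   cluster 5 (A): 103 rows

# 3. Unwrapping ratios versus expression
correlate_ratios_expression(tab, land$expression)
#>   group         rho            p   n
#> 1   G80 -0.25893457 4.203787e-09 500
#> 2  G100  0.03477802 4.377794e-01 500
#> 3  G120  0.05688872 2.041149e-01 500
#> 4  G140  0.23000202 1.992838e-07 500
#> 5  G168  0.18135969 4.522003e-05 500
```

Reading the output: the FLP summit at 60 bp with sub-peaks near 91,
110, 130 and 150 bp reflects the planted unwrapping-state mixture; the
five clusters recover the planted classes (all 100-gene classes found,
labels A–E assigned to their signature groups); and the strongly
unwrapped G80 ratio anti-correlates with expression (rho ≈ −0.26)
while the long-fragment ratios correlate positively — the signature of
unwrapped +1 nucleosomes marking less active genes.

A command-line front end over the same functions is installed at
`exec/nucwrap` (subcommands `simulate`, `flp`, `vplot`, `diffvplot`,
`metaprofile`, `groups`, `plus1`, `cluster`, `orient-cbs`, `tracks`,
`overlap`), driven by a YAML config and a single seed; each run writes
a JSON manifest alongside its outputs.

See `vignettes/nucleosome-unwrapping.Rmd` for the model, conventions,
parameter choices and the generator's scope.

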