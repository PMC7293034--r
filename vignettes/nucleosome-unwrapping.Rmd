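---
title: "Mapping nucleosome unwrapping states from MNase ChIP-seq fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping nucleosome unwrapping states from MNase ChIP-seq fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucwrap)
```

## The measurement model

Micrococcal nuclease digests the DNA that is not protected by bound
protein. In crosslinked chromatin followed by chromatin
immunoprecipitation and paired-end sequencing, each sequenced fragment
is one protected particle, and its *length* carries structural
information: an intact nucleosome core protects ~147 bp, a hexasome
(one H2A--H2B dimer lost) ~120--140 bp, a tetrasome ~80 bp, and
progressively unwrapped intermediates protect characteristic shorter
stretches. Transcription-factor footprints (e.g. CTCF) protect
~30--55 bp. The fragment's *center* carries positional information:
a symmetric core is centered on the nucleosome dyad, while a particle
that has unwrapped from one side retains one edge of the original
147-bp footprint, so its center shifts off-dyad by
$\pm(73 - \lceil L/2 \rceil)$ bp for a protected length $L$.

`nucwrap` operationalizes this model as four connected analyses:

1. **Fragment length profiles (FLP)** -- `compute_flp()` counts
   fragments per base pair of length over 0--200 bp;
   `find_peaks()` locates the summit and sub-peaks after
   moving-average smoothing, using topographic prominence to separate
   genuine unwrapping modes from sampling noise.
2. **V-plots** -- `compute_vplot()` accumulates fragment centers into
   a (length x offset) matrix around reference points
   (TSSs, CTCF sites, nucleosome centers), strand-oriented so that
   positive offsets always point downstream, and normalized to
   *centers per billion read pairs* (CPB):
   $\mathrm{CPB} = \mathrm{count} \times 10^9 / N_\mathrm{pairs}$.
   `difference_vplot()` subtracts two CPB matrices cell-for-cell to
   expose condition-dependent redistribution of protection;
   `aggregate_groups()` collapses rows into per-group meta-profiles.
3. **Fragment groups and ratios** -- `fragment_group_scheme()` fixes
   the five-way length partition G80 (30--80 bp), G100 (81--100),
   G120 (101--120), G140 (121--140), G168 (141--168);
   `window_group_ratios()` computes per-window group ratios (windows
   are typically nucleosome center +/- 100 bp, membership by fragment
   center); `select_plus1()` picks the nucleosome center 50--200 bp
   downstream of each TSS as the +1 nucleosome.
4. **Unwrapping-state classes** -- `scale_ratios()` centers each
   group column by its median and scales by MAD; `hcluster()` cuts a
   hierarchical tree into five classes; `label_clusters()` names them
   A--E after the group each over-represents, via an exact
   maximum-weight bipartite matching so the labels are unique;
   `correlate_ratios_expression()` relates per-gene ratios to
   expression by Spearman rank correlation.

## Coordinate and counting conventions

All coordinates are 0-based half-open (BED convention). A fragment's
center is `floor((start + end) / 2)` -- the left of the two middle
positions for even lengths -- and this convention is used identically
in V-plots, genome tracks and window membership, so the different
views of the same data never disagree by one base. Window membership
is by fragment center (not any-overlap), consistent with the
center-based V-plot normalization.

Inputs are assumed to be mapping-quality filtered upstream (the usual
mapq > 10 contract at alignment time); `read_fragments()` neither
deduplicates nor requires deduplicated input, and ingestion is
lossless by default (length bounds 1--1000 bp) with analysis-level
bounds applied later.

Two readings of the published group bounds coexist in the literature
we follow: a 30-bp and a 35-bp lower bound for the smallest group.
The default is 30; `fragment_group_scheme(min_small = 35)` gives the
stricter variant. We deliberately do not guess which bound applies
where and expose it as a parameter.

The CPB denominator is the *library-level* pair count (all retained
pairs of the sample), not the in-window count. The alternative
window-level reading would make matrices from different window sets
incomparable; the library-level reading keeps CPB a linear rescaling
of raw counts, which is also what makes difference-V-plots
meaningful. It is configurable by constructing `FragmentSet`s with
the desired totals.

A fragment near several reference points increments each of them:
every reference is an independent anchor, the standard V-plot
practice. Fragments are not double-counted within one anchor.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `smooth_halfwidth` | 2 | bp | FLP moving-average half-width; window is `2h + 1` |
| `min_prominence` | 0.05 | fraction of max | minimum topographic prominence of an FLP peak |
| `W` | 2000 (4-kb views), 250 (500-bp views) | bp | V-plot window half-width |
| `len_range` | 30--200 | bp | V-plot row range |
| `halfwidth` (windows) | 100 | bp | half-width of per-nucleosome ratio windows |
| `min_dist`, `max_dist` | 50, 200 | bp | +1 nucleosome selection band downstream of the TSS |
| `min_fragments` | 20 | count | windows below this in-range total are excluded from scaling/clustering |
| `constant` | 1.4826 | -- | MAD normal-consistency factor; `1` gives the raw MAD |
| `k`, `linkage`, `metric` | 5, complete, Euclidean | -- | clustering tree cut and geometry |

The published analysis this package systematizes named neither the
linkage, the metric, nor how five classes were chosen; we take the
defaults of the clustering routine it names (`hclust`: complete
linkage; `dist`: Euclidean) and expose all three. Peak detection in
FLPs is likewise not specified there (peaks were read from plots), so
the smoothing/prominence defaults above are this package's own,
chosen to resolve sub-peaks ~15--20 bp apart at realistic sampling
depths. The 20-fragment window floor stabilizes the MAD scaling:
ratios from a handful of fragments are dominated by multinomial noise
and would inflate the scaled matrix.

Zero-MAD columns (a group with identical ratios in more than half the
windows) cannot be scaled; they pass through as all-zeros with a
warning rather than aborting, preserving the remaining columns.
Degenerate A--E labellings -- two clusters tied as the top enrichment
of the same group with no alternative assignment of equal total
weight -- are an error rather than an arbitrary choice.

Spearman p-values use the t-approximation for n > 30 and the exact
null distribution of the rank statistic for n <= 30 (ties force the
approximation; full permutation enumeration is infeasible beyond a
dozen observations).

## The synthetic-data generator

Every downstream stage is validated against data with *planted* truth
from `simulate_histone_sample()`, `simulate_tss_landscape()`,
`simulate_cbs_landscape()` and `simulate_knockdown()`. The generator
emulates the statistical structure the analyses assume:

* **Unwrapping-state mixtures.** A sample is a mixture of
  `unwrap_state()`s: protected length ~ round(Normal(mode, sd))
  clipped to [20, 200]; placement symmetric, left-retained
  (span `[dyad - 73, dyad - 73 + L)`), right-retained
  (`[dyad + 73 - L, dyad + 73)`) or footprint. The canonical deep-
  digestion default plants modes {147, 127, 105, 91, 69} bp with
  weights {0.45, 0.20, 0.15, 0.12, 0.08} and sd 3; the variant-
  histone default puts weight 0.6 on a broad 55-bp mode. The modes
  are the field's observables; the weights and sds are free
  parameters of this package with the stated defaults.
* **Promoter landscapes.** Each gene gets a stranded TSS, a +1 dyad
  50--200 bp downstream, downstream nucleosomes every 180 bp, an
  upstream nucleosome-depleted region (optionally carrying "fragile"
  short fragments, default proportion 0 -- published abundances are
  not quantified), a planted class A--E, an expression tier, and an
  expression value. Per-gene +1 group weights are the base vector
  (0.40, 0.15, 0.15, 0.15, 0.15) plus a 0.5 boost on the class's
  signature group, a +/-0.05-per-tier transfer from G80 to
  G140/G168 (so unwrapping anti-correlates with expression, matching
  the direction of the published correlations; the magnitude is the
  generator's own), renormalized, then resampled from a
  Dirichlet with concentration 50 (per-nucleosome variability).
  The 0.5 boost is chosen so the five planted class means sit ~4--5
  within-class dispersions apart: distinct classes that a clustering
  method *should* recover, rather than an overlapping continuum for
  which no ground-truth partition would be well defined.
* **CTCF-site landscapes.** The 14-mer consensus CCACNAGGTGGCAG (N
  drawn uniformly) is embedded at each site center on a random
  strand in an emitted random genome; flanking nucleosomes sit at
  +/-(NDR half-width + 73 + k * 180) bp; their subnucleosomal
  fragments use edge-retained placement, which makes short-fragment
  centers bimodal around each flanking dyad (the
  `flanking_placement = "symmetric"` ablation removes exactly this
  and nothing else); footprint fragments (30--55 bp) sit at the site
  center with configurable overall proportion (default 0.1).
* **Knockdown pairs.** `simulate_knockdown()` transfers probability
  mass from states with length mode < 120 bp to states >= 120 bp,
  holding everything else fixed. Structure (positions, classes,
  expression, weights) is drawn under the run seed and fragments
  under seed + 1, so wild type and knockdown share identical
  reference points and truth, and `shift = 0` reproduces the wild
  type byte-for-byte.

What the generator does *not* emulate: sequencing error,
mappability, PCR duplicate structure, crosslinking artifacts,
factor-bound (non-histone) footprints away from CTCF sites,
digestion-condition dependence of the length mixture, and real
genome sequence composition. Passing tests therefore demonstrate the
*algorithmic* correctness and statistical power of the pipeline under
its model assumptions -- not that a given real library satisfies
those assumptions.

## Validation design and problem sizes

The test suite checks every operation against an independent oracle:
V-plots against a literal (fragment x reference) double loop; window
counts against per-window brute-force scans; the 2-cluster case
against exhaustive enumeration of all 2-partitions of six points;
scaling against hand-computed values; motif scanning against
hand-derived reverse complements. Recovery checks run at the sizes
the statistics need: 2 x 10^5 fragments for five-mode FLP recovery,
2500 +1 nucleosomes (500 per class) for clustering (adjusted Rand
index vs the planted partition), 2000 genes for correlation signs,
300 genes for difference-V-plots, 200 sites for CTCF geometry; the
multi-seed checks run 20 seeds and tolerate one failure. These sizes
are the package's chosen study conditions and are reproduced by
`scripts/acceptance.R`.

```{r quick-example, eval = TRUE}
fs <- simulate_histone_sample(mixture_canonical_longmn(), 5e4, seed = 1)
find_peaks(compute_flp(fs))
```

## Known limitations

* Exact consensus matching only for CTCF-site orientation; sites
  whose motif instance deviates from the consensus are dropped
  (position-weight-matrix scanning is outside this package's scope).
* Nucleosome centers are consumed as input (or taken from generator
  truth); the package does not call nucleosome positions.
* Peak calling on genomic enrichment is likewise out of scope; peak
  intervals are inputs.
* Complete-linkage clustering is sensitive to outliers; on hard
  mixtures the tree cut can split a true class. The linkage is a
  parameter, and the adjusted Rand index against planted truth is the
  honest summary of that behaviour.
* FLPs ignore fragments longer than 200 bp by construction (the
  number excluded is recorded on the profile object).
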