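---
title: "Mapping regulatory elements from multi-factor ChIP-Seq peak clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regulatory elements from multi-factor ChIP-Seq peak clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfclusters)
```

## The model

Transcription factor binding sites are not spread uniformly along the
genome: peaks called from many independent ChIP-Seq datasets condense
into a much smaller set of co-occupied regions.  `tfclusters` treats
those co-occupied regions — *transcription factor clusters* — as the
operational unit of a regulatory element and builds a complete
data-driven map from them:

1. **Clustering.**  Every peak shorter than the extension length is
   replaced by a window of exactly `extension_length` bp (default
   2,000 bp, the scale of a typical promoter window) centred on its
   midpoint; longer peaks are kept as called.  Peaks whose extended
   intervals share at least one base belong to the same cluster, i.e.
   clusters are the connected components of the extended-interval
   overlap graph.  Because the intervals live on a line, the connected
   components are exactly the merged (reduced) regions, which is how
   `build_clusters()` computes them; the test suite checks this against
   a brute-force O(n²) pairwise-overlap graph.  Regions holding at
   least `min_cluster_size` peaks (default 2) are clusters; the rest
   are singletons.

2. **The shuffle null.**  Observed clustering is compared with a null
   in which every peak keeps its chromosome, length, factor and
   intensity but its start is redrawn uniformly within the chromosome.
   Short reads cannot be mapped everywhere, so the placement space is
   the chromosome length scaled by a mappability factor (default 0.88,
   the standard value for 25-bp tags): starts are drawn from
   `[0, 0.88·L − length]`.  Shuffled peaks may collide; chance overlap
   is the point of the null.  Under genuine co-binding the ratio of
   real to shuffled cluster counts grows quickly with cluster size,
   while shuffled clusters of a given size are *longer* on average than
   real ones, because co-bound peaks sit closer together than chance
   placement allows.

3. **Gene context.**  Promoters are the windows from 2,000 bp upstream
   to 200 bp downstream of each TSS (TSS = `txStart` on "+",
   `txEnd` on "−").  A cluster overlapping a promoter is a *promoter
   cluster*; otherwise, a cluster overlapping a gene body or the window
   up to 10 kb upstream of a TSS is a *gene cluster*; everything else
   is *intergenic*.  Gene annotations are first made nonredundant by
   grouping genes whose exons overlap on the same strand (transitively)
   and keeping the most expressed gene of each group.  Expression
   classes follow a tertile rule: the `floor(n/3)` most expressed genes
   are `high` (transcribed), zero-expression genes are `zero` (silent),
   the remainder `medium_low`.

4. **Transcript vs enhancer.**  Chromatin domains separate clusters
   sitting in transcribed chromatin from candidate long-range
   (enhancer) elements.  A cluster is a *transcript cluster* when it
   overlaps H3K36me3 or Pol II, when it overlaps an H3K4me3 domain that
   itself overlaps H3K36me3 or Pol II (an *isolated* H3K4me3 domain is
   not transcription evidence), or when it overlaps an independent
   Pol III track.  All remaining clusters are *enhancer clusters*.
   Because CTCF and Rad21 have architectural rather than transcriptional
   roles, clusters composed exclusively of those two factors are dropped
   from classification; mixed clusters keep all their peaks.  Broad
   domains are split to at most 5,000 bp for every overlap statistic,
   but classification deliberately consults the full-length domains.

5. **Composition and coverage.**  For any group of clusters the
   *composition vector* holds, per factor, the fraction of clusters in
   the group containing that factor; groups are compared by Pearson's
   r over a shared factor ordering.  The *coverage curve* asks how many
   target regions (typically promoters of an expression class) are
   touched by at least one clustered peak as factors are added one at a
   time, averaged over randomly shuffled factor orders (default 100).
   The *redundancy ratio* of a mark is the number of its regions
   divided by the number of its regions overlapped by a cluster.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `extension_length` | 2000 | bp | promoter-window scale; the merge radius of the clustering |
| `min_cluster_size` | 2 | peaks | intensity-bin analysis shows no confidence gain at 3 |
| `mappability` | 0.88 | fraction | mappable genome fraction for 25-bp tags |
| promoter window | −2000/+200 | bp | the usual annotated-promoter convention |
| `upstream_gene_limit` | 10000 | bp | distal-promoter/5' zone counted as gene context |
| `domain_max_length` | 5000 | bp | puts broad and narrow marks on comparable footing |
| `ocr_merge_gap` | 600 | bp | open-chromatin regions are fragmented; nearby pieces are one site |
| `n_coverage_orders` | 100 | orders | sampling error of the curve mean is well below plotting resolution |
| `n_intensity_bins` | 20 | bins | equal-count quantile bins, so occupancy per bin is interpretable |
| `exclude_factors` | CTCF, Rad21 | — | architectural pair, excluded from transcript/enhancer calls |

Coordinates are 0-based half-open (the BED dialect) at every file
boundary and in every documented contract; in memory the package uses
`GRanges` with the usual 1-based closed convention and converts at the
boundary (`granges0()`, `df0()`).  Overlap always means at least one
shared base; no minimum-width variant is implemented.

## What the synthetic genome emulates

`generate_synthetic()` builds, deterministically from one seed, a
genome whose structure matches what the pipeline assumes about real
data:

* two 10-Mb chromosomes with 200 tandem genes (15–40 kb, 20–30 kb
  apart) in the left part of each chromosome, leaving a gene-free tail;
* zero-inflated log-normal expression (30% zeros, log-normal tail) —
  the expression classes only require a point mass at zero plus a
  continuous positive tail;
* 500 planted elements in five classes: active promoters (at TSSs of
  `high` genes), silent promoters (at TSSs of `zero` genes), genic
  enhancers (≥ 10 kb into gene bodies), intergenic enhancers and
  intergenic transcript units (≥ 50 kb from any gene);
* per-class factor-composition probabilities over 12 factors
  (CTCF, Rad21, TF01–TF10) drive multi-factor peak emission inside each
  element; peak lengths are 150–400 bp and intensities log-normal, so
  quantile binning has non-degenerate quantiles;
* per-class chromatin domains (the nine marks plus OCR) emitted as the
  element interval padded by a mark-specific margin — e.g. 6 kb for
  H3K36me3, so broad domains exercise the 5-kb splitter — with an
  optional dropout probability;
* uniform noise peaks at 5 per Mb.

Element spacing is chosen so that clusters from different elements
never merge (inter-element gaps comfortably exceed the 2-kb merge
radius) and so that, at zero noise and zero dropout, the classification
and context rules recover every planted label exactly.  Silent-promoter
elements emit H3K4me3 and H3K27me3 but no H3K36me3/Pol II; under the
classification rules their clusters are therefore expected to be
labelled `enhancer`, and the manifest records that expectation
(`expected_class`) alongside the element class itself.

What the generator does **not** emulate: read-level noise and peak-call
uncertainty, irregular gene density, overlapping or nested elements,
copy-number structure, distance-dependent co-binding, and the empirical
peak-count scale of ENCODE datasets (thousands of peaks rather than
hundreds of thousands).  Passing tests therefore demonstrate
correctness of the procedures and recoverability under the stated
generative assumptions, not performance on real ChIP-Seq libraries.

## Numerical and design choices

* **Extension** is symmetric about the peak midpoint: peaks carry no
  strand, so a strand-free reading is the only consistent one.  The
  midpoint of `[s, e)` is `⌊(s+e)/2⌋` and the window `[m − t/2,
  m − t/2 + t)`, so the result is exact for even `t` and deterministic
  for odd `t`.  Extended windows clamp (truncate, never shift) to
  chromosome bounds.
* **Cluster regions** are the merged union of the member *extended*
  intervals — consistent with how the overlaps were found — so a
  singleton region is never shorter than the extension length.
* **Domain splitting** proceeds left-to-right in full-length pieces
  with the remainder last; any partition satisfying the bound would do,
  left-greedy is deterministic and conserves total length exactly.
* **Gap merging** measures edge-to-edge distance (`next start − prev
  end`); gap 0 merges only touching or overlapping intervals.
* **Expression ties** at the tertile boundary resolve by descending
  expression then lexicographic id; nonredundant-group ties by highest
  expression, then longest transcript, then id.  The tertile is
  computed over the nonredundant set, since every downstream mapping
  uses nonredundant genes.
* **Multi-gene hits** (a cluster qualifying for several genes) assign
  the gene with the TSS nearest the cluster midpoint; the context label
  itself never depends on the winner.
* **Rule precedence** in classification (H3K36me3, Pol II,
  H3K4me3-linked, Pol III) is fixed only so the recorded provenance is
  reproducible; the class is order-independent, which the tests assert
  via monotonicity.
* **Coverage** counts a target as covered by the *peaks* of the
  selected factor prefix (members of clusters computed once on the full
  factor set, or all peaks in the singleton-inclusive variant).
  Re-clustering per prefix would change cluster identity as factors are
  added.  The curve is a mean over orders, sampled with a fixed seed;
  an exhaustive-enumeration mode (`n_orders = NULL`) exists for small
  factor sets and is what the closed-form tests use.
* **Degenerate inputs**: empty peak sets yield empty cluster sets; an
  empty cluster group yields a flagged zero composition vector; a
  constant composition vector makes `pearson_r()` fail loudly rather
  than return 0; a mark with no occupied region has redundancy ratio 0
  (sentinel) rather than infinity.
* With `min_cluster_size > 2`, merged regions below the threshold are
  returned in the `singletons` slot (the "below threshold" list), so
  the partition identity over peaks always holds.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: the default 20-Mb/500-element genome (~2,400 peaks) for the
null-contrast, recovery and coverage checks; a 72-Mb/900-gene variant
with 300 active promoters for composition recovery; 200 random
instances of up to 500 peaks for the brute-force clustering oracle; and
a 6-Mb miniature for the orchestrated byte-identity runs.  These sizes
keep every check well inside interactive runtimes while leaving the
statistics (binomial fractions, correlation recovery) comfortably away
from their thresholds.

## Known limitations

* The pipeline is purely interval-based: no sequence, no read-level
  processing, no peak calling, and no BigWig/BigBed support.
* Domains are consumed as called intervals; calling them from reads
  (e.g. with an island finder) is upstream of this package.
* Cross-cell-type cluster comparison is out of scope.
* The transcript/enhancer split inherits the known ambiguity that some
  true enhancers recruit Pol II and produce short transcripts; such
  elements are classified as transcript clusters by construction.
* `assign_gene_context()` does not exclude a 10-kb upstream window that
  happens to overlap a *neighbouring* gene's promoter; with the
  synthetic spacings this situation does not arise, and on real data
  the promoter rule wins first anyway.
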