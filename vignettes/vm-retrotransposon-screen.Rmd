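---
title: "Screening retrotransposons for inter-individual methylation variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening retrotransposons for inter-individual methylation variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmscreen)
```

## Background

Intracisternal A-particle (IAP) elements are a young, active family of mouse
endogenous retroviruses (ERVs). A small subset of them behave as metastable
epialleles: their DNA methylation state varies between genetically identical
individuals but is consistent across cells within an individual. `vmscreen`
implements the computational core of a genome-wide screen for such variably
methylated elements (VM elements) from whole-genome bisulphite sequencing
(WGBS) data, in three stages:

1. **Catalogue repair** — RepeatMasker annotates one biological element as
   several fragmented entries; the screen needs accurate element boundaries,
   so fragments are mended back into fully-structured elements.
2. **Variability screen** — per-sample methylation is summarised at element
   edges and elements are ranked by the inter-individual methylation range in
   each cell type.
3. **Sequence enrichment** — k-mer derived sequences over-represented in the
   LTRs of variably methylated elements are assembled and reported.

A seeded synthetic-data generator reproduces the screen's input formats with
known truth, so every stage is testable without any genomic download.

## Catalogue repair

An rmsk-style table is parsed into subelement features (0-based half-open
coordinates throughout) which are grouped by RepeatMasker's element ID into
elements. Subelement roles come from a 25-type registry (15 LTR types, 10
internal types); a name is internal when it ends in `-int`, with `IAPLTR4_I`
an explicit registry exception, and the registry is an overridable
configuration file rather than hard-coded.

Each element is classified by its element-relative (strand-aware) structure:

* `FULL` — internal portion flanked by LTRs on both ends;
* `SOLO_LTR` — LTR feature(s) only;
* `FRAG_NO5`, `FRAG_NO3` — exactly one flanking LTR missing;
* `FRAG_INTERNAL_ONLY` — no LTR at all;
* `FRAG_OTHER` — remaining arrangements.

Two repairs are applied. First, elements split at exact multiples of 500 kb
(a binning artefact of the source table) are re-unified; the match is exact
because the artefact is exact by construction. Second, fragmented elements
are mended: for a missing 5' LTR the heuristic tries, in order, (1) an
adjacent fragment missing its 3' LTR, (2) an adjacent solo LTR, (3) an
adjacent fully-structured element (producing a double or higher-order
element); symmetrically for a missing 3' LTR, and internal-only fragments are
mended on both edges. Partners must face the edge within `max_gap` (default
2000 bp, measured between envelope boundaries; overlapping envelopes count
as adjacent because nested insertions of other elements are common), and
merging never crosses a chromosome or strand.

Several details of the procedure were genuinely open and are fixed here as
package policy: fragments are processed in genomic order with the 5' mend
attempted before the 3' mend; each partner is consumed at most once per pass
and passes iterate to a fixpoint so chains of fragments coalesce; ties among
equally ranked partners go to the nearest and then the 5'-most partner.
These choices make the output deterministic and order-independent, which the
test suite checks against an independent step-wise re-derivation. Two guard
rails handle RepeatMasker's ID reuse: a group is split when one ID spans
chromosomes or strands, and when consecutive features of one ID are more
than 50 kb apart.

## The variability screen

For every element, only the two outward-facing edges are screened (the
internal-facing LTR edges of a full element are skipped). Both outward
edges are windowed for every structure, including solo LTRs, whose two
envelope edges are both outward-facing. The window at an edge holds the 8
CpGs nearest the edge, taken from *inside* the element: the measured object
is LTR methylation, so interior CpGs are the defensible default (a distance
cap of 200 bp is applied instead for the LINE/SINE/non-ERV variant, which
also repairs its annotation only by joining same-class features within
100 bp).

Per sample, the edge methylation is the pooled-count mean: the sum of
methylated calls over the sum of all calls across the window CpGs. The
pooled mean is stabler than the mean of per-CpG fractions under uneven
coverage (the alternative remains available via
`screen_params(mean_method = "per_cpg")`). A sample is *informative* at an
edge only with at least 20 calls over the window and at least 4 covered
CpGs; an edge survives only with at least 5 informative samples in every
cell type. The per-cell-type *range* is max minus min of informative
samples' means, with no trimming of extremes.

The candidate rule combines the group ranges conservatively: the screen
statistic is the *minimum* of the per-group ranges (variability must be
present in every cell type), and an edge is a candidate when it passes the
sample filter and the statistic reaches the 10% threshold. The maximum rule
is available via `screen_params(statistic = "max")` for tissue-specific
behaviour. Raw counts always take precedence over the percentage column of
coverage files, records on the two strands of a CpG dyad are pooled onto the
plus-strand C, and a sample with no data at an edge is uninformative rather
than an error.

## Sequence enrichment in candidate LTRs

Foreground is the set of oriented 5' LTR sequences of candidate elements
(for a solo LTR, its single LTR); background is the remaining 5' LTRs.
All 15-mers present in at least two foreground LTRs are enumerated by
presence (a k-mer counts once per sequence), skipping k-mers containing N.
Counting is on the oriented strand only — LTR regulatory sequence is
orientation-specific — with `kmer_params(canonical = TRUE)` available.

Fold enrichment is the ratio of presence fractions; a zero background
presence is replaced by a pseudocount of 0.5 so that enrichment stays finite
and trimming comparisons remain ordered. K-mers present in at least 5
foreground LTRs with at least 20-fold enrichment are grouped into connected
components under the k−1 overlap relation and each component is laid out
along a maximal simple path of its overlap graph, giving the shortest
superstring consistent with the overlaps. On branching graphs the path
maximising total foreground presence wins and left-over members are
regrouped recursively, so the procedure is deterministic and every k-mer
ends up in some extended sequence. Each extended sequence is trimmed to the
substring (length ≥ 10, avoiding trivially promiscuous substrings) that
maximises fold enrichment, ties going to the longer and then the 5'-most
substring. Final sequences are flagged against a 2% genome-wide presence
cap, and reports include per-set presence counts and the number of
foreground LTRs containing at least one sequence.

## The synthetic test bed

`sim_params()` fixes the simulated study conditions:

* **Design** — 8 individuals × 2 cell types (`B`, `T`), one WGBS sample per
  individual per cell type.
* **Elements** — LTR–internal–LTR (300/1500/300 bp) with identical flanking
  LTRs per element; 20% solo LTRs; LTRs are mutated copies (5% per-base) of
  a family consensus with a CG imposed every 25 bp so edge windows always
  have CpGs; element strands are random, which exercises all strand-aware
  logic.
* **Coverage** — per CpG and sample, totals are Poisson(10) and methylated
  calls Binomial at the true level. Poisson coverage is the simplest model
  with the right failure modes: zero-coverage CpGs and uninformative
  samples arise naturally.
* **Regimes** — background (`HYPER`) levels are Beta(380, 20) per element
  and sample (mean 0.95, ≈1% spread), reflecting uniformly hypermethylated
  non-variable elements. Constitutively variable loci (`CVM`) draw one
  Uniform(0.05, 0.95) level per individual shared across cell types —
  mimicking the observed near-0-to-near-1 spread of metastable epialleles.
  Tissue-specific loci (`TSVM`) are variable in the first group only and
  hypermethylated in the others, matching the dominant observed class.
* **Fragmentation** — with probability `fragmentation_rate` an element's
  annotation is split at subelement boundaries into fresh element IDs, with
  up to 150 bp eroded at each split (all gaps stay below the 2000 bp mending
  reach); 500 kb boundary splits can be injected explicitly.
* **Seeding** — one global seed feeds a named stream per operation, so
  adding operations never shifts existing draws; a run is byte-identical
  given `(params, seed)`.

What the generator does *not* emulate: sequence divergence between repeat
families, genuine (biological) fragmentation, bisulphite conversion error,
read-level artefacts, and correlated coverage along reads. Passing tests
therefore demonstrate the algorithmic correctness of the pipeline under the
stated noise model, not its end-to-end performance on real WGBS data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
mend round-trips use 200-element catalogues, screen recovery uses 10 planted
variable loci among 200 hypermethylated ones at 10× coverage (where
sensitivity and specificity at the 10% threshold both exceed 95%), and
motif recovery plants one 15-mer in 5 of 51 foreground LTRs against 1000
background LTRs. Genome-scale inputs (the mm10 RepeatMasker table and
genome) are deliberately not required anywhere.

Degenerate inputs are handled explicitly: an element with no internal CpGs
yields empty windows (flagged, not an error); an edge absent from a sample's
coverage is uninformative; an extended sequence shorter than the trimming
floor is returned untrimmed with a flag; an empty catalogue summarises to
zeros. One caveat found during development: absorbing a solo LTR into an
internal-only fragment whose other edge stays unmended can *raise* the
fragmented proportion even as the element count falls, so monotonicity of
the fragmented fraction holds for structured catalogues but not for
arbitrary adversarial inputs.

## Worked example

```{r example, eval = FALSE}
library(vmscreen)

## a complete synthetic dataset with known truth
ds <- simulate_vm_dataset(
  sim_params(n_elements = 30, vm_fraction = 0.2, fragmentation_rate = 0.4,
             motif = "ACGTGACCTTGAGCA", n_carriers = 5, seed = 5),
  dir = "demo_data")

## end-to-end: mend -> screen -> extract LTRs -> k-mers
res <- run_pipeline(list(annotation  = ds$paths$annotation,
                         genome      = ds$paths$genome,
                         sample_sheet = ds$paths$samples,
                         out_dir     = "demo_out"))
res$manifest$counts

## or stage by stage
cat0 <- group_into_elements(parse_rm_annotation(ds$paths$annotation))
summary(cat0)                       # fragmented before mending
mended <- mend_fragmented(patch_boundary_splits(cat0))
summary(mended)                     # truth catalogue recovered

scr <- screen_catalogue(mended,
                        lapply(ds$coverage, read_coverage),
                        ds$samples,
                        cpg_positions = find_cpg_sites(ds$genome))
screen_candidates(scr)
```

## Limitations

* The mending heuristic is annotation repair, not sequence re-alignment: it
  cannot recover elements whose fragments lie more than `max_gap` apart, and
  it trusts subelement typing.
* The candidate rule (minimum over group ranges at 10%) is one defensible
  reading of a two-cell-type screen; tissue-specific discovery needs the
  `max` statistic plus downstream per-tissue validation, which is out of
  scope here.
* Overlap-graph merging resolves branches greedily by foreground presence;
  alternative superstrings consistent with the same overlaps exist on
  branching graphs.
* Genome-wide cataloguing of mm10 IAPs requires the mm10 RepeatMasker
  table and genome as inputs; the package's own tests and acceptance script
  run entirely on synthetic data.
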