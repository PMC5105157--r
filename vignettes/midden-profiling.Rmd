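---
title: "Profiling midden sedaDNA: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling midden sedaDNA: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedaprof)
library(dplyr)
```

Archaeological middens preserve DNA from the tissues, excreta and bones that
accumulated while a site was occupied. Shotgun sequencing of such sediments
yields short, degraded fragments from a mixture of taxa; the analytical
problem is to turn those reads into per-layer faunal profiles that can be
compared with the zooarchaeological bone record, while demonstrating that the
signal is ancient rather than modern contamination. `sedaprof` implements
that pipeline end to end and ships a generative counterpart — a read
simulator with known ground truth — so every stage can be validated without
any external database.

## The pipeline at a glance

1. **Pre-processing**: exact-duplicate removal, a minimum-length filter and a
   DUST-style low-complexity filter.
2. **Alignment** of surviving reads against a taxid-tagged organelle
   reference panel.
3. **Taxonomic assignment**: reads with a single best alignment go to that
   reference's taxon; reads with several equally good alignments go to the
   lowest common ancestor (LCA) of the tied taxa.
4. **Profiles**: restriction to vertebrates at family rank or lower, merging
   of libraries from the same stratigraphic layer, collapsing of redundant
   higher-order taxa, relative abundances and vertebrate DNA concentration.
5. **Authentication**: per-taxon 5' C->T misincorporation frequency.
6. **Comparison**: Bray-Curtis/NMDS ordination of layers, and Pearson
   correlation of read counts with bone-derived quantities (NISP, MNI,
   expected biomass).
7. **Consensus**: majority-rule consensus of reads realigned to a single
   reference, with coverage depth.

## Filters and their thresholds

All thresholds are exposed but default to the values the pipeline was
designed around:

* **Duplicates** — a read is discarded when its sequence is an exact copy
  (same sequence, hence same length) of an earlier read. The comparison is
  deliberately strand-naive and quality-blind; reverse complements are kept.
* **Length** — reads shorter than 25 nt are discarded; a 25-mer survives.
  Shorter fragments cannot be placed confidently in a eukaryote-scale
  reference set.
* **Complexity** — for each 64 nt window (or the whole read when shorter),
  with triplet counts $c_t$ over the 64 trinucleotides, the window score is
  $\sum_t c_t(c_t-1)/2 \,/\, (w-3)$ and the read score is the maximum over
  windows; reads scoring above 1 are dropped (exactly 1 survives). A
  64 nt homopolymer scores 31; uniform random sequence almost surely scores
  well below 1. The normalisation is this package's documented convention,
  chosen so results are reproducible bit for bit; other DUST
  implementations scale the same statistic differently.
* **Alignment quality** — hits with edit distance above 5% of the read
  length are discarded; equality survives (5 edits on a 100 nt read pass,
  6 do not). Soft-clipped bases count toward read length.
* **Damage reporting** — per-taxon damage estimates are suppressed below
  500 qualifying reads; terminal-substitution frequencies from fewer reads
  are too unstable to interpret.

## Assignment model

Ties are defined on edit distance (the `NM` value), not on a mapper-specific
alignment score: the pipeline's own quality filter is stated in edit
distance, and edit distance is reproducible across aligners. Multiple
placements of one read on the *same* reference collapse to a single vote, so
long references cannot dominate an LCA. Reads whose accession lacks a taxid
mapping are dropped with a logged count (the fate of records mapped to
obsolete identifiers). Assignments above family rank within vertebrates stay
in the raw table for audit but are excluded from profiles; `"no rank"` nodes
(e.g. Vertebrata itself) resolve rank thresholds through their nearest
ranked ancestor, since taxonomy dumps interleave unranked clades and no
published rule exists for them.

For collapsing, the package applies the name-based rules used for display
(Bos/Bovinae to *Bos*; Canis, *C. lupus*, *C. l. familiaris* to *C. lupus*;
Pusa and *P. hispida* to *P. hispida*; Balaenidae and *B. mysticetus* to
*B. mysticetus*; Cervidae, Odocoilinae, *R. tarandus* to *R. tarandus*), and
offers an automatic generalisation: any ancestor node whose counts can only
belong to one species with nonzero counts in the data set is folded into
that species. Uniqueness is judged across the whole profile (all sites and
layers), matching the "represented by a single species in the data set"
reading; a rule whose source and target are not on one lineage is suspicious
and warns, but is still applied as written.

## The damage model and its estimator

Post-mortem cytosine deamination concentrates in single-stranded fragment
overhangs, read out as C->T substitutions at the 5' terminus. The simulator
applies C->T at read position $p$ with probability
$d_1 \cdot \lambda^{p-1}$ ($d_1$ = terminal rate, $\lambda \in (0,1)$ the
geometric decay per position), on the sequenced strand, after fragment
excision and before sequencing error. A mirrored 3' G->A channel exists but
is off by default, since the reported statistic is the 5' C->T frequency
only.

The estimator conditions on the reference base: among reads whose chosen
best alignment pairs the read's 5'-terminal base with a reference C, it
reports the fraction carrying T. Reverse-strand alignments use the reverse
complement of the reference window, so "position 1" is always the read's
sequenced 5' terminus. Two geometry rules matter in corner cases and are the
package's own choices: reads whose 5'-terminal CIGAR operation is not a
match/mismatch are excluded (an indel or clip pairs no reference base
there), and when several references tie, the alignment used for geometry is
chosen deterministically (lexicographically smallest accession, then
position). The per-position profile (`ct_profile()`) additionally restricts
to gapless alignments so interior positions are exact.

One tie-break deserves a note. When damage creates a terminal mismatch, an
equal-cost alignment often exists that trades the mismatch for a terminal
indel (skipping the mismatching reference base and pairing the damaged base
with a coincidentally matching neighbour). Preferring "longest" or "first"
placements silently selects such variants often enough to bias the damage
estimate downward by almost half on one strand. `best_hits()` therefore
prefers the placement with the fewest indel bases in its CIGAR, which keeps
the substitution-only interpretation whenever one exists; with that rule the
estimator is unbiased and strand-symmetric in simulation across terminal
rates from 0 to 0.13, the range relevant for reported midden damage
(roughly 0-13%).

## Ordination and correlation

Bray-Curtis dissimilarity is computed from the definition
$1 - 2\sum_i \min(u_i, v_i) / (\sum u + \sum v)$ and cross-checked against
`vegan::vegdist` in the tests. NMDS is delegated to
`vegan::metaMDS`/`monoMDS` (Kruskal stress-1, monotone regression, 20 seeded
random starts by default) — the standard implementation in community
ecology; `layout_stress()` exposes the same stress function for arbitrary
configurations so fitted ordinations can be compared against random layouts.
Correlations use the Pearson statistic with the two-sided $t$ p-value on
$n-2$ degrees of freedom, computed on raw read counts by default (a
`log10(x+1)` option exists). MNI extrapolation multiplies by the reciprocal
of the excavated fraction rounded to one decimal — an 8.7% sample gives the
factor 11.5.

The shipped biomass table
(`inst/extdata/synthetic_biomass_qeqertasussuk.tsv`) is a synthetic
stand-in with plausible arctic-midden magnitudes; the original
excavation-monograph table it emulates is not redistributable here. It
exercises the correlation machinery (species alignment, exclusion
reporting, scaling); correlations against it are demonstrations, not
reproductions of published coefficients. The bone-count table
(`site_bone_counts.tsv`) carries the printed cetacean find counts, from
which the Qajaa cetacean share (3 of ~15,000 bones, 0.02%) is recomputed.

## The synthetic-data generator

`make_toy_taxonomy()` builds a fixed ~56-node tree shaped like the NCBI
dumps: arctic and Norse-farm mammals (bowhead whale, harp and ringed seal,
canids, livestock, caribou, hares) under Vertebrata, plus the tapeworm and
roundworm families whose species corroborate their vertebrate hosts. Three
genera (*Lepus*, *Taenia*, *Toxocara*) carry two species each;
`make_reference_panel()` plants a shared identical backbone over the first
30% of congeneric references so that genuinely ambiguous reads — and hence
above-species LCA assignments — occur at a realistic rate, while all other
reference pairs stay at Hamming distance >= 10% of their length.

Defaults encode the study conditions the pipeline targets: fragment lengths
normal with mean 60 nt, sd 15, truncated at 25 nt (the length filter's
floor); uniform strand; terminal damage $d_1 = 0.10$ with decay
$\lambda = 0.5$, inside the elevated range reported for authentic layers;
sequencing error $10^{-3}$ per base after quality trimming; 10% exact PCR
duplicates; 2% homopolymer/dinucleotide contaminant reads; constant Q37
qualities (quality trimming is upstream and out of scope). Reference length
defaults to 16 kb — mitogenome scale. That last choice matters more than it
looks: with toy-length (1 kb) references, independent reads frequently
coincide in locus, length and strand, so "exact copy" deduplication removes
a noticeably larger share of abundant taxa and distorts recovered
abundances; at 16 kb the coincidence rate is realistic and the distortion is
well inside counting noise.

What the generator does *not* emulate — population-level sequence variation
within a taxon, indel-type damage, chimeric library artefacts, GC-dependent
error — bounds what passing tests show: they validate the pipeline's
bookkeeping, filters, estimator calibration and classification logic on
reads whose generative process is known, not robustness to every artefact of
real sequencing.

## Numerical and scale choices

The built-in aligner is exact semi-global dynamic programming (read
consumed end to end, free reference ends, unit costs), with a pigeonhole
seed-and-verify fast path: an alignment with at most $k$ edits must contain
one of $k+1$ contiguous read pieces exactly, so 11-mer seed hits locate
every candidate window and windowed DP verifies them. The fast path is
provably equivalent to the full scan (both are exposed and the tests assert
identical hit sets) and keeps 50,000 reads against a 16-reference
mitogenome-scale panel under ten seconds. It is still a transparent test
aligner for desk-scale panels, not a replacement for a production mapper.

Problem sizes used by the validation suite were chosen to give comfortable
statistical resolution: 50,000 reads for mixture recovery (binomial SE
about 0.24 pp on the dominant taxon), 10,000 reads per point for damage
calibration (SE about 0.6 pp on the terminal frequency), six layers for
ordination, and a 5.8x library for consensus. Deterministic tie-breaks are
documented where they bite: consensus ties call `N` rather than the
reference base (avoiding reference bias), deletions leave a position
unobserved, insertions have no consensus coordinate, and uncovered or
below-`min_depth` positions call `N` (`min_depth` defaults to 1; no
published minimum exists for the consensus depth rule, so it is
configurable). NMDS restarts and seeds are recorded in the result object.

## Worked example

```{r example, eval = FALSE}
tree <- make_toy_taxonomy()
cfg <- pipeline_config(
  seed = 11,
  libraries = list(
    list(library_id = "SED1", site = "Qeq", layer = "A",
         sim = list(n_reads = 5000,
                    mixture = c("30" = 0.6, "31" = 0.4))),
    list(library_id = "HEL1", site = "Qeq", layer = "A",
         library_type = "helminth",
         sim = list(n_reads = 2000, mixture = c("50" = 0.7, "51" = 0.3)))
  ),
  damage_min_reads = 500
)
res <- run_pipeline(cfg)
res$profile
res$damage
helminth_unique_counts(res$assignments, tree,
                       c("Taenia hydatigena", "Taenia multiceps"))
```

## Known limitations

* The reference panel is one sequence per leaf taxon; within-taxon
  diversity, numts and partial references are not modelled, so real-data
  ambiguity rates will differ from the toy panel's.
* The LCA is unweighted; no probabilistic reassignment of ambiguous reads is
  attempted.
* Damage estimation pools reads across tied references after a
  deterministic choice; whether such pooling biases estimates for deeply
  diverged reference sets is flagged but not resolved here.
* `exhaustive_align()` scales linearly in panel size and is meant for
  dozens of references; genuine database-scale mapping should come from a
  production aligner, whose SAM output `read_sam()` ingests directly.
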