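# sedaprof

Taxonomic profiling of sedimentary ancient DNA (sedaDNA) from archaeological
middens.

Midden deposits accumulate DNA from the animals people butchered, ate and
lived with. Shotgun sequencing of such sediment yields short (~30–100 nt),
damaged fragments from a mixture of taxa. `sedaprof` is an R package for
archaeogeneticists and computational biologists who want to turn those reads
into per-layer faunal profiles and check them against the bone record:

* **LCA read assignment** — reads are aligned against a taxid-tagged
  organelle reference panel; a read with a single best alignment (by edit
  distance, `NM`) is assigned to that taxon, a read with several equally
  good alignments to the **lowest common ancestor** of the tied taxa.
* **Degraded-library filters** — exact-duplicate removal (same sequence and
  length), a minimum-length filter (< 25 nt discarded), a DUST-style
  low-complexity score (windowed triplet statistic
  `Σ c_t(c_t−1)/2 / (w−3)`; reads scoring > 1 discarded), and an
  edit-distance filter (> 5 % of read length discarded).
* **Ancient-DNA authentication** — the per-taxon frequency of C→T
  substitutions at the read 5′ terminus (post-mortem cytosine deamination),
  reported only for taxa with ≥ 500 qualifying reads.
* **Profiles and comparison** — library merging per stratigraphic layer,
  taxon collapsing, relative abundances, vertebrate DNA concentration
  (reads per million analysed), Bray–Curtis dissimilarity
  (`1 − 2Σmin(u,v)/(Σu+Σv)`) with NMDS ordination (Kruskal stress-1, via
  vegan), Pearson correlation of read counts with zooarchaeological NISP /
  MNI / expected-biomass tables, and MNI extrapolation by the reciprocal of
  the excavated fraction (8.7 % → factor 11.5).
* **Consensus assembly** — majority-rule pileup consensus against a single
  reference with per-position coverage depth.
* **Synthetic data with ground truth** — a toy arctic-midden taxonomy
  (whales, seals, canids, livestock, caribou, hares; tapeworm and roundworm
  parasites), a mitogenome-scale reference panel with planted congeneric
  backbones, and a read simulator with terminal deamination, sequencing
  error, PCR duplicates and low-complexity contaminants — so the whole
  pipeline validates against known truth without any download.

The package is tidyverse-native: functions take tibbles and return tibbles,
results plot with `autoplot()`/`plot_*()`, and fitted objects support
`tidy()`/`glance()`.

## Worked example

```r
library(sedaprof)

cfg <- pipeline_config(
  seed = 11,
  libraries = list(
    list(library_id = "SED1", site = "Qeq", layer = "A",
         sim = list(n_reads = 5000, mixture = c("30" = 0.6, "31" = 0.4)))
  )
)
res <- run_pipeline(cfg)
res$profile
#> # A tibble: 2 × 8
#>   site  layer taxid name                     rank    count total_reads_analysed fraction
#>   <chr> <chr> <int> <chr>                    <chr>   <int>                <int>    <dbl>
#> 1 Qeq   A        30 Balaena mysticetus       species  2612                 4383    0.596
#> 2 Qeq   A        31 Pagophilus groenlandicus species  1770                 4383    0.404

res$damage
#> # A tibble: 2 × 5
#>   taxon                    taxid n_reads_used n_ref_c freq_ct_pos1
#>   <chr>                    <int>        <int>   <int>        <dbl>
#> 1 Balaena mysticetus          30         2612     633       0.106
#> 2 Pagophilus groenlandicus    31         1770     448       0.0759
```

Of 5000 simulated reads, 4383 survive deduplication, the length filter and
the low-complexity filter; the recovered relative abundances (59.6 % bowhead
whale, 40.4 % harp seal) match the configured 60/40 mixture within counting
noise, and both taxa show a terminal C→T frequency scattered around the
simulator's default damage rate (`damage_d1 = 0.10`, estimated here from 633
and 448 reference-C termini respectively) — the signature that authenticates
reads as ancient.

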