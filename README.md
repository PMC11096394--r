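# palaeomt

Curation, sharing phylogeography and coalescence dating of human
mitochondrial control-region (HVS-I) haplotypes.

Classic ancient-DNA datasets of mtDNA HVS-I haplotypes — PCR-amplified in
short overlapping fragments and Sanger-sequenced — carry characteristic
laboratory artefacts: partial contamination, *chimeric* haplotypes stitched
together from two templates across amplicons, *phantom mutations* recurring
on unrelated haplogroup backgrounds, and amplicon dropout that truncates
haplotypes into apparent novelties. `palaeomt` is for researchers
re-analysing such legacy data (its motivating case is the indigenous
maternal gene pool of a drift-dominated island archipelago): it curates the
haplotypes with an auditable rule set, analyses haplotype *sharing* rather
than drift-inflated frequencies, and dates founder lineages with the rho
statistic under a fast mutation clock.

## The core machinery

* **Variant-string parsing** of the field's minus-16000 notation
  (`"093 192"` = 16093 + 16192; letter suffixes for recorded derived bases,
  `@pos` for back mutations, parentheses for unscored positions), site
  filtering (16519 hotspot; indels around 309/522/573/16193) and rCRS-style
  coordinate scoring of aligned sequences.
* **Motif classification**: haplogroups form a rooted tree with private
  diagnostic variants per edge; a haplotype is scored against each
  cumulative motif by `|shared| − |missing·scored| − |extra|`, with untyped
  sites never penalized.
* **Curation**: verdicts partition a dataset into *clean*, *incomplete*
  (variants ⊂ motif, missing sites unscored or in terminal amplicons),
  *chimera* (a minimum-cost two-haplogroup decomposition
  `2·|unexplained| + 1·|missing|` beats the single-haplogroup reading) and
  *phantom-bearing*; dataset-wide phantom detection requires recurrence on
  phylogenetically independent backgrounds.
* **Sharing phylogeography**: binary presence matrices, Venn partitions,
  persistence fractions, exclusive-region labels, match-based distances
  (Jaccard `D = 1 − |A∩B|/|A∪B|` on presence sets, min-normalised
  alternative), classical PCoA, and exact Fisher / sign / Welch tests.
* **Rho dating**: `ρ = Σdᵢ/n` founder-to-member differences;
  `age = ρ × 1400` years (95% CI of the clock 1261–1539, i.e.
  4.33 × 10⁻⁸ mutations/site/year); statistical error by site bootstrap
  (B = 3600 column resamplings, percentile CI); calendar conversion
  (`year = 2000 − age`) and settlement-wave grouping at the largest age
  gaps.
* **Synthetic data with known truth**: simulated motif panels, continental
  pools, Wright–Fisher-drifted island populations across epochs, injected
  chimeras/dropout/phantoms over the seven-amplicon layout, and star or
  coalescent founder clades of known age — every stage of the pipeline is
  testable offline.

## Worked example

```r
library(palaeomt)

panel <- loadMotifPanel(system.file("extdata/motif_panel.tsv",
                                    package = "palaeomt"))
hs <- applySiteFilter(parseVariantString(
  c(gm1 = "126 255 292 294", gm2 = "239 278",
    gm3 = "145 176G 223 297 311")))
cur <- curateDataset(hs, panel)
cur$report[, c("id", "detected", "verdict", "hg_primary",
               "most_probable", "contaminator", "hg_contaminator")]
#>    id             detected    verdict hg_primary                  most_probable
#> 1 gm1      126 255 292 294    chimera        T2c              16126 16292 16294
#> 2 gm2              239 278 incomplete     U6a1a1                    16239 16278
#> 3 gm3 145 176G 223 297 311      clean     N1b1a7 16145 16176G 16223 16297 16311
#>   contaminator hg_contaminator
#> 1  16126 16255            J1c1
#> 2                         <NA>
#> 3                         <NA>
```

Reading the report: `gm1` is a chimera whose most probable indigenous
component is the T2c motif `16126 16292 16294`, contaminated by a
`16255`-bearing J1c-derived haplotype; `gm2` is an incompletely sequenced
U6a1a1 (its diagnostic 16172/16219 sites lie in amplicons upstream of the
observed variants); `gm3` matches the N1b1a7 motif exactly and is clean.

Dating a simulated 2000-year-old star clade of 50 lineages:

```r
sim <- simulateClade(T_years = 2000, nTips = 50, genealogy = "star",
                     nSites = 1000, seed = 11)
bs <- bootstrapRho(sim$clade, B = 3600, seed = 12)
ageFromRho(bs$rho, rhoCI = bs$ci, n = 50, replicates = 3600L)
#> AgeEstimate: rho = 1.140 (n = 50) -> 1596 ya [95% CI 1204-2044]
toCalendar(1596)
#> [1] "404 AD"
```

The point estimate is `ρ × 1400` = 1596 years; the interval is the
2.5–97.5 percentile of 3600 site-bootstrap replicates (a single 50-tip
draw scatters around the truth with SD ≈ `1400·√(ρ/n)` ≈ 210 years, which
is exactly what the interval reflects).

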