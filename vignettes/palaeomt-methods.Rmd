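---
title: "Curation, sharing phylogeography and rho dating of mtDNA control-region haplotypes"
author: "palaeomt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation, sharing phylogeography and rho dating of mtDNA control-region haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeomt)
```

## The problem

Ancient-DNA studies of human mitochondrial control-region (HVS-I) haplotypes
built on PCR amplification and Sanger sequencing are vulnerable to three
laboratory artefacts: contamination of a sample by a second haplotype,
*chimeric* haplotypes assembled from two templates across overlapping
amplicons, and *phantom mutations* — sequencing errors that recur on
unrelated haplogroup backgrounds. When the HVS-I window is amplified in
seven short overlapping fragments, amplicon dropout additionally truncates
haplotypes, and a truncated haplotype can masquerade as a novel lineage.
`palaeomt` implements a rule-based curation of such datasets, a
haplotype-sharing phylogeography (match sets, exclusive-region
classification, match-based distances with principal coordinates), and
rho-statistic coalescence dating with a site bootstrap under a fast
mutation clock. The motivating system is the indigenous maternal gene pool
of an island archipelago settled from a nearby continent, where strong
founder drift makes frequency-based statistics unreliable and
presence/absence sharing is the more robust signal.

## Data model

A **variant** is one scored difference from the reference sequence, held as
a compact token in 1-based reference coordinates: `16093` (transition),
`16111A` (substitution with recorded derived base), `@16124` (back
mutation), `16166d` (deletion), `16193.1C` (insertion). HVS-I tables use
the minus-16000 shorthand; `parseVariantString()` adds the offset to
positions below 1000, records parenthesized tokens as *unscored* positions,
and returns a `HaplotypeSet` whose canonical identity is the filtered
variant set within the comparison window — unscored positions never
contribute to identity. The `siteFilter()` defaults exclude the 16519
hotspot outright and indel variants within ±3 positions of 309, 522, 573
and 16193 (substitutions at those positions are kept); the source material
says "indels around" these anchors without a radius, so the radius is a
configurable choice.

The HVS-I comparison window is `16001–16400` inclusive at both ends. The
published range statement does not say whether 16400 itself is included; we
include it (the bound is an argument of `restrictToWindow()`), since
diagnostic positions such as 16399/16400 appear in published haplotypes.

A **motif panel** is a rooted haplogroup tree in which each node carries
the private diagnostic variants of its edge; `cumulativeMotif()` unions the
root path with back-mutation cancellation. This is deliberately a
*simplified stand-in* for full phylogeny-database classification: the
packaged `motif_panel.tsv` encodes roughly 50 haplogroup motifs exactly as
their HVS-I strings are printed in the source tables (plus a few
coding-region diagnostics), not the complete reference phylogeny.
Classification ranks candidates by

`score = |shared| − w_miss·|missing, sequenced and scored| − w_extra·|extra|`

with `w_miss = w_extra = 1`. The weights are symmetric because the source
gives no scoring scheme; ties break towards shallower tree depth (the less
committed call) and then lexicographically. Motif sites outside the
sequenced range or among the unscored positions never penalize — that is
what lets `(172 219) 239 278` classify cleanly despite two untyped
diagnostic sites.

## Curation rules

Verdicts partition a dataset into `clean`, `incomplete`, `chimera` and
`phantom_bearing`, decided in this order per haplotype:

1. **Clean**: the variant set equals some cumulative motif exactly — unless
   a deeper motif completes the haplotype entirely within the *unscored*
   positions, in which case the deeper clade cannot be excluded and the
   haplotype is reported incomplete. This exception is what recovers
   dropout events whose lost variants leave an exact ancestor motif behind.
2. **Incomplete**: the variants are a proper subset of some motif and every
   missing site is unscored or lies in a terminal segment of the window
   (outside the span of the observed variants). The terminal-segment
   reading reflects amplicon dropout under the seven-fragment design:
   absence *interior* to the observed span is real evidence against the
   clade, absence beyond the outermost observed variant is not. The
   minimal-missing completing haplogroup is reported.
3. **Chimera**: novel variants exist and a two-haplogroup decomposition
   beats the single-haplogroup reading. The decomposition minimises
   `w_unexplained·|variants in neither motif| + w_missing·|scored motif
   sites absent from each component|` over haplogroup pairs, with
   `w_unexplained = 2 > w_missing = 1` so that explaining variants by a
   second real haplotype is preferred over declaring them novel. Shared
   ancestral variants may belong to both components. At equal cost the
   search prefers full coverage (fewer unexplained), then the primary with
   the higher regional-panel frequency, then lexicographic order; the
   candidate set is pruned to haplogroups sharing at least one variant with
   the input.
4. **Phantom-bearing**: everything else with novel variants.

Dataset-wide, `detectPhantoms()` flags a novel variant recurring on at
least two *independent* backgrounds. Independence needs care on HVS-I,
where shallow haplogroups are often indistinguishable: each occurrence
contributes its full set of top-scoring candidates, two occurrences are
independent when some candidate pair is neither ancestor nor descendant in
the tree, **and** carriers whose variant backgrounds are nested (one a
subset of the other) never count as separate backgrounds — nested
haplotypes are plausibly one lineage observed at two resolutions. Without
the candidate-set rule, an ambiguous `H/HV/U/R`-type carrier would always
resolve to the tree root and could never be independent of anything;
without the nested veto, a clade and its own derived haplotype would count
as two backgrounds whenever a deep candidate's diagnostics are
coding-region only.

## Sharing phylogeography

`buildPresenceMatrix()` reduces observations to a binary haplotype ×
population matrix (counts kept as an attribute); `vennPartition()` counts
exact intersection cells for 2–3 population groups; `persistenceFraction()`
reports both denominators for the survival of an earlier pool in a later
one, because published persistence percentages can be read either way.
`exclusiveRegionLabels()` assigns each haplotype the single region group
containing all of its continental presences, or `shared`/`none`.

`matchDistance()` implements the match-based population distance on
presence sets: the referenced formula is not reproduced in the source, so
the default is Jaccard dissimilarity `1 − |A∩B|/|A∪B|` — the standard
sharing dissimilarity, a semimetric on presence sets that preserves the
qualitative ordination geometry — with a min-normalised alternative
(`1 − |A∩B|/min(|A|,|B|)`) behind a flag. Two modes mirror the two
published analyses: `shared_indigenous` restricts rows to a reference
haplotype set; `own_pool` compares full pools. `pcoaAnalysis()` is
classical metric scaling (Gower double-centering, eigendecomposition,
coordinates scaled by the square root of the positive eigenvalues) via
`stats::cmdscale`; negative eigenvalues are reported, not used, and no
correction is applied by default (Cailliez and Lingoes are options).

The exact tests are the ones a practitioner would reach for: Fisher's
exact 2×2 p as the sum of hypergeometric probabilities not exceeding the
observed table's; the sign test as a doubled binomial tail capped at 1
(the convention matters only for near-balanced counts); Welch's t with
Satterthwaite degrees of freedom, with the degenerate zero-variance case
pinned to p = 1 for equal means.

## Coalescence dating

For a founder clade, `rhoStatistic()` is the mean number of masked-site
differences between the founder haplotype and each member. The clock is
the fast rate for shallow phylogenies: one mutation per lineage every 1400
years (95% CI 1261–1539), equivalently 4.33e-8 mutations/site/year (95% CI
3.90–4.82e-8). The two printed numbers jointly imply an effective sequence
length near 16,500; `clockModel()` therefore carries
`effectiveLength = round(1/(1400 × 4.33e-8)) = 16496` as an explicit field
rather than assuming the full molecule length. Ages are exactly
`rho × 1400`.

Statistical error comes from a **site bootstrap**: each of B = 3600
replicates (the published replicate count; tests scale to 500 for speed)
resamples the masked alignment columns with replacement and recomputes
rho; the 95% CI is the 2.5–97.5 percentile interval. Clock uncertainty is
*not* folded in by default — the published per-lineage intervals are far
narrower than the clock CI would produce, so they must be rho-bootstrap
intervals; `propagateClockCI = TRUE` multiplies the rho bounds by the
clock bounds when both sources are wanted. The implementation draws one
multinomial weight vector per replicate and reduces the per-member
difference matrix by a single matrix product, so B = 3600 on a 50-tip
clade costs milliseconds. When no founder is supplied it is reconstructed
as the modal state per masked site (a token carried by more than half the
members); deeper root reconstruction is out of scope.

Calendar conversion uses reference year 2000: all three published
period/mean-age pairs are consistent with `year = 2000 − age`
(2000−1876 = 124, 2000−883 = 1117, 2000−570 = 1430). Ages before year 1
print as `(1−year) BC`.

`groupWaves()` partitions lineage ages into k waves at the k−1 largest
gaps between consecutive sorted ages — a deterministic, assumption-free
reading of "grouping by relative proximity"; model-based 1-D clustering
was rejected as harder to audit for the same answer. Per group it reports
the mean age, a t-interval across member ages, the calendar period of the
mean, and Welch tests between adjacent groups. Whether published group
intervals are pooled bootstrap or across-lineage intervals is unstated, so
both the per-lineage bootstrap CIs and the across-lineage t-intervals are
emitted and neither is asserted against published values.

## The synthetic-data generators

`simConfig()` fixes the study conditions: 288 indigenous HVS-I
observations across seven islands (sample sizes 80/80/40/40/20/14/14),
continental screening panels totalling 3246 northern African and 10,960
European sequences, the seven-fragment amplicon design, artefact rates of
0.1 chimera / 0.1 dropout with two phantom sites of five carriers each,
and a three-wave founder-clade set (ages 1900/900/500 years; 5/4/6 clades;
150 tips each). Island founder sizes (15–40) and 40 generations of
multinomial Wright–Fisher resampling at small population size (80–300)
produce the strong drift the archipelago is known for; the later epochs
mix in European immigration (50% historic, 70% current) so that
persistence of the indigenous pool declines across epochs. Where the
source states a number (sample sizes, panel sizes, replicate counts, the
clock) the default *is* that number; the remaining defaults are one-time
choices of realistic magnitudes and are not tuned.

The generators assume infinite sites within a run — no recurrent hits
inside a panel or clade — which keeps truth labels exact, and artefact
truth is *effect-based*: a chimera is recorded only when the fragment swap
actually introduces a foreign variant, a dropout only when a variant is
actually lost. Events that leave the observable haplotype unchanged are
physically indistinguishable from clean data and are not labelled
artefacts. What the generators do **not** emulate: per-base quality and
post-mortem deamination damage, heteroplasmy, recurrent mutation at
hotspots (hotspot weights shape *where* panel motifs arise, not repeat
hits), selection, and population growth in the coalescent (constant size
only). Passing the recovery tests therefore demonstrates the rule set's
internal correctness under clean-truth conditions, not its error rates on
real damaged aDNA.

## Numerical and testing choices

Ties in classification break shallow-first, in completion minimal-missing
first, in decomposition coverage-first; all are deterministic. Distances
validate symmetry to 1e-8 and zero diagonal to 1e-12; PCoA treats
eigenvalues within 1e-12 of zero as null. Degenerate inputs error early:
empty panels, empty clades, zero-width site masks, empty later pools in
persistence, k outside 1..n in wave grouping.

Problem sizes in the test suite are chosen to keep the default run within
a few minutes of CPU: star-clade recovery uses 100 replicates per true age
in {500, 1000, 2000} with 50 tips and B = 500 bootstrap replicates
(coverage is then assessed over the 300 runs jointly); the end-to-end
pipeline curates one 288-haplotype indigenous cohort against a 30-node
simulated panel; the brute-force chimera oracle enumerates all haplogroup
pairs and all 3^|V| component assignments, so it is applied to variant
sets of at most six tokens on panels of at most ten motifs. The Fisher and
sign tests are checked against exhaustive enumeration for every 2×2 table
with margins up to 30.

## Known limitations

* The motif panel is a curated stand-in; haplotypes outside its coverage
  classify to the nearest encoded clade, and contaminant flagging is only
  as complete as the within-haplogroup polymorphism lists supplied.
* Chimera decomposition searches haplogroup *pairs*; three-template
  chimeras are reported as the best two-component approximation with a
  residue.
* The incomplete/clean boundary is intentionally conservative in both
  directions (see the curation ordering above); a fully scored haplotype
  missing interior motif sites is reported incomplete-but-inconsistent
  rather than invented as a new clade.
* rho dating assumes the members descend from the stated founder; with a
  misidentified founder the statistic is biased upward, and no rate
  heterogeneity across sites is modelled.
* The packaged reference FASTA is a synthetic stand-in sequence (the
  coordinate logic never depends on its bases); users scoring real
  mitogenomes should supply the real reference alignment.
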