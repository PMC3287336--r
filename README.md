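# motuDiet

DNA-metabarcoding diet analysis from tagged amplicon reads to niche-overlap
inference, in R.

`motuDiet` implements the complete analysis chain used in molecular
scatology studies of insectivorous predators (the worked example is a pair
of sympatric cryptic bat species, *Plecotus austriacus* and *P. auritus*):
pooled fecal DNA is PCR-amplified with 5′-tagged ("fusion") generic
arthropod COI primers targeting a 157 bp fragment, sequenced in bulk, and
the reads are carried through demultiplexing, quality filtering, MOTU
clustering, taxonomic assignment and dietary niche statistics. Because such
studies rarely deposit raw reads, the package also ships a synthetic-data
generator that emulates every input — reference taxa with controlled
divergence, tagged error-bearing reads, diet matrices with tunable overlap —
so the whole pipeline is testable end to end, plus the published per-taxon
consumer-count table of the bat study as a packaged worked example.

## What it computes

**Sequence processing.** Reads are assigned to samples only when their 5′
prefix is *exactly* `MID tag + primer` (one substitution discards the
read), trimmed, length-filtered (default 141 bp = 90% of the 157 bp
amplicon), collapsed into haplotypes, and purged of singletons (unique
sequences seen once). Haplotypes are clustered into Molecular Operational
Taxonomic Units (MOTUs) by single linkage on pairwise alignment p-distance
(Needleman–Wunsch, unit costs, free end gaps). The divergence threshold is
swept over 0–10% and the working threshold is read off the inflection
point of the MOTU-count curve — the first threshold where the curve stops
dropping after collapse has begun (2% for data of this kind). Each MOTU's
three most abundant haplotypes are matched against a local
taxonomy-annotated reference library, with a three-tier confidence scheme:

1. all matches >98.5% name one species (or one genus) — species/genus
   assignment;
2. matches >98.5% span several genera but only one species is on the
   regional checklist — species assignment to that species;
3. matches >98% stay within one family — family assignment.

**Diet statistics.** From a predator × resource utilization matrix
(occurrence counts of each prey taxon across fecal samples) the package
computes percent frequency of occurrence by order, Levins' standardized
niche breadth

  B = 1 / Σᵢ pᵢ² ,  B_A = (B − 1)/(n − 1),

Shannon diversity H = −Σᵢ pᵢ ln pᵢ, and Pianka's niche overlap

  O_jk = Σᵢ P_ij P_ik / √(Σᵢ P_ij² · Σᵢ P_ik²).

Whether observed overlap exceeds chance is tested with an EcoSim-style
null model: Randomization Algorithm 3 (RA3) independently permutes each
predator's count vector across all resource states (conserving its niche
breadth), the overlap is recomputed for 10,000 randomized matrices, and a
one-tailed add-one permutation p-value (r + 1)/(n + 1) is reported, with
Bonferroni control across comparisons. Prey with known habitat
associations can be cross-classified (grassland vs woodland specialists ×
predator) and tested with a Pearson chi-square.

## Worked example

The packaged fixture is the published list of 79 arthropod prey taxa with
the number of individual bats of each species (28 *P. austriacus*, 24
*P. auritus*) that consumed each taxon:

```r
library(motuDiet)
um <- loadTable1Fixture()
um
#> UtilizationMatrix: 79 resources x 2 predators
#>   predators: P. austriacus, P. auritus
#>   total occurrences: 206

piankaOverlap(um)
#> [1] 0.713474
```

The interspecific dietary overlap is 0.713 — the published analysis prints
0.72; the small residual arises because the printed table omits the
unidentified MOTUs. The null model asks whether that overlap could arise
by chance:

```r
overlapNullTest(um, nIterations = 10000, seed = 1)
#> NullModelResult ( RA3 ): P. austriacus vs P. auritus
#>   observed O_jk = 0.7135 | null mean = 0.2554 | P = 0.0016 (10000 iterations, one-tailed)
```

Observed overlap sits far above the null mean (~0.26): the two cryptic
bats share dietary resources much more than random resource use would
produce. Family-level structure and richness:

```r
round(familyShare(um, "P. austriacus", "Lepidoptera", "Noctuidae"), 1)
#> [1] 71
round(familyShare(um, "P. auritus", "Lepidoptera", "Noctuidae"), 1)
#> [1] 83.3
ordersPerPredator(um)
#> P. austriacus    P. auritus
#>             6             5
richnessInflation(59, 52)   # 59 Lepidoptera MOTUs resolved to 52 species
#> [1] 12
```

Noctuid ("eared") moths dominate the lepidopteran diet of both bats (71%
and 83.3% of Lepidoptera occurrences); six prey orders were detected for
*P. austriacus* and five for *P. auritus*; and MOTU counting overestimates
species richness by 12%. For a fully synthetic run — from mock reference
panel through simulated tagged reads to recovered MOTUs and assignments —
see `?runPipeline` and the methods vignette.

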