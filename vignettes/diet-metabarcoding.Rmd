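---
title: "Methods: from tagged COI amplicons to niche-overlap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tagged COI amplicons to niche-overlap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motuDiet)
```

`motuDiet` analyses predator diets from pooled fecal amplicon sequencing:
a short (157 bp) fragment of the mitochondrial COI barcode is amplified
from fecal DNA with generic arthropod primers carrying sample-identifying
5′ MID tags, sequenced in bulk, and processed into a predator × prey
utilization matrix on which dietary niche statistics are computed. This
vignette documents the model behind each stage, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic
data generator does and does not emulate.

## 1. Read filtering

Molecular scatology data are noisy: fecal DNA is degraded, and bulk
sequencing introduces substitution errors that can masquerade as rare prey
haplotypes. The package therefore takes a deliberately conservative,
fixed-order filter chain (`filterAmplicons()`):

1. **Exact demultiplexing** (`demultiplex()`). A read is assigned to a
   sample only if its 5′ prefix is *exactly* `tag + primer`; the prefix is
   then trimmed. One substitution anywhere in the tag or primer region —
   including an ambiguous `N` — discards the read. Only the forward
   tag+primer is checked: the reads are treated as single-ended, and
   reverse-primer trimming is not applied by default.
2. **Length filter** (`lengthFilter()`). Trimmed inserts shorter than
   `minLength` are dropped. The default is 141 bp, 90% of the expected
   157 bp amplicon: the underlying protocol never quantified "too short",
   so the cutoff is exposed as a parameter and 90% chosen as a value that
   tolerates modest terminal degradation while rejecting primer artefacts.
3. **Dereplication** (`dereplicate()`). Identical inserts collapse into
   haplotypes carrying total and per-sample abundances. Haplotype ids are
   assigned by decreasing abundance (ties by sequence order), so they are
   deterministic.
4. **Singleton removal** (`removeSingletons()`). Unique sequences observed
   exactly once are the signature of sequencing error and are removed.
   "Once" is scoped **globally** (across the whole run) by default — the
   conservative reading — with a `per_sample` alternative, since protocols
   differ on whether singleton removal precedes or follows per-sample
   splitting.

Every stage updates a single filter report whose conservation identity
(`input = retained + Σ discards`, in read units) is asserted on every run.

## 2. MOTU clustering

With an incomplete reference library, species are approximated by
Molecular Operational Taxonomic Units: clusters of haplotypes within a
divergence threshold.

**Distance.** `pairwiseDistance()` is a p-distance on an optimal global
alignment with unit mismatch and gap costs and *free end gaps*
(mismatches + internal gap columns, divided by alignment length excluding
end gaps). Free end gaps make length variation from degradation cheap
while substitutions stay expensive. Two numerical conventions matter:

- The alignment engine may clip a terminal mismatch into the free end
  gaps; the clipped columns that both sequences could still have provided
  are charged back as mismatches, so the distance is 0 only when the
  aligned region is genuinely identical. (A pair whose optimal ends-free
  alignment is an exact overlap — one sequence extending the other — still
  scores 0; this is inherent to free end gaps and harmless for same-locus
  amplicons.)
- Tracebacks among equally optimal alignments can differ in length, so
  each pair is aligned in a canonical orientation (lexicographically
  smaller sequence as pattern), making the distance exactly symmetric.
- Distances are rounded to 6 decimals before any threshold comparison,
  and thresholds are compared with `<=`, avoiding floating-point boundary
  flapping at grid points.

**Clustering.** `clusterAtThreshold()` takes the connected components of
the graph joining pairs at distance ≤ t — single linkage — which makes
partitions at increasing thresholds exactly nested (the hierarchy property
tested in the suite against an independent connected-components oracle).
MOTU labels are deterministic: decreasing cluster size, ties broken by the
lexicographically smallest member sequence.

**Threshold choice.** `sweepThresholds()` cuts the hierarchy over a 0–10%
grid in 0.5% steps and `selectInflectionThreshold()` picks the first
threshold where the count curve reaches its asymptote (drop to the next
grid point ≤ `plateauTolerance`, default 0). One refinement was needed:
with a 0.5% grid and 157 bp sequences the smallest possible nonzero
distance is 1/157 ≈ 0.64%, so the curve is necessarily flat between 0 and
0.5% before any collapsing has happened. A literal "first zero-drop" rule
would select 0 and return one MOTU per haplotype. The implemented rule
therefore requires collapse to have begun: candidate thresholds start
after the first drop, while a globally constant curve still selects the
first threshold. Thresholds are expressed as a fraction of the alignment
length (2% of 157 bp ≈ 3 bp), the natural unit for the percent-divergence
sweep. `plateauTolerance` is exposed because an asymptote read off a graph
is inherently a judgement call.

**Representatives.** Up to the three most abundant haplotypes per MOTU
(ties broken by lexicographically smaller sequence) are carried to
taxonomic assignment.

## 3. Taxonomic assignment

`similaritySearch()` scores a query against every record of a local
taxonomy-annotated reference FASTA as `1 − pairwiseDistance` — the same
aligner as the clustering stage, for internal consistency. A short barcode
often matches several species, so `assignConfidence()` applies a tiered
scheme with two thresholds: `speciesThreshold = 0.985` (species/genus
assignment) and `familyThreshold = 0.98` (family assignment). "All hits
above the threshold" is operationalized as every hit above the threshold
*or* within 0.5 percentage points of the best hit, whichever set is
larger — a reproducible analogue of reading a reference database's hit
page. When matches above the species threshold span several genera, a
regional species checklist (a data input, generalizing the original
U.K.-species rule to any region) can rescue a level-2 species assignment
if exactly one matching species is on it; two tied checklist species are
ambiguous, logged, and degraded by the agreement rule.

A MOTU's assignment is the **consensus over its representatives**:
conflicts degrade the call to the deepest rank on which all agree, with
the weakest confidence level among them; any unknown representative makes
the MOTU unknown. The source protocol queried three representatives but
never stated a conflict rule, so this conservative one is the package's
own choice.

`richnessInflation()` quantifies the known tendency of MOTUs to
over-split species (intraspecific polymorphism): 100·(n_MOTU −
n_species)/n_MOTU, rounded to the nearest integer percent.

## 4. Diet statistics

All niche statistics operate on a `UtilizationMatrix` (a
`SummarizedExperiment` of occurrence counts: samples of predator j
containing resource i). The defining proportions p_i are occurrence
counts normalized to sum to 1 within each predator. Stated as "the
proportion of fecal samples containing MOTU i", the p_i would not sum to
one; normalization is the convention under which the worked example's
published overlap value is reproducible from its printed table, and since
Levins, Shannon and Pianka are all scale-invariant the choice only fixes
an interpretation, not the values.

- `levinsBreadth()`: B = 1/Σp², B_A = (B−1)/(n−1). The pool size n
  defaults to the number of resources observed in that predator's diet;
  a wider pool can be passed because "possible resources in the diet" is
  ambiguous — the two conventions differ exactly by the ratio of pool
  sizes in (n−1).
- `shannonDiversity()`: H = −Σ p ln p (natural log).
- `piankaOverlap()`: ΣP_ij P_ik / √(ΣP_ij² ΣP_ik²); symmetric, in [0,1],
  invariant to rescaling either vector, so raw counts can be passed.
- `percentFoByOrder()`: occurrences of an order divided by total
  occurrences of all orders × 100; sums to 100 up to rounding.
- Reported percentages are rounded to one decimal, half away from zero
  (83.333 → "83.3"); unrounded values are returned by the functions.
- `sampleSummary()` uses the sample (n−1) SD by convention of
  "mean ± SD" reporting; the population convention is available and is
  the one under which a single sample has SD 0.

## 5. Null models

`overlapNullTest()` implements the EcoSim-style randomization test:
**RA3** independently permutes each predator's count vector across all
resource states (zeros included), conserving each predator's count
multiset — hence its Levins breadth and Shannon diversity — while
scrambling which resources are used. RA1/RA2/RA4 variants are
deliberately out of scope. Two conventions are the package's own choices,
recorded in every serialized result:

- the test is **one-tailed** (observed ≥ null), matching the scientific
  question "greater overlap than expected by chance";
- the p-value uses the **add-one permutation estimator**
  (r+1)/(n+1), the standard bias-safe choice, which can never return 0.

The test refuses degenerate inputs (fewer than two resource states).
Calibration is asserted in the suite: when the data are themselves RA3
draws, p-values are uniform (Kolmogorov–Smirnov check over 500 replicates
of 200 iterations, allowing the (n+1)-point grid spacing on top of the KS
critical value — a bound fixed before running). `bonferroni()` divides the
family alpha by the number of comparisons (0.05/3 ≈ 0.017).

One caution for fixture-based reanalysis: the null distribution is
sensitive to the number of resource states. A printed prey table that
omits unidentifiable MOTUs carries fewer states than the full matrix the
original software saw, which fattens the null tail; p-values recomputed
from such a table are therefore conservative (larger) relative to the
original run, even when the observed overlap is essentially unchanged.

## 6. Habitat analysis

`classifyDiet()` cross-classifies distinct prey taxa by habitat class
(from a user-supplied lookup compiled from field guides — data, not code)
and predator; a taxon eaten by both predators counts in both columns.
With `specialistsOnly = TRUE` the generalists and unknowns are excluded,
leaving the grassland/woodland contrast. `chiSquareIndependence()` is
Pearson's test without Yates correction by default (both variants
available for 2×2), refusing zero marginals and non-positive expected
counts.

## 7. The synthetic-data generator

Because studies of this kind rarely deposit raw reads, the generator is a
first-class module that emulates the study conditions:

- `generateReferencePanel()`: taxa at > 4% pairwise base-sequence
  divergence with variants at < 2% of their base — the separation regime
  under which a 2% threshold delimits species. Variants are uniform
  random substitutions; an indel-free default is sufficient because the
  clustering contract is defined on aligned distance. Infeasible
  constraint combinations fail explicitly after bounded retries rather
  than silently violating the invariants.
- `simulateReads()`: reads are `tag + primer + variant` with per-base
  substitution errors (default rate 0.005) and a geometric abundance skew
  across variants (default ratio 0.7), so the base haplotype dominates
  and rare variants exercise singleton removal and representative
  selection. Tags are distinct 8-mers at pairwise Hamming distance ≥ 2,
  precluding demultiplexing ambiguity. Defaults of 200 reads per sample
  and 157 bp amplicons are field-realistic choices; the original
  instrument's error and abundance statistics were never published, so
  these are not calibrated to it. A truth table records every read's
  source taxon; identical seed and configuration give byte-identical
  output.
- `simulateUtilizationMatrix()`: count matrices whose predator supports
  are sliding blocks over a shared count template, giving identical rows
  at `overlapLevel = 1`, disjoint supports at 0, and monotonically
  interpolating Pianka overlap in between — the calibration input for the
  null-model tests.

What the generator does **not** emulate: homopolymer errors, chimeras,
PCR-abundance bias, and quality scores beyond a constant placeholder.
Passing tests therefore demonstrate the correctness of the algorithms
under substitution-dominated noise and well-separated taxa; they do not
certify performance on real data with chimeric reads or heavily skewed
amplification.

## 8. Problem sizes and limitations

The test suite runs entirely on generated data at deliberate desk scale —
panels of 3–10 taxa, 40–400 reads per sample, null tests at 200–10,000
iterations, 500-replicate calibration — sizes chosen so the full suite
completes in minutes while still exercising every contract. Known
limitations:

- occurrence counts deliberately ignore read abundance within a sample:
  amplicon counts are not a quantitative measure of diet composition,
  so only presence per sample is used;
- rarefaction/coverage estimation, chimera detection, paired-end merging
  and phylogenetic species delimitation are out of scope;
- the ends-free distance assigns 0 to exact-overlap (shift) pairs, a
  theoretical corner that cannot arise between same-locus amplicons of
  honest length;
- level-2 assignments inherit the completeness of the regional checklist,
  and all assignments inherit the completeness of the reference library.
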