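#' @import methods
NULL

#' Occurrence counts of a utilization matrix
#'
#' @param x A [UtilizationMatrix-class] object.
#' @return Integer matrix of occurrence counts, resources in rows, predators
#'   in columns.
#' @export
setGeneric("occurrenceCounts", function(x) standardGeneric("occurrenceCounts"))

#' @rdname occurrenceCounts
#' @export
setGeneric("predatorNames", function(x) standardGeneric("predatorNames"))

#' @rdname occurrenceCounts
#' @export
setGeneric("resourceNames", function(x) standardGeneric("resourceNames"))

#' Resource annotation (order/family) of a utilization matrix
#'
#' @param x A [UtilizationMatrix-class] object.
#' @return A `data.frame` with one row per resource.
#' @export
setGeneric("resourceInfo", function(x) standardGeneric("resourceInfo"))

#' Accessors for mock reference panels
#'
#' @param x A [MockTaxonPanel-class] object.
#' @return `baseSequences()` a named [Biostrings::DNAStringSet] of one base
#'   sequence per taxon; `variantSequences()` a [Biostrings::DNAStringSetList]
#'   of intraspecific variants (base sequence first); `taxonomyTable()` a
#'   `data.frame` of lineages.
#' @export
setGeneric("baseSequences", function(x) standardGeneric("baseSequences"))

#' @rdname baseSequences
#' @export
setGeneric("variantSequences", function(x) standardGeneric("variantSequences"))

#' @rdname baseSequences
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' Accessors for dereplicated haplotype sets
#'
#' @param x A [HaplotypeSet-class] object.
#' @return `haplotypeSequences()` a named [Biostrings::DNAStringSet];
#'   `haplotypeAbundance()` a named integer vector of total abundances;
#'   `sampleCounts()` an integer matrix, haplotypes in rows, samples in
#'   columns.
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))

#' @rdname haplotypeSequences
#' @export
setGeneric("haplotypeAbundance", function(x) standardGeneric("haplotypeAbundance"))

#' @rdname haplotypeSequences
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' Accessors for MOTU clusterings and threshold sweeps
#'
#' @param x A [MotuClustering-class] or [ThresholdSweep-class] object.
#' @return `motuMembership()` a named integer vector mapping haplotype ids to
#'   MOTU indices; `nMotus()` the number of MOTUs; `sweepThresholdValues()` and
#'   `sweepMotuCounts()` the sweep grid and per-threshold MOTU counts;
#'   `selectedThreshold()` the working divergence threshold.
#' @export
setGeneric("motuMembership", function(x) standardGeneric("motuMembership"))

#' @rdname motuMembership
#' @export
setGeneric("nMotus", function(x) standardGeneric("nMotus"))

#' @rdname motuMembership
#' @export
setGeneric("sweepThresholdValues", function(x) standardGeneric("sweepThresholdValues"))

#' @rdname motuMembership
#' @export
setGeneric("sweepMotuCounts", function(x) standardGeneric("sweepMotuCounts"))

#' @rdname motuMembership
#' @export
setGeneric("selectedThreshold", function(x) standardGeneric("selectedThreshold"))

#' Accessors for null-model results
#'
#' @param x A [NullModelResult-class] object.
#' @return `observedOverlap()` the observed Pianka overlap;
#'   `nullDistribution()` the simulated overlaps; `pValue()` the one-tailed
#'   add-one permutation p-value.
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname observedOverlap
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @rdname observedOverlap
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
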