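#' @importClassesFrom Biostrings DNAStringSet DNAStringSetList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Biostrings DNAStringSet DNAStringSetList width
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame
NULL

# ---- MockTaxonPanel ---------------------------------------------------------

#' Mock COI reference panel
#'
#' A set of synthetic reference taxa emulating a curated barcode panel:
#' one base sequence per taxon plus intraspecific variants (the base sequence
#' is always the first variant), with guaranteed interspecific separation and
#' bounded intraspecific variation on the proportion of differing sites.
#'
#' @slot baseSequences Named [Biostrings::DNAStringSet], one entry per taxon.
#' @slot variants [Biostrings::DNAStringSetList] parallel to `baseSequences`;
#'   each element holds the taxon's variants, base sequence first.
#' @slot taxonomy `data.frame` with columns `taxon_id`, `order`, `family`,
#'   `genus`, `species`.
#' @slot minInterspecific Minimum pairwise base-sequence p-distance enforced
#'   between distinct taxa (fraction).
#' @slot maxIntraspecific Strict upper bound on variant-to-base p-distance
#'   (fraction).
#'
#' @seealso [generateReferencePanel()]
#' @export
setClass("MockTaxonPanel",
  slots = c(
    baseSequences = "DNAStringSet",
    variants = "DNAStringSetList",
    taxonomy = "data.frame",
    minInterspecific = "numeric",
    maxIntraspecific = "numeric"
  )
)

.hammingFraction <- function(a, b) {
  # equal-length, substitution-only comparison
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv) / length(av)
}

setValidity("MockTaxonPanel", function(object) {
  msgs <- character()
  n <- length(object@baseSequences)
  if (is.null(names(object@baseSequences)) || anyDuplicated(names(object@baseSequences)))
    msgs <- c(msgs, "base sequences must carry unique taxon ids as names")
  if (length(object@variants) != n)
    msgs <- c(msgs, "one variant set per taxon required")
  if (nrow(object@taxonomy) != n)
    msgs <- c(msgs, "taxonomy must have one row per taxon")
  base <- as.character(object@baseSequences)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (.hammingFraction(base[i], base[j]) <= object@minInterspecific)
        msgs <- c(msgs, sprintf("taxa %s and %s violate the interspecific minimum",
                                names(base)[i], names(base)[j]))
    }
  }
  for (i in seq_len(n)) {
    vs <- as.character(object@variants[[i]])
    if (length(vs) < 1L || vs[1] != base[i])
      msgs <- c(msgs, sprintf("taxon %s: base sequence must be the first variant", names(base)[i]))
    if (any(vapply(vs, .hammingFraction, numeric(1), b = base[i]) >= object@maxIntraspecific))
      msgs <- c(msgs, sprintf("taxon %s: variant exceeds the intraspecific bound", names(base)[i]))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("baseSequences", "MockTaxonPanel", function(x) x@baseSequences)
setMethod("variantSequences", "MockTaxonPanel", function(x) x@variants)
setMethod("taxonomyTable", "MockTaxonPanel", function(x) x@taxonomy)

setMethod("show", "MockTaxonPanel", function(object) {
  cat("MockTaxonPanel with", length(object@baseSequences), "taxa,",
      sum(lengths(object@variants)), "variant sequences\n")
  cat("  amplicon length:", unique(width(object@baseSequences)), "bp\n")
  cat("  interspecific p-distance >", object@minInterspecific,
      "| intraspecific <", object@maxIntraspecific, "\n")
})

# ---- HaplotypeSet -----------------------------------------------------------

#' Dereplicated haplotypes with per-sample abundances
#'
#' The result of collapsing identical trimmed reads: one record per distinct
#' sequence, with its total abundance and its abundance in every sample.
#'
#' @slot sequences Named [Biostrings::DNAStringSet] of distinct sequences.
#' @slot sampleCounts Integer matrix (haplotype x sample); row sums are the
#'   total abundances.
#'
#' @seealso [dereplicate()], [removeSingletons()]
#' @export
setClass("HaplotypeSet",
  slots = c(sequences = "DNAStringSet", sampleCounts = "matrix")
)

setValidity("HaplotypeSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (nrow(object@sampleCounts) != n)
    msgs <- c(msgs, "sampleCounts must have one row per haplotype")
  if (n > 0) {
    if (!identical(rownames(object@sampleCounts), names(object@sequences)))
      msgs <- c(msgs, "sampleCounts rownames must equal haplotype ids")
    if (any(object@sampleCounts < 0) || any(object@sampleCounts != round(object@sampleCounts)))
      msgs <- c(msgs, "sampleCounts must be non-negative integers")
    if (any(rowSums(object@sampleCounts) < 1))
      msgs <- c(msgs, "every haplotype must have total abundance >= 1")
    if (anyDuplicated(as.character(object@sequences)))
      msgs <- c(msgs, "haplotype sequences must be distinct")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("haplotypeSequences", "HaplotypeSet", function(x) x@sequences)
setMethod("haplotypeAbundance", "HaplotypeSet", function(x) {
  n <- rowSums(x@sampleCounts)
  storage.mode(n) <- "integer"
  n
})
setMethod("sampleCounts", "HaplotypeSet", function(x) x@sampleCounts)
setMethod("length", "HaplotypeSet", function(x) length(x@sequences))

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet with", length(object@sequences), "haplotypes across",
      ncol(object@sampleCounts), "samples\n")
  if (length(object@sequences) > 0)
    cat("  total reads:", sum(object@sampleCounts),
        "| abundance range:", min(rowSums(object@sampleCounts)), "-",
        max(rowSums(object@sampleCounts)), "\n")
})

# ---- MotuClustering / ThresholdSweep ---------------------------------------

#' Single-linkage MOTU partition at one divergence threshold
#'
#' Haplotypes are grouped into molecular operational taxonomic units (MOTUs):
#' the connected components of the graph joining every pair of haplotypes at
#' alignment p-distance at or below the threshold. MOTU indices are assigned
#' deterministically by decreasing cluster size, ties broken by the
#' lexicographically smallest member id.
#'
#' @slot membership Named integer vector mapping haplotype ids to MOTU index
#'   (1-based, dense).
#' @slot threshold The divergence threshold (fraction) the partition was cut
#'   at.
#'
#' @seealso [clusterAtThreshold()]
#' @export
setClass("MotuClustering",
  slots = c(membership = "integer", threshold = "numeric")
)

setValidity("MotuClustering", function(object) {
  msgs <- character()
  m <- object@membership
  if (length(m) > 0) {
    if (is.null(names(m))) msgs <- c(msgs, "membership must be named by haplotype id")
    k <- max(m)
    if (!setequal(unique(m), seq_len(k)))
      msgs <- c(msgs, "MOTU indices must be dense 1..k")
  }
  if (object@threshold < 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("motuMembership", "MotuClustering", function(x) x@membership)
setMethod("nMotus", "MotuClustering", function(x) {
  if (length(x@membership) == 0L) 0L else max(x@membership)
})
setMethod("selectedThreshold", "MotuClustering", function(x) x@threshold)

setMethod("show", "MotuClustering", function(object) {
  cat("MotuClustering:", nMotus(object), "MOTUs from",
      length(object@membership), "haplotypes at threshold",
      object@threshold, "\n")
})

#' MOTU-count curve over a divergence-threshold sweep
#'
#' MOTU counts at a grid of divergence thresholds, with the working threshold
#' chosen at the inflection point of the curve — the first threshold where
#' the count stops dropping (new MOTUs are no longer being recognized but
#' existing MOTUs have not yet been collapsed).
#'
#' @slot thresholds Increasing numeric vector of divergence thresholds.
#' @slot motuCounts Integer vector of MOTU counts, parallel to `thresholds`;
#'   non-increasing by the nesting of single-linkage partitions.
#' @slot selectedThreshold The chosen working threshold (`NA` until selected).
#'
#' @seealso [sweepThresholds()], [selectInflectionThreshold()]
#' @export
setClass("ThresholdSweep",
  slots = c(thresholds = "numeric", motuCounts = "integer",
            selectedThreshold = "numeric")
)

setValidity("ThresholdSweep", function(object) {
  msgs <- character()
  if (length(object@thresholds) != length(object@motuCounts))
    msgs <- c(msgs, "thresholds and motuCounts must be parallel")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msgs <- c(msgs, "thresholds must be strictly increasing")
  if (any(diff(object@motuCounts) > 0))
    msgs <- c(msgs, "MOTU counts must be non-increasing in the threshold")
  st <- object@selectedThreshold
  if (!is.na(st) && !any(abs(object@thresholds - st) < 1e-12))
    msgs <- c(msgs, "selectedThreshold must be one of the sweep thresholds")
  if (length(msgs)) msgs else TRUE
})

setMethod("sweepThresholdValues", "ThresholdSweep", function(x) x@thresholds)
setMethod("sweepMotuCounts", "ThresholdSweep", function(x) x@motuCounts)
setMethod("selectedThreshold", "ThresholdSweep", function(x) x@selectedThreshold)

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep over [", min(object@thresholds), ",",
      max(object@thresholds), "] (", length(object@thresholds), "points )\n")
  cat("  MOTU counts:", object@motuCounts[1], "->",
      object@motuCounts[length(object@motuCounts)], "\n")
  if (!is.na(object@selectedThreshold))
    cat("  selected threshold:", object@selectedThreshold, "\n")
})

# ---- UtilizationMatrix ------------------------------------------------------

#' Predator-by-resource utilization matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding occurrence counts:
#' entry (i, j) is the number of fecal samples of predator j in which
#' resource i (a MOTU or assigned taxon) was detected. Resources are rows
#' (with optional order/family annotation in `rowData`); predators are
#' columns. This is the object on which niche breadth, diversity, overlap
#' and the randomization null models are computed.
#'
#' @seealso [buildUtilizationMatrix()], [piankaOverlap()], [overlapNullTest()]
#' @export
setClass("UtilizationMatrix", contains = "SummarizedExperiment")

setValidity("UtilizationMatrix", function(object) {
  msgs <- character()
  if (!"occurrence" %in% SummarizedExperiment::assayNames(object))
    return("an assay named 'occurrence' is required")
  m <- SummarizedExperiment::assay(object, "occurrence")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    msgs <- c(msgs, "occurrence counts must be non-negative integers")
  # note: all-zero rows are excluded by the builders, not here -- RA3
  # randomization may transiently empty a row
  if (is.null(rownames(m)) && nrow(m) > 0)
    msgs <- c(msgs, "resources must be named")
  if (is.null(colnames(m)) && ncol(m) > 0)
    msgs <- c(msgs, "predators must be named")
  if (length(msgs)) msgs else TRUE
})

#' Construct a UtilizationMatrix
#'
#' @param counts Integer matrix of occurrence counts, resources in rows and
#'   predators in columns, both dimensions named.
#' @param resourceInfo Optional `data.frame` with one row per resource;
#'   columns `order` and `family` are recognized by the order/family-level
#'   summaries.
#' @return A [UtilizationMatrix-class] object.
#' @examples
#' m <- matrix(c(2L, 1L, 0L, 1L), 2, 2,
#'             dimnames = list(c("r1", "r2"), c("p1", "p2")))
#' UtilizationMatrix(m)
#' @export
UtilizationMatrix <- function(counts, resourceInfo = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(resourceInfo)) {
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    rd <- S4Vectors::DataFrame(resourceInfo, row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(occurrence = counts), rowData = rd)
  methods::new("UtilizationMatrix", se)
}

setMethod("occurrenceCounts", "UtilizationMatrix", function(x) {
  SummarizedExperiment::assay(x, "occurrence")
})
setMethod("predatorNames", "UtilizationMatrix", function(x) colnames(x))
setMethod("resourceNames", "UtilizationMatrix", function(x) rownames(x))
setMethod("resourceInfo", "UtilizationMatrix", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

setMethod("show", "UtilizationMatrix", function(object) {
  m <- occurrenceCounts(object)
  cat("UtilizationMatrix:", nrow(m), "resources x", ncol(m), "predators\n")
  cat("  predators:", paste(colnames(m), collapse = ", "), "\n")
  cat("  total occurrences:", sum(m), "\n")
})

# ---- NullModelResult --------------------------------------------------------

#' Result of a randomization null-model test of niche overlap
#'
#' Holds the observed Pianka overlap between two predators, the distribution
#' of overlaps across RA3-randomized matrices, and the one-tailed add-one
#' permutation p-value \eqn{(1 + r)/(n + 1)} where r counts simulated
#' overlaps at or above the observed value.
#'
#' @slot observed Observed overlap.
#' @slot simulated Numeric vector of simulated overlaps (length
#'   `nIterations`).
#' @slot pValue One-tailed p-value in (0, 1].
#' @slot nIterations Number of randomized matrices.
#' @slot seed Integer seed used for the randomization stream.
#' @slot algorithm Randomization algorithm label (`"RA3"`).
#' @slot predators The two predator labels compared.
#'
#' @seealso [overlapNullTest()]
#' @export
setClass("NullModelResult",
  slots = c(observed = "numeric", simulated = "numeric", pValue = "numeric",
            nIterations = "integer", seed = "integer", algorithm = "character",
            predators = "character")
)

setValidity("NullModelResult", function(object) {
  msgs <- character()
  if (length(object@simulated) != object@nIterations)
    msgs <- c(msgs, "simulated distribution length must equal nIterations")
  if (object@pValue <= 0 || object@pValue > 1)
    msgs <- c(msgs, "p-value must lie in (0, 1]")
  if (length(object@predators) != 2L)
    msgs <- c(msgs, "exactly two predators are compared")
  if (length(msgs)) msgs else TRUE
})

setMethod("observedOverlap", "NullModelResult", function(x) x@observed)
setMethod("nullDistribution", "NullModelResult", function(x) x@simulated)
setMethod("pValue", "NullModelResult", function(x) x@pValue)

setMethod("show", "NullModelResult", function(object) {
  cat("NullModelResult (", object@algorithm, "):",
      paste(object@predators, collapse = " vs "), "\n")
  cat(sprintf("  observed O_jk = %.4f | null mean = %.4f | P = %.4g (%d iterations, one-tailed)\n",
              object@observed, mean(object@simulated), object@pValue,
              object@nIterations))
})
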