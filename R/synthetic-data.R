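#' @importFrom Biostrings DNAStringSet DNAStringSetList writeXStringSet
NULL

# disambiguated forward primer for the 157 bp generic arthropod COI fragment
.DEFAULT_PRIMER <- "AGATATTGGAACTTTATATTTTATTTTTGG"

#' Generate a mock COI reference panel
#'
#' Draws `nTaxa` synthetic reference taxa with guaranteed sequence
#' separation: base sequences of distinct taxa differ at more than
#' `minInterspecific` of sites, and every intraspecific variant differs from
#' its base sequence at fewer than `maxIntraspecific` of sites. Variants are
#' produced by uniform random substitutions (no indels), which is sufficient
#' to exercise divergence-threshold clustering because the clustering
#' contract is defined on aligned distance.
#'
#' Taxa receive invented lineages (arthropod order labels cycling over
#' Lepidoptera / Diptera / Coleoptera, unique mock families, genera and
#' species) so taxonomic assignment and habitat classification can be tested
#' end to end.
#'
#' @param nTaxa Number of taxa (>= 1).
#' @param length Amplicon length in bases (default 157, the target COI
#'   fragment).
#' @param minInterspecific Minimum pairwise p-distance between base
#'   sequences of distinct taxa (strict, default 0.04).
#' @param maxIntraspecific Strict upper bound on variant-to-base p-distance
#'   (default 0.02).
#' @param nVariants Number of variants per taxon including the base sequence
#'   (default 3).
#' @param seed Optional integer seed; identical seed and arguments give an
#'   identical panel.
#' @return A [MockTaxonPanel-class] object.
#' @examples
#' panel <- generateReferencePanel(5, seed = 1)
#' panel
#' @export
generateReferencePanel <- function(nTaxa, length = 157,
                                   minInterspecific = 0.04,
                                   maxIntraspecific = 0.02,
                                   nVariants = 3, seed = NULL) {
  nTaxa <- .assertCount(nTaxa, "nTaxa")
  length <- .assertCount(length, "length", min = 10L)
  minInterspecific <- .assertFraction(minInterspecific, "minInterspecific",
                                      lo.open = TRUE)
  maxIntraspecific <- .assertFraction(maxIntraspecific, "maxIntraspecific",
                                      hi = 1, hi.open = TRUE)
  nVariants <- .assertCount(nVariants, "nVariants")
  if (maxIntraspecific >= minInterspecific)
    stop("maxIntraspecific must be smaller than minInterspecific")
  if (!is.null(seed)) set.seed(seed)

  # random sequences sit near 75% divergence, so moderate minima are easy;
  # bounded retries turn genuinely infeasible constraints into an error
  maxAttempts <- 200L * nTaxa
  base <- character(0)
  attempts <- 0L
  while (length(base) < nTaxa) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(
        "could not place %d taxa at > %.3f pairwise divergence (length %d); ",
        nTaxa, minInterspecific, length),
        "divergence constraints are infeasible for this panel size")
    cand <- .randomDNA(length)
    ok <- all(vapply(base, .hammingFraction, numeric(1), b = cand) >
                minInterspecific)
    if (ok) base <- c(base, cand)
  }

  maxSub <- ceiling(maxIntraspecific * length) - 1L
  variants <- lapply(base, function(b) {
    extra <- character(0)
    if (nVariants > 1L && maxSub >= 1L) {
      extra <- vapply(seq_len(nVariants - 1L), function(i) {
        .substituteBases(b, sample.int(maxSub, 1L))
      }, character(1))
    }
    DNAStringSet(c(b, extra))
  })

  ids <- sprintf("TAX%03d", seq_len(nTaxa))
  orders <- c("Lepidoptera", "Diptera", "Coleoptera")
  taxonomy <- data.frame(
    taxon_id = ids,
    order = orders[(seq_len(nTaxa) - 1L) %% 3L + 1L],
    family = sprintf("Mockfamily%03d", seq_len(nTaxa)),
    genus = sprintf("Mockgenus%03d", seq_len(nTaxa)),
    species = sprintf("Mockgenus%03d species%03d", seq_len(nTaxa), seq_len(nTaxa)),
    stringsAsFactors = FALSE
  )

  bs <- DNAStringSet(base)
  names(bs) <- ids
  vs <- DNAStringSetList(variants)
  names(vs) <- ids
  methods::new("MockTaxonPanel", baseSequences = bs, variants = vs,
               taxonomy = taxonomy, minInterspecific = minInterspecific,
               maxIntraspecific = maxIntraspecific)
}

#' Read-simulation configuration
#'
#' Bundles and validates the parameters of [simulateReads()].
#'
#' @param tagLength MID tag length in bases (default 8).
#' @param primerForward Forward primer sequence prepended (after the tag) to
#'   every read; default is the generic arthropod COI forward primer with
#'   ambiguity codes resolved.
#' @param readsPerSample Reads emitted per sample (default 200).
#' @param substitutionErrorRate Per-base substitution probability in
#'   \eqn{[0, 1)} (default 0.005).
#' @param abundanceSkew Geometric decay ratio in (0, 1] across a taxon's
#'   variants: variant v is drawn with weight `abundanceSkew^(v-1)`, so the
#'   base haplotype dominates and rarer variants exercise singleton removal
#'   (default 0.7).
#' @param seed Optional integer seed.
#' @return A validated list of class `ReadSimConfig`.
#' @export
readSimConfig <- function(tagLength = 8, primerForward = .DEFAULT_PRIMER,
                          readsPerSample = 200,
                          substitutionErrorRate = 0.005,
                          abundanceSkew = 0.7, seed = NULL) {
  cfg <- list(
    tagLength = .assertCount(tagLength, "tagLength", min = 4L),
    primerForward = toupper(primerForward),
    readsPerSample = .assertCount(readsPerSample, "readsPerSample"),
    substitutionErrorRate = .assertFraction(substitutionErrorRate,
                                            "substitutionErrorRate",
                                            hi = 1, hi.open = TRUE),
    abundanceSkew = .assertFraction(abundanceSkew, "abundanceSkew",
                                    lo = 0, lo.open = TRUE),
    seed = if (is.null(seed)) NULL else .assertCount(seed, "seed", min = 0L)
  )
  if (!grepl("^[ACGT]+$", cfg$primerForward))
    stop("primerForward must contain only A/C/G/T (resolve ambiguity codes)")
  class(cfg) <- "ReadSimConfig"
  cfg
}

# distinct fixed-length tags with pairwise Hamming distance >= 2,
# preventing demultiplexing ambiguity
.generateTags <- function(n, tagLength) {
  tags <- character(0)
  attempts <- 0L
  while (length(tags) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n)
      stop("could not generate ", n, " tags of length ", tagLength,
           " at pairwise Hamming distance >= 2")
    cand <- .randomDNA(tagLength)
    ok <- all(vapply(tags, function(t) {
      sum(strsplit(t, "")[[1]] != strsplit(cand, "")[[1]]) >= 2L
    }, logical(1)))
    if (ok) tags <- c(tags, cand)
  }
  tags
}

#' Simulate tagged amplicon reads from a mock panel
#'
#' Emits `readsPerSample` reads for every sample in `trueDiet`. Each read is
#' `tag + primer + variant sequence` where the variant is drawn from the
#' source taxon's variants under the geometric abundance skew and then
#' subjected to per-base substitution errors. A truth table records the
#' source taxon of every read.
#'
#' @param panel A [MockTaxonPanel-class].
#' @param trueDiet Named list mapping sample id to a character vector
#'   (multiset) of taxon ids consumed in that sample; repetitions weight the
#'   taxon.
#' @param config A [readSimConfig()] list.
#' @return A list with elements `reads` (named
#'   [Biostrings::DNAStringSet]), `tagMap` (`data.frame` with columns
#'   `tag`, `sample_id`), and `truth` (`data.frame` with columns `read_id`,
#'   `sample_id`, `taxon_id`).
#' @examples
#' panel <- generateReferencePanel(3, seed = 1)
#' diet <- list(s1 = c("TAX001", "TAX002"), s2 = "TAX003")
#' sim <- simulateReads(panel, diet, readSimConfig(readsPerSample = 20, seed = 2))
#' sim$truth[1:3, ]
#' @export
simulateReads <- function(panel, trueDiet, config = readSimConfig()) {
  stopifnot(methods::is(panel, "MockTaxonPanel"), inherits(config, "ReadSimConfig"))
  samples <- names(trueDiet)
  if (is.null(samples) || anyDuplicated(samples) || length(samples) == 0L)
    stop("trueDiet must be a non-empty list named by unique sample ids")
  allTaxa <- unlist(trueDiet, use.names = FALSE)
  unknown <- setdiff(allTaxa, names(baseSequences(panel)))
  if (length(unknown))
    stop("trueDiet references taxa absent from the panel: ",
         paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)

  tags <- .generateTags(length(samples), config$tagLength)
  tagMap <- data.frame(tag = tags, sample_id = samples,
                       stringsAsFactors = FALSE)

  variants <- variantSequences(panel)
  nTotal <- length(samples) * config$readsPerSample
  readSeq <- character(nTotal)
  truthTaxon <- character(nTotal)
  truthSample <- character(nTotal)
  k <- 0L
  for (s in seq_along(samples)) {
    dietTaxa <- trueDiet[[s]]
    prefix <- paste0(tags[s], config$primerForward)
    for (r in seq_len(config$readsPerSample)) {
      k <- k + 1L
      taxon <- dietTaxa[sample.int(length(dietTaxa), 1L)]
      vset <- variants[[taxon]]
      w <- config$abundanceSkew^(seq_along(vset) - 1)
      v <- as.character(vset[[sample.int(length(vset), 1L, prob = w)]])
      readSeq[k] <- paste0(prefix, .applySequencingErrors(
        v, config$substitutionErrorRate))
      truthTaxon[k] <- taxon
      truthSample[k] <- samples[s]
    }
  }
  ids <- sprintf("read%07d", seq_len(nTotal))
  reads <- DNAStringSet(readSeq)
  names(reads) <- ids
  list(reads = reads, tagMap = tagMap,
       truth = data.frame(read_id = ids, sample_id = truthSample,
                          taxon_id = truthTaxon, stringsAsFactors = FALSE))
}

#' Simulate a utilization matrix with controlled interspecific overlap
#'
#' Builds an occurrence-count matrix whose rows share a fixed per-resource
#' count template; each predator uses a contiguous (circular) block of
#' resources whose offset shrinks with `overlapLevel`. At `overlapLevel = 1`
#' all predators have identical count vectors (Pianka overlap 1); at
#' `overlapLevel = 0` their supports are disjoint (overlap 0); intermediate
#' levels interpolate monotonically. Resources used by no predator are
#' dropped.
#'
#' @param nSpecies Number of predator species (>= 2).
#' @param nResources Number of resource states before dropping unused ones;
#'   must be at least `nSpecies` so disjoint supports are possible.
#' @param overlapLevel Target overlap in `[0, 1]`.
#' @param seed Optional integer seed (controls the count template).
#' @return A [UtilizationMatrix-class].
#' @examples
#' um <- simulateUtilizationMatrix(2, 20, overlapLevel = 0.5, seed = 1)
#' piankaOverlap(um)
#' @export
simulateUtilizationMatrix <- function(nSpecies = 2, nResources = 40,
                                      overlapLevel = 0.5, seed = NULL) {
  nSpecies <- .assertCount(nSpecies, "nSpecies", min = 2L)
  nResources <- .assertCount(nResources, "nResources", min = nSpecies)
  overlapLevel <- .assertFraction(overlapLevel, "overlapLevel")
  if (!is.null(seed)) set.seed(seed)

  m <- nResources %/% nSpecies          # support size per predator
  template <- sample.int(9L, nResources, replace = TRUE,
                         prob = 0.5^seq_len(9L))  # skewed positive counts
  counts <- matrix(0L, nResources, nSpecies,
                   dimnames = list(sprintf("RES%03d", seq_len(nResources)),
                                   sprintf("predator%02d", seq_len(nSpecies))))
  for (j in seq_len(nSpecies)) {
    offset <- round((j - 1L) * m * (1 - overlapLevel))
    idx <- ((offset + seq_len(m) - 1L) %% nResources) + 1L
    counts[idx, j] <- template[idx]
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  UtilizationMatrix(counts)
}

#' Write a mock reference panel as FASTA
#'
#' Headers follow `taxon_id|order|family|genus|species`; every variant of a
#' taxon is written under its taxon's header fields.
#'
#' @param panel A [MockTaxonPanel-class].
#' @param file Output FASTA path.
#' @return `file`, invisibly.
#' @export
writeReferencePanel <- function(panel, file) {
  tax <- taxonomyTable(panel)
  vs <- variantSequences(panel)
  seqs <- unlist(lapply(seq_len(nrow(tax)), function(i) as.character(vs[[i]])))
  hdr <- unlist(lapply(seq_len(nrow(tax)), function(i) {
    rep(paste(tax$taxon_id[i], tax$order[i], tax$family[i], tax$genus[i],
              tax$species[i], sep = "|"), length(vs[[i]]))
  }))
  out <- DNAStringSet(seqs)
  names(out) <- hdr
  writeXStringSet(out, file)
  invisible(file)
}

#' Write simulated reads and their truth table
#'
#' @param sim Result of [simulateReads()].
#' @param readsFile FASTA output path for the reads.
#' @param truthFile Optional TSV output path for the truth table
#'   (`read_id`, `sample_id`, `taxon_id`).
#' @param tagMapFile Optional TSV output path for the tag map
#'   (`tag`, `sample_id`).
#' @return `readsFile`, invisibly.
#' @export
writeSimulatedReads <- function(sim, readsFile, truthFile = NULL,
                                tagMapFile = NULL) {
  writeXStringSet(sim$reads, readsFile)
  if (!is.null(truthFile))
    write.table(sim$truth, truthFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(tagMapFile))
    write.table(sim$tagMap, tagMapFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(readsFile)
}
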