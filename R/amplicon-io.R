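#' @importFrom Biostrings readDNAStringSet subseq width
NULL

.emptyFilterReport <- function() {
  list(input_reads = 0L, discarded_primer_mismatch = 0L,
       discarded_short = 0L, discarded_singletons = 0L, retained = 0L)
}

.checkFilterReport <- function(rep) {
  stopifnot(rep$input_reads ==
    rep$retained + rep$discarded_primer_mismatch +
    rep$discarded_short + rep$discarded_singletons)
  rep
}

#' Read amplicon sequences from FASTA or FASTQ
#'
#' @param file Path to a FASTA or FASTQ file; the format is taken from the
#'   file extension (`.fastq`/`.fq` read as FASTQ, anything else as FASTA).
#' @return A named [Biostrings::DNAStringSet].
#' @export
readAmplicons <- function(file) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", file, ignore.case = TRUE))
    "fastq" else "fasta"
  reads <- readDNAStringSet(file, format = fmt)
  # keep only the id token of the header
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Read a MID tag map
#'
#' @param file Two-column TSV with header columns `tag` and `sample_id`.
#' @return `data.frame` with columns `tag`, `sample_id`.
#' @export
readTagMap <- function(file) {
  tm <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("tag", "sample_id") %in% names(tm)))
    stop("tag map must have columns 'tag' and 'sample_id'")
  tm
}

.asTagMap <- function(tagMap) {
  if (is.data.frame(tagMap)) {
    stopifnot(all(c("tag", "sample_id") %in% names(tagMap)))
    tm <- setNames(as.character(tagMap$sample_id), toupper(tagMap$tag))
  } else {
    tm <- setNames(as.character(tagMap), toupper(names(tagMap)))
  }
  if (length(tm) == 0L) stop("tag map is empty")
  if (anyDuplicated(names(tm))) stop("duplicate tags in tag map")
  if (length(unique(nchar(names(tm)))) != 1L)
    stop("all tags must have equal length")
  tm
}

#' Demultiplex tagged reads by exact tag+primer prefix
#'
#' A read is assigned to a sample if and only if its 5' prefix is exactly
#' the sample's MID tag immediately followed by the forward primer; the tag
#' and primer are trimmed from assigned reads. Any mismatch — including
#' ambiguous bases (N) inside the tag or primer region — discards the read
#' as a primer mismatch. Only the forward tag+primer is checked; reads are
#' treated as single-ended.
#'
#' @param reads Named [Biostrings::DNAStringSet] (or character vector) of
#'   raw reads.
#' @param tagMap `data.frame` with columns `tag` and `sample_id`, or a named
#'   character vector mapping tag to sample.
#' @param primer Forward primer sequence (A/C/G/T).
#' @return A list with elements `reads` (trimmed [Biostrings::DNAStringSet]
#'   of assigned reads), `sample` (character vector parallel to `reads`),
#'   and `report` (filter-report list; see [filterAmplicons()]).
#' @export
demultiplex <- function(reads, tagMap, primer) {
  tm <- .asTagMap(tagMap)
  primer <- toupper(primer)
  if (!grepl("^[ACGT]+$", primer)) stop("primer must contain only A/C/G/T")
  reads <- if (methods::is(reads, "DNAStringSet")) reads else
    Biostrings::DNAStringSet(reads)
  n <- length(reads)
  report <- .emptyFilterReport()
  report$input_reads <- n
  if (n == 0L) {
    return(list(reads = Biostrings::DNAStringSet(), sample = character(0),
                report = .checkFilterReport(report)))
  }
  tagLen <- nchar(names(tm)[1])
  prefLen <- tagLen + nchar(primer)
  expected <- setNames(paste0(names(tm), primer), names(tm))
  long <- width(reads) > prefLen   # insert must be non-empty
  pref <- rep(NA_character_, n)
  pref[long] <- as.character(subseq(reads[long], 1L, prefLen))
  hit <- match(pref, expected)
  keep <- !is.na(hit)
  assigned <- subseq(reads[keep], prefLen + 1L)
  names(assigned) <- names(reads)[keep]
  report$discarded_primer_mismatch <- sum(!keep)
  report$retained <- sum(keep)
  list(reads = assigned, sample = unname(tm[hit[keep]]),
       report = .checkFilterReport(report))
}

#' Discard reads shorter than a minimum insert length
#'
#' The default minimum is 141 bases, 90\% of the expected 157 bp amplicon.
#'
#' @param demux Result of [demultiplex()] (a list with `reads`, `sample`,
#'   `report`).
#' @param minLength Minimum trimmed read length in bases (>= 1).
#' @return The input list with short reads removed and
#'   `report$discarded_short` updated.
#' @export
lengthFilter <- function(demux, minLength = 141) {
  minLength <- .assertCount(minLength, "minLength")
  keep <- width(demux$reads) >= minLength
  report <- demux$report
  report$discarded_short <- report$discarded_short + sum(!keep)
  report$retained <- report$retained - sum(!keep)
  list(reads = demux$reads[keep], sample = demux$sample[keep],
       report = .checkFilterReport(report))
}

#' Collapse identical reads into haplotypes
#'
#' One haplotype per distinct trimmed sequence, with per-sample abundances.
#' Haplotype ids are assigned by decreasing total abundance, ties broken by
#' sequence order, so ids are deterministic.
#'
#' @param demux Result of [demultiplex()] / [lengthFilter()].
#' @return A [HaplotypeSet-class].
#' @export
dereplicate <- function(demux) {
  seqs <- as.character(demux$reads)
  samples <- demux$sample
  if (length(seqs) == 0L) {
    return(methods::new("HaplotypeSet",
      sequences = Biostrings::DNAStringSet(),
      sampleCounts = matrix(0L, 0, 0)))
  }
  tab <- table(sequence = seqs, sample = samples)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab))
  colnames(counts) <- colnames(tab)
  ord <- order(-rowSums(counts), rownames(tab))
  counts <- counts[ord, , drop = FALSE]
  uniq <- rownames(tab)[ord]
  ids <- sprintf("HAP%05d", seq_along(uniq))
  rownames(counts) <- ids
  hs <- Biostrings::DNAStringSet(uniq)
  names(hs) <- ids
  methods::new("HaplotypeSet", sequences = hs, sampleCounts = counts)
}

#' Remove singleton haplotypes
#'
#' A singleton is a unique sequence observed exactly once. With
#' `scope = "global"` (default, the conservative reading) a haplotype is a
#' singleton when its total abundance over the whole run is 1; with
#' `scope = "per_sample"`, per-sample occurrences of 1 are zeroed and
#' haplotypes that lose all support are dropped.
#'
#' @param haplotypes A [HaplotypeSet-class].
#' @param scope `"global"` or `"per_sample"`.
#' @return A list with `haplotypes` (the filtered [HaplotypeSet-class]) and
#'   `discardedReads` (number of reads removed). Warns when the filter
#'   empties the set.
#' @export
removeSingletons <- function(haplotypes, scope = c("global", "per_sample")) {
  scope <- match.arg(scope)
  counts <- sampleCounts(haplotypes)
  if (scope == "global") {
    keep <- rowSums(counts) > 1L
    discarded <- sum(rowSums(counts)[!keep])
    counts <- counts[keep, , drop = FALSE]
    seqs <- haplotypeSequences(haplotypes)[keep]
  } else {
    discarded <- sum(counts == 1L)
    counts[counts == 1L] <- 0L
    keep <- rowSums(counts) > 0L
    counts <- counts[keep, , drop = FALSE]
    seqs <- haplotypeSequences(haplotypes)[keep]
  }
  if (nrow(counts) == 0L && length(haplotypes) > 0L)
    warning("all haplotypes were singletons; the filtered set is empty")
  out <- methods::new("HaplotypeSet", sequences = seqs, sampleCounts = counts)
  list(haplotypes = out, discardedReads = as.integer(discarded))
}

#' Run the full read-filter chain
#'
#' Applies, in the fixed order of the workflow, exact tag+primer
#' demultiplexing, the minimum-length filter, dereplication into haplotypes,
#' and singleton removal, accumulating a single conservation-checked filter
#' report (`input_reads = retained + sum of discards`, in read units).
#'
#' @inheritParams demultiplex
#' @inheritParams lengthFilter
#' @param singletonScope Passed to [removeSingletons()].
#' @return A list with `haplotypes` (a [HaplotypeSet-class]) and `report`.
#' @examples
#' panel <- generateReferencePanel(3, seed = 1)
#' sim <- simulateReads(panel, list(s1 = "TAX001", s2 = c("TAX002", "TAX003")),
#'                      readSimConfig(readsPerSample = 50, seed = 2))
#' res <- filterAmplicons(sim$reads, sim$tagMap, readSimConfig()$primerForward)
#' res$report
#' @export
filterAmplicons <- function(reads, tagMap, primer, minLength = 141,
                            singletonScope = "global") {
  dm <- demultiplex(reads, tagMap, primer)
  lf <- lengthFilter(dm, minLength)
  hs <- dereplicate(lf)
  sf <- removeSingletons(hs, singletonScope)
  report <- lf$report
  report$discarded_singletons <- sf$discardedReads
  report$retained <- report$retained - sf$discardedReads
  list(haplotypes = sf$haplotypes, report = .checkFilterReport(report))
}

#' Serialize a filter report as JSON
#'
#' @param report A filter-report list as returned in the `report` element of
#'   [filterAmplicons()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeFilterReport <- function(report, file) {
  jsonlite::write_json(.checkFilterReport(report), file, auto_unbox = TRUE)
  invisible(file)
}
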