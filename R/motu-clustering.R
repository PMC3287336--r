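#' @importFrom Biostrings pairwiseAlignment pattern subject score DNAString
NULL

# unit-cost scoring over A/C/G/T/N; N mismatches everything including N
.scoreMatrix <- local({
  m <- matrix(-1L, 5, 5, dimnames = list(c(.DNA_BASES, "N"),
                                         c(.DNA_BASES, "N")))
  diag(m)[1:4] <- 1L
  m
})

# digits used when comparing distances to thresholds, avoiding
# floating-point boundary flapping
.DIST_DIGITS <- 6L

# p-distance of an ends-free global alignment. The optimal overlap
# alignment under match +1 / mismatch -1 clips terminal mismatch columns
# into the free end gaps; the columns that *both* sequences could still
# have provided (the shorter flank on each side) are charged back as
# mismatches so that the distance is 0 only for identical sequences while
# genuine end gaps from length differences stay free.
.alignmentDistance <- function(alns, widthA, widthB) {
  len <- nchar(as.character(pattern(alns)))
  mmGap <- (len - score(alns)) / 2
  sp <- pattern(alns)
  ss <- subject(alns)
  extraL <- pmin(BiocGenerics::start(sp) - 1L, BiocGenerics::start(ss) - 1L)
  extraR <- pmin(widthA - BiocGenerics::end(sp), widthB - BiocGenerics::end(ss))
  d <- (mmGap + extraL + extraR) / (len + extraL + extraR)
  round(d, .DIST_DIGITS)
}

#' Pairwise sequence divergence
#'
#' p-distance between two nucleotide sequences under an optimal global
#' alignment with unit mismatch and gap costs and free end gaps:
#' mismatches plus internal gap columns, divided by the alignment length
#' (end gaps excluded). Symmetric; 0 for identical sequences and positive
#' whenever the optimally aligned region differs (a pair whose ends-free
#' alignment is an exact overlap — one sequence extending the other — also
#' scores 0, as end gaps carry no cost). Distances are rounded to six
#' decimals before any threshold comparison.
#'
#' @param a,b Non-empty nucleotide strings (A/C/G/T/N).
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwiseDistance("ACGTACGT", "ACGTACGT")  # 0
#' pairwiseDistance("ACGTACGT", "ACTTACGT")  # 1/8
#' @export
pairwiseDistance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  if (a == b) return(0)
  # canonical orientation: tracebacks among equally optimal alignments can
  # differ in length, so fix which sequence is the pattern to make the
  # distance exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- pairwiseAlignment(Biostrings::DNAStringSet(a), DNAString(b),
                           type = "overlap",
                           substitutionMatrix = .scoreMatrix,
                           gapOpening = 0, gapExtension = 1)
  .alignmentDistance(aln, nchar(a), nchar(b))
}

#' All-pairs divergence matrix of a haplotype set
#'
#' @param haplotypes A [HaplotypeSet-class], named
#'   [Biostrings::DNAStringSet], or named character vector of sequences.
#' @return Symmetric numeric matrix of p-distances with zero diagonal,
#'   dimnames taken from the input names.
#' @export
distanceMatrix <- function(haplotypes) {
  if (methods::is(haplotypes, "HaplotypeSet"))
    haplotypes <- haplotypeSequences(haplotypes)
  seqs <- toupper(as.character(haplotypes))
  ids <- names(seqs) %||% sprintf("SEQ%04d", seq_along(seqs))
  n <- length(seqs)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(dm)
  wid <- nchar(seqs)
  # vectorized over patterns per subject, with the same canonical
  # orientation as pairwiseDistance() (pattern lexicographically smaller
  # than subject) so the matrix is exactly symmetric; identical pairs
  # keep distance 0
  for (j in seq_len(n)) {
    idx <- which(seqs < seqs[j])
    if (length(idx) == 0L) next
    alns <- pairwiseAlignment(Biostrings::DNAStringSet(seqs[idx]),
                              DNAString(seqs[j]), type = "overlap",
                              substitutionMatrix = .scoreMatrix,
                              gapOpening = 0, gapExtension = 1)
    d <- .alignmentDistance(alns, wid[idx], wid[j])
    dm[idx, j] <- d
    dm[j, idx] <- d
  }
  dm
}

# union-find with path compression
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Single-linkage MOTU clustering at one divergence threshold
#'
#' MOTUs are the connected components of the graph joining every pair of
#' haplotypes whose (rounded) distance is at or below the threshold — i.e.
#' the single-linkage partition cut at the threshold. MOTU indices are
#' ordered by decreasing cluster size, ties broken by the lexicographically
#' smallest member sequence (or member id when sequences are not supplied),
#' so the labelling is deterministic.
#'
#' @param dm Symmetric distance matrix as from [distanceMatrix()].
#' @param threshold Divergence threshold in `[0, 1]`.
#' @param sequences Optional named character vector (or
#'   [HaplotypeSet-class]) giving the member sequences used for the
#'   tie-break ordering.
#' @return A [MotuClustering-class].
#' @export
clusterAtThreshold <- function(dm, threshold, sequences = NULL) {
  threshold <- .assertFraction(threshold, "threshold")
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  ids <- rownames(dm) %||% sprintf("SEQ%04d", seq_len(n))
  if (methods::is(sequences, "HaplotypeSet"))
    sequences <- as.character(haplotypeSequences(sequences))
  if (n == 0L)
    return(methods::new("MotuClustering", membership = integer(0),
                        threshold = threshold))
  thr <- round(threshold, .DIST_DIGITS)
  parent <- seq_len(n)
  for (j in seq_len(n - 1L)) for (i in seq(j + 1L, n)) {
    if (round(dm[i, j], .DIST_DIGITS) <= thr) {
      ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  comp <- match(root, unique(root))
  sizes <- tabulate(comp)
  key <- if (!is.null(sequences)) sequences[match(ids, names(sequences) %||% ids)] else ids
  minKey <- vapply(seq_len(max(comp)), function(k) min(key[comp == k]),
                   character(1))
  ord <- order(-sizes, minKey)
  relabel <- match(comp, ord)
  membership <- setNames(as.integer(relabel), ids)
  methods::new("MotuClustering", membership = membership,
               threshold = threshold)
}

#' Sweep MOTU counts over a grid of divergence thresholds
#'
#' Cuts the single-linkage hierarchy at every threshold of the grid and
#' records the MOTU count. Counts are non-increasing in the threshold
#' because single-linkage partitions are nested.
#'
#' @param dm Symmetric distance matrix.
#' @param start,stop Sweep range (fractions, default 0 to 0.10).
#' @param step Grid step (default 0.005).
#' @return A [ThresholdSweep-class] (selected threshold unset).
#' @export
sweepThresholds <- function(dm, start = 0, stop = 0.10, step = 0.005) {
  start <- .assertFraction(start, "start")
  stop <- .assertFraction(stop, "stop")
  stopifnot("'start' must be smaller than 'stop'" = start < stop,
            "'step' must be positive" = is.numeric(step) && step > 0)
  thresholds <- round(seq(start, stop, by = step), .DIST_DIGITS)
  counts <- vapply(thresholds, function(t) nMotus(clusterAtThreshold(dm, t)),
                   integer(1))
  stopifnot(all(diff(counts) <= 0L))  # nesting of single-linkage partitions
  methods::new("ThresholdSweep", thresholds = thresholds,
               motuCounts = counts, selectedThreshold = NA_real_)
}

#' Select the working threshold at the inflection point of the sweep
#'
#' Returns the smallest threshold where the MOTU-count curve has reached its
#' asymptote: the drop in count from that threshold to the next is at most
#' `plateauTolerance` (default 0 — the count stops changing). If the curve
#' never plateaus, the last threshold is returned with a warning.
#'
#' @param sweep A [ThresholdSweep-class] with at least 3 thresholds.
#' @param plateauTolerance Maximum tolerated MOTU-count drop per step.
#' @return The input sweep with `selectedThreshold` filled in; read it with
#'   [selectedThreshold()].
#' @export
selectInflectionThreshold <- function(sweep, plateauTolerance = 0) {
  stopifnot(methods::is(sweep, "ThresholdSweep"))
  th <- sweepThresholdValues(sweep)
  if (length(th) < 3L) stop("sweep must contain at least 3 thresholds")
  drops <- -diff(sweepMotuCounts(sweep))
  idx <- which(drops <= plateauTolerance)
  # the asymptote is reached only once collapsing has begun: skip a flat
  # leading segment (which arises when the grid step is finer than the
  # smallest pairwise distance); a globally constant curve keeps the first
  # threshold
  firstDrop <- which(drops > 0)[1]
  if (!is.na(firstDrop)) idx <- idx[idx > firstDrop]
  if (length(idx) == 0L) {
    warning("MOTU counts never plateau over the sweep; ",
            "returning the last threshold")
    sel <- th[length(th)]
  } else {
    sel <- th[min(idx)]
  }
  methods::initialize(sweep, selectedThreshold = sel)
}

#' Representative sequences of each MOTU
#'
#' For every MOTU, the up-to-three most abundant member haplotypes, ordered
#' by decreasing total abundance with ties broken by the lexicographically
#' smaller sequence. These are the sequences submitted to taxonomic
#' assignment.
#'
#' @param clustering A [MotuClustering-class].
#' @param haplotypes The [HaplotypeSet-class] the clustering was computed
#'   from.
#' @param nRep Maximum representatives per MOTU (default 3).
#' @return `data.frame` with columns `motu_id`, `rank`, `haplotype_id`,
#'   `sequence`, `abundance`.
#' @export
motuRepresentatives <- function(clustering, haplotypes, nRep = 3) {
  memb <- motuMembership(clustering)
  ab <- haplotypeAbundance(haplotypes)
  seqs <- as.character(haplotypeSequences(haplotypes))
  names(seqs) <- names(haplotypeSequences(haplotypes))
  stopifnot(setequal(names(memb), names(ab)))
  out <- lapply(seq_len(nMotus(clustering)), function(k) {
    ids <- names(memb)[memb == k]
    ord <- order(-ab[ids], seqs[ids])
    ids <- ids[ord][seq_len(min(nRep, length(ids)))]
    data.frame(motu_id = sprintf("MOTU%04d", k),
               rank = seq_along(ids), haplotype_id = ids,
               sequence = unname(seqs[ids]),
               abundance = unname(ab[ids]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-sample MOTU presence
#'
#' @param clustering A [MotuClustering-class].
#' @param haplotypes The matching [HaplotypeSet-class].
#' @return `data.frame` with columns `sample` and `resource` (MOTU id), one
#'   row per (sample, MOTU) with at least one read.
#' @export
motuPresence <- function(clustering, haplotypes) {
  memb <- motuMembership(clustering)
  counts <- sampleCounts(haplotypes)
  motu <- sprintf("MOTU%04d", memb[rownames(counts)])
  agg <- rowsum(counts, motu)
  idx <- which(agg > 0, arr.ind = TRUE)
  data.frame(sample = colnames(agg)[idx[, 2]],
             resource = rownames(agg)[idx[, 1]],
             stringsAsFactors = FALSE)
}

#' Write MOTU outputs
#'
#' `writeMotuTable()` writes one row per MOTU (id, threshold, number of
#' haplotypes, total abundance, samples); `writeSweepCurve()` writes the
#' threshold/count curve; `writeRepresentativesFasta()` writes
#' representative sequences with headers `motu_id|rank|abundance`.
#'
#' @param clustering A [MotuClustering-class].
#' @param haplotypes The matching [HaplotypeSet-class].
#' @param sweep A [ThresholdSweep-class].
#' @param reps Result of [motuRepresentatives()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeMotuTable <- function(clustering, haplotypes, file) {
  memb <- motuMembership(clustering)
  counts <- sampleCounts(haplotypes)
  ab <- haplotypeAbundance(haplotypes)
  rows <- lapply(seq_len(nMotus(clustering)), function(k) {
    ids <- names(memb)[memb == k]
    smp <- colnames(counts)[colSums(counts[ids, , drop = FALSE]) > 0]
    data.frame(motu_id = sprintf("MOTU%04d", k),
               threshold = selectedThreshold(clustering),
               n_haplotypes = length(ids),
               total_abundance = sum(ab[ids]),
               samples = paste(smp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeMotuTable
#' @export
writeSweepCurve <- function(sweep, file) {
  write.table(data.frame(threshold = sweepThresholdValues(sweep),
                         motu_count = sweepMotuCounts(sweep)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMotuTable
#' @export
writeRepresentativesFasta <- function(reps, file) {
  out <- Biostrings::DNAStringSet(reps$sequence)
  names(out) <- paste(reps$motu_id, reps$rank, reps$abundance, sep = "|")
  Biostrings::writeXStringSet(out, file)
  invisible(file)
}
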