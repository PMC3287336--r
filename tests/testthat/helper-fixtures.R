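# shared fixtures, all built in code

FWD_PRIMER <- readSimConfig()$primerForward

# small panel + simulated run used by several files; built once
smallPanel <- function(n = 4, seed = 101) generateReferencePanel(n, seed = seed)

smallRun <- function(panel = smallPanel(), seed = 202, readsPerSample = 120,
                     errorRate = 0.005) {
  taxa <- taxonomyTable(panel)$taxon_id
  diet <- list(s1 = taxa[c(1, 2)], s2 = taxa[c(2, 3)],
               s3 = taxa[c(3, 4, 4)])
  simulateReads(panel, diet,
                readSimConfig(readsPerSample = readsPerSample,
                              substitutionErrorRate = errorRate, seed = seed))
}

# hand-buildable haplotype set from explicit sequences/counts
makeHaplotypes <- function(seqs, counts) {
  counts <- as.matrix(counts)
  rownames(counts) <- names(seqs)
  storage.mode(counts) <- "integer"
  hs <- Biostrings::DNAStringSet(seqs)
  names(hs) <- names(seqs)
  methods::new("HaplotypeSet", sequences = hs, sampleCounts = counts)
}

# independent connected-components oracle over a distance matrix
bruteForceComponents <- function(dm, threshold) {
  n <- nrow(dm)
  adj <- round(dm, 6) <= round(threshold, 6)
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    return(igraph::components(g)$membership)
  }
  # fallback: repeated boolean closure
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { k <- k + 1L; comp[reach[i, ]] <- k }
  }
  comp
}

# partitions equal up to label permutation
samePartition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
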