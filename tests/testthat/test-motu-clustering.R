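test_that("pairwise distance matches direct counting and is symmetric", {
  a <- strrep("ACGT", 39)                       # 156-mers for clean arithmetic
  expect_equal(pairwiseDistance(a, a), 0)

  s157 <- paste0(a, "A")
  one <- s157
  substr(one, 80, 80) <- "C"                    # interior substitution
  expect_equal(pairwiseDistance(s157, one), round(1 / 157, 6))

  # terminal substitution still counts: distance is 0 only for identity
  last <- s157
  substr(last, 157, 157) <- "C"
  expect_equal(pairwiseDistance(s157, last), round(1 / 157, 6))

  # one internal deletion: one gap column
  del <- paste0(substr(s157, 1, 80), substr(s157, 82, 157))
  expect_equal(pairwiseDistance(s157, del), round(1 / 157, 6))

  # symmetry on random pairs
  set.seed(42)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_identical(pairwiseDistance(x, y), pairwiseDistance(y, x))
  }
  expect_error(pairwiseDistance("", "ACGT"), "non-empty")
})

test_that("single-linkage clustering equals the connected-components oracle", {
  # chain A-B 1.5%, B-C 1.5%, A-C 3%: one MOTU at 2%
  dm <- matrix(c(0, 0.015, 0.03,
                 0.015, 0, 0.015,
                 0.03, 0.015, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- clusterAtThreshold(dm, 0.02)
  expect_identical(nMotus(cl), 1L)

  # zero threshold: one MOTU per distinct sequence
  set.seed(13)
  seqs <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
    character(1)), c("h1", "h2", "h3"))
  dm0 <- distanceMatrix(seqs)
  expect_identical(nMotus(clusterAtThreshold(dm0, 0)), 3L)

  # random instances of <= 12 haplotypes vs the exhaustive oracle
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- round(runif(n * (n - 1) / 2, 0, 0.08), 6)
    d <- d + t(d)
    dimnames(d) <- list(paste0("h", 1:n), paste0("h", 1:n))
    thr <- runif(1, 0, 0.08)
    ours <- motuMembership(clusterAtThreshold(d, thr))
    oracle <- bruteForceComponents(d, thr)
    expect_true(samePartition(unname(ours), unname(oracle)))
  }
})

test_that("partitions nest: each haplotype in exactly one MOTU, refined as thresholds drop", {
  sim <- smallRun(readsPerSample = 100)
  hs <- filterAmplicons(sim$reads, sim$tagMap, FWD_PRIMER)$haplotypes
  dm <- distanceMatrix(hs)
  thresholds <- c(0, 0.01, 0.02, 0.05, 0.1)
  parts <- lapply(thresholds, function(t) motuMembership(clusterAtThreshold(dm, t)))
  for (p in parts) {
    expect_identical(sort(names(p)), sort(names(haplotypeSequences(hs))))
    expect_false(anyNA(p))
  }
  # refinement: together at a smaller threshold implies together at a larger one
  for (i in seq_len(length(thresholds) - 1)) {
    a <- parts[[i]]; b <- parts[[i + 1]]
    sameA <- outer(a, a, "==")
    sameB <- outer(b, b, "==")
    expect_true(all(sameB[sameA]))
  }
})

test_that("threshold sweep counts are non-increasing and plateau where constructed", {
  # degenerate: identical haplotypes collapse to one MOTU everywhere
  dmId <- matrix(0, 3, 3, dimnames = list(paste0("h", 1:3), paste0("h", 1:3)))
  swId <- sweepThresholds(dmId)
  expect_true(all(sweepMotuCounts(swId) == 1L))

  # constructed panel: counts reach the number of taxa and plateau over [2%, 4%)
  panel <- generateReferencePanel(10, seed = 31)
  sim <- simulateReads(panel,
                       setNames(split(taxonomyTable(panel)$taxon_id,
                                      rep(1:5, each = 2)),
                                paste0("s", 1:5)),
                       readSimConfig(readsPerSample = 150, seed = 32))
  hs <- filterAmplicons(sim$reads, sim$tagMap, FWD_PRIMER)$haplotypes
  sw <- sweepThresholds(distanceMatrix(hs))
  counts <- sweepMotuCounts(sw)
  th <- sweepThresholdValues(sw)
  expect_true(all(diff(counts) <= 0))
  plateau <- th >= 0.02 & th < 0.04
  expect_true(all(counts[plateau] == 10L))
})

test_that("inflection selection finds the asymptote of the MOTU curve", {
  mk <- function(th, counts) methods::new("ThresholdSweep",
    thresholds = th, motuCounts = as.integer(counts),
    selectedThreshold = NA_real_)

  sw <- mk(c(0, 0.01, 0.02, 0.03, 0.04), c(100, 60, 50, 50, 49))
  expect_equal(selectedThreshold(selectInflectionThreshold(sw)), 0.02)

  # strictly decreasing: last threshold with a warning
  sw2 <- mk(c(0, 0.01, 0.02, 0.03), c(40, 30, 20, 10))
  expect_warning(sel2 <- selectInflectionThreshold(sw2), "plateau")
  expect_equal(selectedThreshold(sel2), 0.03)

  # constant curve: first threshold
  sw3 <- mk(c(0, 0.01, 0.02), c(5, 5, 5))
  expect_equal(selectedThreshold(selectInflectionThreshold(sw3)), 0)

  # a flat leading segment (grid finer than the minimum distance) is not
  # the asymptote
  sw4 <- mk(c(0, 0.005, 0.01, 0.015, 0.02, 0.025),
            c(17, 17, 13, 11, 5, 5))
  expect_equal(selectedThreshold(selectInflectionThreshold(sw4)), 0.02)

  # tolerance admits small drops
  sw5 <- mk(c(0, 0.01, 0.02, 0.03), c(100, 60, 59, 59))
  expect_equal(selectedThreshold(selectInflectionThreshold(sw5, 1)), 0.01)
})

test_that("representatives are the up-to-three most abundant members, ties lexicographic", {
  seqs <- setNames(c("AAAA", "CCCC", "GGGG", "TTTT"), paste0("h", 1:4))
  counts <- cbind(s1 = c(10L, 5L, 2L, 1L))
  hs <- makeHaplotypes(seqs, counts)
  dm <- matrix(0.001, 4, 4, dimnames = list(names(seqs), names(seqs)))
  diag(dm) <- 0
  cl <- clusterAtThreshold(dm, 0.02, hs)
  reps <- motuRepresentatives(cl, hs)
  expect_identical(nrow(reps), 3L)
  expect_identical(reps$haplotype_id, c("h1", "h2", "h3"))
  expect_identical(reps$abundance, c(10L, 5L, 2L))

  # tie at rank 3: lexicographically smaller sequence wins, deterministically
  counts2 <- cbind(s1 = c(10L, 5L, 2L, 2L))
  hs2 <- makeHaplotypes(seqs, counts2)
  reps2 <- motuRepresentatives(clusterAtThreshold(dm, 0.02, hs2), hs2)
  expect_identical(reps2$sequence[3], "GGGG")

  # two-member cluster returns both
  hs3 <- makeHaplotypes(seqs[1:2], cbind(s1 = c(3L, 1L)))
  dm3 <- dm[1:2, 1:2]
  reps3 <- motuRepresentatives(clusterAtThreshold(dm3, 0.02, hs3), hs3)
  expect_identical(nrow(reps3), 2L)
})

test_that("planted taxa are recovered exactly at the selected threshold", {
  for (K in c(3, 7)) {
    panel <- generateReferencePanel(K, seed = 50 + K)
    taxa <- taxonomyTable(panel)$taxon_id
    diet <- setNames(lapply(seq_len(K), function(i) taxa[i]),
                     paste0("s", seq_len(K)))
    sim <- simulateReads(panel, diet,
                         readSimConfig(readsPerSample = 120,
                                       substitutionErrorRate = 0.005,
                                       seed = 60 + K))
    hs <- filterAmplicons(sim$reads, sim$tagMap, FWD_PRIMER)$haplotypes
    dm <- distanceMatrix(hs)
    sw <- selectInflectionThreshold(sweepThresholds(dm))
    cl <- clusterAtThreshold(dm, selectedThreshold(sw), hs)
    expect_identical(nMotus(cl), as.integer(K))
  }
})

test_that("MOTU exports carry the documented formats", {
  sim <- smallRun(readsPerSample = 80)
  hs <- filterAmplicons(sim$reads, sim$tagMap, FWD_PRIMER)$haplotypes
  dm <- distanceMatrix(hs)
  cl <- clusterAtThreshold(dm, 0.02, hs)
  reps <- motuRepresentatives(cl, hs)

  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(fileext = ".fasta")
  writeMotuTable(cl, hs, f1)
  tab <- read.delim(f1)
  expect_identical(nrow(tab), nMotus(cl))
  expect_identical(sum(tab$n_haplotypes), length(hs))

  writeSweepCurve(sweepThresholds(dm, 0, 0.05, 0.01), f2)
  expect_identical(names(read.delim(f2)), c("threshold", "motu_count"))

  writeRepresentativesFasta(reps, f3)
  fa <- Biostrings::readDNAStringSet(f3)
  expect_match(names(fa)[1], "^MOTU0001\\|1\\|")
})
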