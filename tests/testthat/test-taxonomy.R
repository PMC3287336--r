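referenceFixture <- function() {
  set.seed(91)
  mkSeq <- function() paste(sample(c("A", "C", "G", "T"), 157, TRUE),
                            collapse = "")
  seqs <- c(ref1 = mkSeq(), ref2 = mkSeq(), ref3 = mkSeq(), ref4 = mkSeq())
  records <- data.frame(
    id = names(seqs),
    order = c("Lepidoptera", "Lepidoptera", "Lepidoptera", "Diptera"),
    family = c("Noctuidae", "Noctuidae", "Noctuidae", "Tipulidae"),
    genus = c("Noctua", "Agrotis", "Noctua", "Tipula"),
    species = c("Noctua pronuba", "Agrotis puta", "Noctua comes",
                "Tipula oleracea"),
    in_checklist = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- records$id
  list(sequences = ss, records = records)
}

mutateAt <- function(seq, n) {
  v <- strsplit(seq, "")[[1]]
  pos <- seq(5, by = 7, length.out = n)       # deterministic interior sites
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

test_that("similarity search scores, sorts and matches brute force", {
  ref <- referenceFixture()
  q <- as.character(ref$sequences[["ref1"]])
  hits <- similaritySearch(q, ref)
  expect_identical(hits$id[1], "ref1")
  expect_equal(hits$similarity[1], 1.0)

  # one mismatch from a 157-base reference: 1 - 1/157
  hits2 <- similaritySearch(mutateAt(q, 1), ref)
  expect_equal(hits2$similarity[1], round(1 - 1 / 157, 6))

  # ordering agrees with exhaustive pairwise computation
  q3 <- mutateAt(q, 3)
  hits3 <- similaritySearch(q3, ref)
  brute <- vapply(as.character(ref$sequences), function(s)
    1 - pairwiseDistance(q3, s), numeric(1))
  expect_identical(hits3$id, names(sort(brute, decreasing = TRUE)))

  expect_error(similaritySearch(q, list(sequences = NULL, records = NULL)),
               "empty")
})

test_that("the tiered confidence scheme follows the match rules", {
  hit <- function(species, genus, family, order, sim, uk = TRUE) {
    data.frame(id = species, order = order, family = family, genus = genus,
               species = species, in_checklist = uk, similarity = sim,
               stringsAsFactors = FALSE)
  }
  # solid match to one species: level 1, species rank
  a1 <- assignConfidence(hit("Noctua pronuba", "Noctua", "Noctuidae",
                             "Lepidoptera", 0.992))
  expect_identical(a1$confidence_level, 1L)
  expect_identical(a1$assigned_rank, "species")
  expect_identical(a1$assigned_name, "Noctua pronuba")

  # several species of one genus: level 1, genus rank
  a1g <- assignConfidence(rbind(
    hit("Noctua pronuba", "Noctua", "Noctuidae", "Lepidoptera", 0.992),
    hit("Noctua comes", "Noctua", "Noctuidae", "Lepidoptera", 0.990)))
  expect_identical(a1g$confidence_level, 1L)
  expect_identical(a1g$assigned_rank, "genus")
  expect_identical(a1g$assigned_name, "Noctua")

  # two genera, one checklist species: level 2, the checklist species
  a2 <- assignConfidence(rbind(
    hit("Noctua pronuba", "Noctua", "Noctuidae", "Lepidoptera", 0.990, TRUE),
    hit("Agrotis exotica", "Agrotis", "Noctuidae", "Lepidoptera", 0.990, FALSE)))
  expect_identical(a2$confidence_level, 2L)
  expect_identical(a2$assigned_rank, "species")
  expect_identical(a2$assigned_name, "Noctua pronuba")

  # three genera of one family at 98.2%: level 3, family rank
  a3 <- assignConfidence(rbind(
    hit("Apamea crenata", "Apamea", "Noctuidae", "Lepidoptera", 0.982),
    hit("Noctua comes", "Noctua", "Noctuidae", "Lepidoptera", 0.982),
    hit("Agrotis puta", "Agrotis", "Noctuidae", "Lepidoptera", 0.981)))
  expect_identical(a3$confidence_level, 3L)
  expect_identical(a3$assigned_rank, "family")
  expect_identical(a3$assigned_name, "Noctuidae")

  # best hit below every threshold: unknown
  a4 <- assignConfidence(hit("Noctua pronuba", "Noctua", "Noctuidae",
                             "Lepidoptera", 0.97))
  expect_identical(a4$assigned_rank, "unknown")
  expect_true(is.na(a4$confidence_level))
})

test_that("lowering the species threshold never demotes level 1/2 to 3/unknown", {
  ref <- referenceFixture()
  set.seed(17)
  for (i in 1:8) {
    base <- as.character(ref$sequences[[sample(4, 1)]])
    q <- mutateAt(base, sample(0:2, 1))
    hits <- similaritySearch(q, ref)
    hi <- assignConfidence(hits, speciesThreshold = 0.99)
    lo <- assignConfidence(hits, speciesThreshold = 0.985)
    if (!is.na(hi$confidence_level) && hi$confidence_level <= 2L)
      expect_lte(lo$confidence_level, 2L)
  }
})

test_that("error-free representatives from the panel get level-1 species calls", {
  panel <- smallPanel(5, seed = 71)
  ref <- referenceLibraryFromPanel(panel)
  tax <- taxonomyTable(panel)
  for (i in seq_len(5)) {
    a <- assignMotu(as.character(baseSequences(panel)[[i]]), ref)
    expect_identical(a$confidence_level, 1L)
    expect_identical(a$assigned_rank, "species")
    expect_identical(a$assigned_name, tax$species[i])
  }
})

test_that("conflicting representatives degrade to the deepest agreeing rank", {
  ref <- referenceFixture()
  s1 <- as.character(ref$sequences[["ref1"]])   # Noctua pronuba
  s3 <- as.character(ref$sequences[["ref3"]])   # Noctua comes, same genus
  s4 <- as.character(ref$sequences[["ref4"]])   # Tipula oleracea

  same <- assignMotu(c(s1, s1), ref)
  expect_identical(same$assigned_rank, "species")

  genusAgree <- assignMotu(c(s1, s3), ref)
  expect_identical(genusAgree$assigned_rank, "genus")
  expect_identical(genusAgree$assigned_name, "Noctua")

  noAgree <- assignMotu(c(s1, s4), ref)
  expect_identical(noAgree$assigned_rank, "unknown")
})

test_that("reference libraries round-trip through FASTA", {
  panel <- smallPanel(3, seed = 81)
  ref <- referenceLibraryFromPanel(panel, checklist = taxonomyTable(panel)$species[1:2])
  f <- tempfile(fileext = ".fasta")
  hdr <- with(ref$records, paste(id, order, family, genus, species,
                                 as.integer(in_checklist), sep = "|"))
  out <- ref$sequences
  names(out) <- hdr
  Biostrings::writeXStringSet(out, f)
  back <- readReferenceLibrary(f)
  expect_identical(back$records, ref$records)
  expect_identical(as.character(back$sequences), as.character(ref$sequences))
})

test_that("richness inflation reproduces the MOTU-vs-species overestimate", {
  expect_identical(richnessInflation(59, 52), 12L)
  expect_identical(richnessInflation(10, 10), 0L)
  expect_identical(richnessInflation(100, 75), 25L)
  expect_error(richnessInflation(50, 52), "exceed")
})
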