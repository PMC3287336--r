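test_that("utilization matrices count samples containing each resource", {
  presence <- data.frame(
    sample = c("f1", "f2", "f1", "f3", "f3"),
    predator = c("P1", "P1", "P1", "P1", "P1"),
    resource = c("R", "R", "Q", "Q", "Q"))
  um <- buildUtilizationMatrix(presence)
  m <- occurrenceCounts(um)
  expect_identical(m["R", "P1"], 2L)
  expect_identical(m["Q", "P1"], 2L)

  # empty input gives an empty matrix
  e <- buildUtilizationMatrix(presence[0, ])
  expect_identical(dim(occurrenceCounts(e)), c(0L, 0L))

  # a sample in two predators is rejected
  bad <- rbind(presence,
               data.frame(sample = "f1", predator = "P2", resource = "R"))
  expect_error(buildUtilizationMatrix(bad), "exactly one predator")

  # the packaged fixture round-trips through build
  umF <- loadTable1Fixture()
  long <- do.call(rbind, lapply(predatorNames(umF), function(p) {
    counts <- occurrenceCounts(umF)[, p]
    do.call(rbind, lapply(names(counts)[counts > 0], function(r) {
      data.frame(sample = paste0(p, "_b", seq_len(counts[r])),
                 predator = p, resource = r)
    }))
  }))
  rebuilt <- buildUtilizationMatrix(long)
  m2 <- occurrenceCounts(rebuilt)[resourceNames(umF), predatorNames(umF)]
  expect_identical(unname(m2), unname(occurrenceCounts(umF)))
})

test_that("percent frequency of occurrence follows its printed definition", {
  so <- data.frame(sample = c("f1", "f1", "f2", "f3"), predator = "P1",
                   order = c("Lepidoptera", "Diptera", "Lepidoptera",
                             "Lepidoptera"))
  fo <- percentFoByOrder(so, "P1")
  expect_equal(unname(fo["Lepidoptera"]), 75)
  expect_equal(unname(fo["Diptera"]), 25)

  # single order: 100%
  one <- percentFoByOrder(data.frame(sample = c("f1", "f2"), predator = "P",
                                     order = "Lepidoptera"), "P")
  expect_equal(unname(one), 100)

  # normalization on random inputs
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    so2 <- data.frame(sample = paste0("f", sample(10, n, TRUE)),
                      predator = "P",
                      order = sample(LETTERS[1:4], n, TRUE))
    expect_lt(abs(sum(percentFoByOrder(so2, "P")) - 100), 0.01)
  }
  expect_error(percentFoByOrder(so, "absent"), "no order occurrences")
})

test_that("Levins breadth matches hand evaluation and its bounds", {
  # uniform use of n resources: B = n, BA = 1
  u <- levinsBreadth(rep(2, 6))
  expect_equal(u$B, 6)
  expect_equal(u$BA, 1)
  # single resource: B = 1, BA = 0
  s <- levinsBreadth(c(0, 5, 0))
  expect_equal(s$B, 1)
  expect_equal(s$BA, 0)
  # counts (2,1,1): B = 8/3, BA = 5/6
  h <- levinsBreadth(c(2, 1, 1))
  expect_equal(h$B, 8 / 3)
  expect_equal(h$BA, 5 / 6)
  # n = 1 convention and the pool precondition
  expect_equal(levinsBreadth(5, nResources = 1)$BA, 0)
  expect_error(levinsBreadth(c(1, 1, 1), nResources = 2), "at least")
})

test_that("Shannon diversity matches hand evaluation and vegan", {
  expect_equal(shannonDiversity(rep(1, 4)), log(4))
  expect_equal(shannonDiversity(c(0, 7, 0)), 0)
  expect_equal(shannonDiversity(c(2, 1, 1)), 1.0397208, tolerance = 1e-6)
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:5) {
    counts <- sample(0:20, 10, TRUE)
    counts[1] <- counts[1] + 1
    expect_equal(shannonDiversity(counts),
                 unname(vegan::diversity(counts, index = "shannon")))
  }
})

test_that("Pianka overlap matches hand evaluation, bounds and symmetry", {
  expect_equal(piankaOverlap(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(piankaOverlap(c(1, 0, 2, 0), c(0, 4, 0, 1)), 0)
  expect_equal(piankaOverlap(c(2, 1, 1, 0), c(1, 1, 0, 2)), 0.5)
  expect_error(piankaOverlap(c(0, 0), c(1, 2)), "at least one resource")

  set.seed(21)
  for (i in 1:20) {
    x <- sample(0:10, 8, TRUE); y <- sample(0:10, 8, TRUE)
    x[1] <- x[1] + 1; y[2] <- y[2] + 1
    o <- piankaOverlap(x, y)
    expect_gte(o, 0); expect_lte(o, 1)
    expect_equal(o, piankaOverlap(y, x))
    # invariance to rescaling either count vector
    expect_equal(o, piankaOverlap(3 * x, y))
    expect_equal(o, piankaOverlap(x, 7 * y))
  }
})

test_that("estimators agree with direct-formula oracles on small instances", {
  # exhaustive check over every composition of <= 5 resources
  set.seed(30)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    counts <- sample(1:9, n, TRUE)
    p <- counts / sum(counts)
    expect_equal(levinsBreadth(counts)$B, 1 / sum(p^2))
    expect_equal(shannonDiversity(counts), -sum(p * log(p)))
    other <- sample(0:9, n, TRUE); other[1] <- other[1] + 1
    q <- other / sum(other)
    expect_equal(piankaOverlap(counts, other),
                 sum(p * q) / sqrt(sum(p^2) * sum(q^2)))
  }
  # scale invariance of breadth and diversity
  counts <- c(4, 2, 1)
  expect_equal(levinsBreadth(counts)$BA, levinsBreadth(counts * 13)$BA)
  expect_equal(shannonDiversity(counts), shannonDiversity(counts * 13))
})

test_that("family shares and order counts reproduce the worked example", {
  um <- loadTable1Fixture()
  expect_equal(familyShare(um, "P. austriacus", "Lepidoptera", "Noctuidae"), 71)
  expect_equal(familyShare(um, "P. auritus", "Lepidoptera", "Noctuidae"),
               100 * 45 / 54)
  # the family covering its whole order saturates at 100
  expect_equal(familyShare(um, "P. austriacus", "Neuroptera", "Chrysopidae"),
               100)
  expect_error(familyShare(um, "P. auritus", "Neuroptera", "Chrysopidae"),
               "absent")
  expect_identical(unname(ordersPerPredator(um)),
                   c(6L, 5L))
})

test_that("per-sample summaries follow the configured SD convention", {
  pres <- data.frame(
    sample = rep(c("f1", "f2", "f3"), times = c(3, 5, 7)),
    resource = paste0("R", c(1:3, 1:5, 1:7)))
  s <- sampleSummary(pres)
  expect_equal(s$mean, 5)
  expect_identical(s$min, 3L)
  expect_identical(s$max, 7L)
  expect_equal(s$sd, sd(c(3, 5, 7)))

  one <- sampleSummary(data.frame(sample = "f1", resource = c("a", "b")),
                       convention = "population")
  expect_equal(one$sd, 0)

  # zero-error synthetic truth: per-sample MOTU counts equal planted counts
  panel <- smallPanel(4, seed = 55)
  taxa <- taxonomyTable(panel)$taxon_id
  diet <- list(s1 = taxa[1:3], s2 = taxa[1:2], s3 = taxa[4])
  sim <- simulateReads(panel, diet,
                       readSimConfig(readsPerSample = 400,
                                     substitutionErrorRate = 0, seed = 56))
  hs <- filterAmplicons(sim$reads, sim$tagMap, FWD_PRIMER)$haplotypes
  dm <- distanceMatrix(hs)
  cl <- clusterAtThreshold(dm, 0.02, hs)
  pres2 <- motuPresence(cl, hs)
  s2 <- sampleSummary(pres2)
  expect_identical(s2$perSample[c("s1", "s2", "s3")],
                   c(s1 = 3L, s2 = 2L, s3 = 1L))
})
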