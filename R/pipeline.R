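#' Read a pipeline run configuration from YAML
#'
#' A flat-key YAML file whose entries mirror the arguments of
#' [runPipeline()]: input paths (`reads`, `tagMap`, `reference`,
#' `habitatTable`), filter parameters (`primer`, `minLength`,
#' `singletonScope`), clustering parameters (`sweepStart`, `sweepStop`,
#' `sweepStep`, `plateauTolerance`, `fixedThreshold`), assignment
#' thresholds (`speciesThreshold`, `familyThreshold`), null-model
#' parameters (`nIterations`, `seed`) and `outputDir`. Referenced files
#' must exist.
#'
#' @param file YAML path.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  for (f in intersect(c("reads", "tagMap", "reference", "habitatTable"),
                      names(cfg))) {
    if (!file.exists(cfg[[f]]))
      stop("configured input file does not exist: ", cfg[[f]])
  }
  cfg
}

.stageSeed <- function(seed, stage) {
  # one global seed split deterministically into per-stage seeds
  .splitSeed(seed, match(stage, c("simulate", "cluster", "null")))
}

#' Run the full diet-metabarcoding workflow
#'
#' Executes the stages in their fixed order: demultiplex (exact tag+primer)
#' -> length filter -> dereplicate -> singleton removal -> pairwise
#' distances -> threshold sweep and inflection-point selection (or a fixed
#' threshold override) -> MOTU representatives and taxonomic assignment ->
#' utilization matrix and niche descriptors -> RA3 overlap null test ->
#' optional habitat contingency test. Returns a manifest recording
#' parameters, seeds and per-stage record counts alongside every stage
#' output; when `outputDir` is given, stage outputs are also written as
#' FASTA/TSV/JSON files.
#'
#' In fixture-only mode (`utilizationMatrix` supplied instead of reads) the
#' sequence stages are skipped and only the diet statistics, null model and
#' habitat stages run.
#'
#' @param reads Named [Biostrings::DNAStringSet] of raw tagged reads, or a
#'   FASTA/FASTQ path.
#' @param tagMap Tag-to-sample map (`data.frame` with `tag`, `sample_id`,
#'   or a TSV path).
#' @param primer Forward primer sequence.
#' @param sampleMetadata `data.frame` with columns `sample_id` and
#'   `predator` assigning every sample to a predator species.
#' @param reference Reference library (list from [readReferenceLibrary()],
#'   or a FASTA path); `NULL` skips taxonomic assignment.
#' @param habitatTable Named species-to-class vector (or TSV path); `NULL`
#'   skips the habitat stage.
#' @param utilizationMatrix A [UtilizationMatrix-class] for fixture-only
#'   mode; when supplied, `reads`/`tagMap`/`reference` are ignored.
#' @param minLength Minimum trimmed read length (default 141).
#' @param singletonScope Singleton-removal scope (default `"global"`).
#' @param sweepStart,sweepStop,sweepStep Threshold sweep grid (defaults 0,
#'   0.10, 0.005).
#' @param plateauTolerance Plateau tolerance for threshold selection
#'   (default 0).
#' @param fixedThreshold Optional fixed divergence threshold overriding the
#'   sweep selection.
#' @param speciesThreshold,familyThreshold Assignment similarity thresholds
#'   (defaults 0.985 and 0.98).
#' @param nIterations Null-model iterations (default 10000).
#' @param seed Global seed, split deterministically into per-stage seeds
#'   (default 1).
#' @param outputDir Optional directory for stage outputs.
#' @return A list with elements `manifest`, `haplotypes`, `clustering`,
#'   `sweep`, `representatives`, `assignments`, `utilizationMatrix`,
#'   `descriptors`, `nullTest`, and `habitatTest` (elements are `NULL` for
#'   skipped stages).
#' @export
runPipeline <- function(reads = NULL, tagMap = NULL, primer = NULL,
                        sampleMetadata = NULL, reference = NULL,
                        habitatTable = NULL, utilizationMatrix = NULL,
                        minLength = 141, singletonScope = "global",
                        sweepStart = 0, sweepStop = 0.10, sweepStep = 0.005,
                        plateauTolerance = 0, fixedThreshold = NULL,
                        speciesThreshold = 0.985, familyThreshold = 0.98,
                        nIterations = 10000, seed = 1, outputDir = NULL) {
  seed <- .assertCount(seed, "seed", min = 0L)
  manifest <- list(parameters = list(
    minLength = minLength, singletonScope = singletonScope,
    sweep = c(sweepStart, sweepStop, sweepStep),
    plateauTolerance = plateauTolerance,
    fixedThreshold = fixedThreshold,
    speciesThreshold = speciesThreshold, familyThreshold = familyThreshold,
    nIterations = nIterations, seed = seed))
  out <- list(manifest = NULL, haplotypes = NULL, clustering = NULL,
              sweep = NULL, representatives = NULL, assignments = NULL,
              utilizationMatrix = NULL, descriptors = NULL, nullTest = NULL,
              habitatTest = NULL)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(utilizationMatrix)) {
    if (is.character(reads)) reads <- readAmplicons(reads)
    if (is.character(tagMap)) tagMap <- readTagMap(tagMap)
    stopifnot(!is.null(reads), !is.null(tagMap), !is.null(primer),
              !is.null(sampleMetadata))

    filt <- stage("filter", filterAmplicons(reads, tagMap, primer,
                                            minLength, singletonScope))
    hs <- filt$haplotypes
    manifest$filter <- filt$report
    out$haplotypes <- hs

    dm <- stage("distance", distanceMatrix(hs))
    sweep <- stage("sweep", sweepThresholds(dm, sweepStart, sweepStop,
                                            sweepStep))
    sweep <- selectInflectionThreshold(sweep, plateauTolerance)
    thr <- fixedThreshold %||% selectedThreshold(sweep)
    clus <- stage("cluster", clusterAtThreshold(dm, thr, hs))
    out$sweep <- sweep
    out$clustering <- clus
    manifest$clustering <- list(nHaplotypes = length(hs),
                                selectedThreshold = thr,
                                nMotus = nMotus(clus))

    reps <- stage("representatives", motuRepresentatives(clus, hs))
    out$representatives <- reps
    if (!is.null(reference)) {
      if (is.character(reference)) reference <- readReferenceLibrary(reference)
      asn <- stage("assign", assignAllMotus(reps, reference,
                                            speciesThreshold,
                                            familyThreshold))
      out$assignments <- asn
      manifest$assignment <- list(
        nAssigned = sum(asn$assigned_rank != "unknown"),
        byLevel = as.list(table(asn$confidence_level)))
    }

    presence <- motuPresence(clus, hs)
    presence$predator <- sampleMetadata$predator[
      match(presence$sample, sampleMetadata$sample_id)]
    if (anyNA(presence$predator))
      stop("sampleMetadata does not cover all samples")
    resInfo <- NULL
    if (!is.null(out$assignments)) {
      resInfo <- out$assignments[, c("motu_id", "order", "family", "species")]
      names(resInfo)[1] <- "resource"
    }
    um <- stage("dietstats", buildUtilizationMatrix(presence, resInfo))
  } else {
    um <- utilizationMatrix
  }
  out$utilizationMatrix <- um
  manifest$utilization <- list(nResources = nrow(occurrenceCounts(um)),
                               predators = predatorNames(um))

  out$descriptors <- stage("dietstats", nicheDescriptors(um))
  if (ncol(occurrenceCounts(um)) >= 2L && nrow(occurrenceCounts(um)) >= 2L) {
    out$nullTest <- stage("nulltest",
      overlapNullTest(um, nIterations = nIterations,
                      seed = .stageSeed(seed, "null")))
    manifest$nullTest <- list(observed = observedOverlap(out$nullTest),
                              pValue = pValue(out$nullTest),
                              nIterations = nIterations)
  }

  if (!is.null(habitatTable)) {
    if (is.character(habitatTable)) habitatTable <- readHabitatTable(habitatTable)
    out$habitatTest <- stage("habitat", {
      tab <- classifyDiet(um, habitatTable, specialistsOnly = TRUE)
      c(list(table = tab), chiSquareIndependence(tab))
    })
    manifest$habitat <- list(statistic = out$habitatTest$statistic,
                             df = out$habitatTest$df,
                             p.value = out$habitatTest$p.value)
  }

  out$manifest <- manifest
  if (!is.null(outputDir)) .writePipelineOutputs(out, outputDir)
  out
}

.writePipelineOutputs <- function(out, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outputDir, f)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(out$sweep)) writeSweepCurve(out$sweep, p("sweep_curve.tsv"))
  if (!is.null(out$clustering) && !is.null(out$haplotypes))
    writeMotuTable(out$clustering, out$haplotypes, p("motu_table.tsv"))
  if (!is.null(out$representatives))
    writeRepresentativesFasta(out$representatives, p("representatives.fasta"))
  if (!is.null(out$assignments))
    write.table(out$assignments, p("assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$utilizationMatrix))
    writeUtilizationMatrix(out$utilizationMatrix, p("utilization_matrix.tsv"))
  if (!is.null(out$descriptors))
    write.table(out$descriptors, p("niche_descriptors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$nullTest))
    writeNullModelResult(out$nullTest, p("null_test.json"),
                         p("null_distribution.tsv"))
  invisible(outputDir)
}
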