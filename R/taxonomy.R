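#' Read a local taxonomy-annotated reference library
#'
#' The library stands in for an online barcode reference database: a FASTA
#' file whose headers follow
#' `id|order|family|genus|species|checklist_flag`, where `checklist_flag`
#' is 1 when the species is on the regional checklist. `Unknown` (or empty)
#' genus/species fields mark records identified only to a higher rank.
#'
#' @param file FASTA path.
#' @return A list with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `records` (`data.frame` with columns `id`, `order`, `family`, `genus`,
#'   `species`, `in_checklist`).
#' @export
readReferenceLibrary <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 6L))
    stop("reference headers must be 'id|order|family|genus|species|checklist_flag'")
  records <- data.frame(
    id = vapply(parts, `[`, "", 1L),
    order = vapply(parts, `[`, "", 2L),
    family = vapply(parts, `[`, "", 3L),
    genus = vapply(parts, `[`, "", 4L),
    species = vapply(parts, `[`, "", 5L),
    in_checklist = vapply(parts, `[`, "", 6L) == "1",
    stringsAsFactors = FALSE
  )
  names(seqs) <- records$id
  list(sequences = seqs, records = records)
}

#' Build a reference library from a mock panel
#'
#' Convenience for synthetic end-to-end runs: every variant of every panel
#' taxon becomes a reference record carrying the taxon's lineage.
#'
#' @param panel A [MockTaxonPanel-class].
#' @param checklist Character vector of species names on the regional
#'   checklist (defaults to all panel species).
#' @return A reference library list as from [readReferenceLibrary()].
#' @export
referenceLibraryFromPanel <- function(panel, checklist = NULL) {
  tax <- taxonomyTable(panel)
  if (is.null(checklist)) checklist <- tax$species
  vs <- variantSequences(panel)
  rows <- lapply(seq_len(nrow(tax)), function(i) {
    nv <- length(vs[[i]])
    data.frame(id = sprintf("%s_v%d", tax$taxon_id[i], seq_len(nv)),
               order = tax$order[i], family = tax$family[i],
               genus = tax$genus[i], species = tax$species[i],
               in_checklist = tax$species[i] %in% checklist,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  seqs <- Biostrings::DNAStringSet(unlist(lapply(vs, as.character)))
  names(seqs) <- records$id
  list(sequences = seqs, records = records)
}

#' Similarity search against the reference library
#'
#' Scores every reference record as `1 - pairwiseDistance(query, record)`
#' and returns the hit list sorted by decreasing similarity, ties broken by
#' lexicographic lineage order.
#'
#' @param query Nucleotide string.
#' @param reference Reference library list (see [readReferenceLibrary()]).
#' @return `data.frame` of hits with the record columns plus `similarity`.
#' @export
similaritySearch <- function(query, reference) {
  records <- reference$records
  if (is.null(records) || nrow(records) == 0L)
    stop("reference library is empty")
  seqs <- as.character(reference$sequences)
  sim <- 1 - vapply(seqs, pairwiseDistance, numeric(1), a = query)
  hits <- cbind(records, similarity = round(unname(sim), .DIST_DIGITS))
  hits[order(-hits$similarity, hits$order, hits$family, hits$genus,
             hits$species), , drop = FALSE]
}

.isSpeciesAnnotated <- function(hits) {
  !(hits$species %in% c("", "Unknown", "unknown", NA))
}

# hits considered "matching": every hit above the threshold, or every hit
# within the tie window of the best hit, whichever set is larger --
# a reproducible analogue of reading a reference database's top hit page
.matchSet <- function(hits, threshold, tieWindow) {
  above <- hits[hits$similarity > threshold, , drop = FALSE]
  window <- hits[hits$similarity >= max(hits$similarity) - tieWindow, ,
                 drop = FALSE]
  if (nrow(above) >= nrow(window)) above else window
}

#' Tiered confidence assignment from a scored hit list
#'
#' Implements the three-tier identification scheme used when short
#' barcodes match several reference species:
#' \itemize{
#'  \item Level 1 — all matching hits above the species threshold name one
#'    species (species-level), or all share one genus (genus-level);
#'  \item Level 2 — matching hits span several genera but exactly one hit
#'    species is on the regional checklist (species-level, that species);
#'  \item Level 3 — hits above the family threshold fall within a single
#'    family, or are only family-annotated (family-level);
#'  \item otherwise the query is left unknown.
#' }
#'
#' @param hits Hit list from [similaritySearch()].
#' @param speciesThreshold Similarity above which species/genus assignment
#'   is attempted (default 0.985).
#' @param familyThreshold Similarity above which family assignment is
#'   attempted (default 0.98).
#' @param tieWindow Hits within this similarity of the best hit are always
#'   considered (default 0.005).
#' @return A list of class `TaxonAssignment` with elements `assigned_rank`
#'   (`"species"`, `"genus"`, `"family"` or `"unknown"`), `assigned_name`,
#'   `confidence_level` (1, 2, 3 or `NA`), `best_similarity`, `lineage`
#'   (order/family/genus/species, `NA` below the assigned rank), and `hits`.
#' @export
assignConfidence <- function(hits, speciesThreshold = 0.985,
                             familyThreshold = 0.98, tieWindow = 0.005) {
  speciesThreshold <- .assertFraction(speciesThreshold, "speciesThreshold",
                                      lo.open = TRUE)
  familyThreshold <- .assertFraction(familyThreshold, "familyThreshold",
                                     lo.open = TRUE)
  stopifnot(speciesThreshold >= familyThreshold, nrow(hits) >= 1L)
  best <- max(hits$similarity)
  res <- list(assigned_rank = "unknown", assigned_name = NA_character_,
              confidence_level = NA_integer_, best_similarity = best,
              lineage = c(order = NA_character_, family = NA_character_,
                          genus = NA_character_, species = NA_character_),
              hits = hits)
  class(res) <- "TaxonAssignment"

  if (best > speciesThreshold) {
    set <- .matchSet(hits, speciesThreshold, tieWindow)
    set <- set[.isSpeciesAnnotated(set), , drop = FALSE]
    if (nrow(set) > 0L) {
      spp <- unique(set$species)
      if (length(spp) == 1L) {
        res$assigned_rank <- "species"
        res$assigned_name <- spp
        res$confidence_level <- 1L
        res$lineage <- c(order = set$order[1], family = set$family[1],
                         genus = set$genus[1], species = spp)
        return(res)
      }
      if (length(unique(set$genus)) == 1L) {
        res$assigned_rank <- "genus"
        res$assigned_name <- set$genus[1]
        res$confidence_level <- 1L
        res$lineage <- c(order = set$order[1], family = set$family[1],
                         genus = set$genus[1], species = NA_character_)
        return(res)
      }
      ukSpp <- unique(set$species[set$in_checklist])
      if (length(ukSpp) == 1L) {
        row <- set[set$species == ukSpp, , drop = FALSE][1, ]
        res$assigned_rank <- "species"
        res$assigned_name <- ukSpp
        res$confidence_level <- 2L
        res$lineage <- c(order = row$order, family = row$family,
                         genus = row$genus, species = ukSpp)
        return(res)
      }
      if (length(ukSpp) > 1L)
        message("checklist rule ambiguous: ", length(ukSpp),
                " checklist species among top hits; degrading assignment")
    }
  }

  # all hits above the family threshold fall in one family (whether several
  # genera or family-only records): family-level call
  famSet <- hits[hits$similarity > familyThreshold, , drop = FALSE]
  if (nrow(famSet) > 0L && length(unique(famSet$family)) == 1L) {
    res$assigned_rank <- "family"
    res$assigned_name <- famSet$family[1]
    res$confidence_level <- 3L
    res$lineage <- c(order = famSet$order[1], family = famSet$family[1],
                     genus = NA_character_, species = NA_character_)
    return(res)
  }
  res
}

#' Consensus assignment of a MOTU from its representative sequences
#'
#' Each representative (up to three) is assigned independently; when the
#' representatives disagree, the MOTU assignment degrades to the deepest
#' rank on which all agree (species > genus > family), with the weakest
#' (largest) confidence level among them. If any representative is unknown,
#' or no rank agrees, the MOTU is left unknown.
#'
#' @param sequences Character vector of representative sequences (1 to 3).
#' @param reference Reference library list.
#' @inheritParams assignConfidence
#' @return A `TaxonAssignment` list (see [assignConfidence()]).
#' @export
assignMotu <- function(sequences, reference, speciesThreshold = 0.985,
                       familyThreshold = 0.98, tieWindow = 0.005) {
  asn <- lapply(sequences, function(s) {
    assignConfidence(similaritySearch(s, reference), speciesThreshold,
                     familyThreshold, tieWindow)
  })
  if (length(asn) == 1L) return(asn[[1]])
  base <- asn[[1]]
  if (any(vapply(asn, function(a) a$assigned_rank == "unknown", logical(1)))) {
    base$assigned_rank <- "unknown"
    base$assigned_name <- NA_character_
    base$confidence_level <- NA_integer_
    base$lineage[] <- NA_character_
    base$best_similarity <- max(vapply(asn, `[[`, 0, "best_similarity"))
    return(base)
  }
  level <- max(vapply(asn, `[[`, 0L, "confidence_level"))
  lineages <- lapply(asn, `[[`, "lineage")
  agree <- function(rank) {
    v <- vapply(lineages, `[`, "", rank)
    !anyNA(v) && length(unique(v)) == 1L
  }
  base$best_similarity <- max(vapply(asn, `[[`, 0, "best_similarity"))
  for (rank in c("species", "genus", "family")) {
    if (agree(rank)) {
      base$assigned_rank <- rank
      base$assigned_name <- lineages[[1]][[rank]]
      base$confidence_level <- if (rank == "family") 3L else as.integer(level)
      keep <- c("order", "family", "genus", "species")
      cut <- match(rank, keep)
      base$lineage <- lineages[[1]]
      if (cut < 4L) base$lineage[seq(cut + 1L, 4L)] <- NA_character_
      return(base)
    }
  }
  base$assigned_rank <- "unknown"
  base$assigned_name <- NA_character_
  base$confidence_level <- NA_integer_
  base$lineage[] <- NA_character_
  base
}

#' Assign every MOTU of a representatives table
#'
#' @param reps Result of [motuRepresentatives()].
#' @param reference Reference library list.
#' @inheritParams assignConfidence
#' @return `data.frame` with one row per MOTU: `motu_id`, `assigned_rank`,
#'   `assigned_name`, `confidence_level`, `best_similarity`, `order`,
#'   `family`, `genus`, `species`.
#' @export
assignAllMotus <- function(reps, reference, speciesThreshold = 0.985,
                           familyThreshold = 0.98, tieWindow = 0.005) {
  out <- lapply(split(reps, reps$motu_id), function(r) {
    a <- assignMotu(r$sequence, reference, speciesThreshold,
                    familyThreshold, tieWindow)
    data.frame(motu_id = r$motu_id[1], assigned_rank = a$assigned_rank,
               assigned_name = a$assigned_name,
               confidence_level = a$confidence_level,
               best_similarity = a$best_similarity,
               order = a$lineage[["order"]], family = a$lineage[["family"]],
               genus = a$lineage[["genus"]], species = a$lineage[["species"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$motu_id), , drop = FALSE]
}

#' MOTU-based species-richness inflation
#'
#' The percentage by which MOTU counting overestimates species richness
#' when several MOTUs resolve to the same species:
#' \eqn{100 (n_{MOTU} - n_{species}) / n_{MOTU}}, rounded to the nearest
#' integer percent.
#'
#' @param nMotus Number of MOTUs (>= `nSpecies`).
#' @param nSpecies Number of distinct species they resolve to (>= 1).
#' @return Integer percentage.
#' @examples
#' richnessInflation(59, 52)  # 12
#' @export
richnessInflation <- function(nMotus, nSpecies) {
  nMotus <- .assertCount(nMotus, "nMotus")
  nSpecies <- .assertCount(nSpecies, "nSpecies")
  if (nSpecies > nMotus)
    stop("nSpecies cannot exceed nMotus")
  as.integer(.roundHalfUp(100 * (nMotus - nSpecies) / nMotus))
}
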