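.HABITAT_CLASSES <- c("generalist", "grassland_specialist",
                      "woodland_specialist", "unknown")

#' Read a prey habitat-association lookup table
#'
#' Habitat classes are compiled from field guides and treated as data: a
#' two-column TSV mapping species to one of `generalist`,
#' `grassland_specialist`, `woodland_specialist` or `unknown`.
#'
#' @param file TSV path with header columns `species` and `class`.
#' @return Named character vector mapping species to habitat class.
#' @export
readHabitatTable <- function(file) {
  ht <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("species", "class") %in% names(ht)))
    stop("habitat table must have columns 'species' and 'class'")
  bad <- setdiff(unique(ht$class), .HABITAT_CLASSES)
  if (length(bad))
    stop("unknown habitat classes: ", paste(bad, collapse = ", "))
  setNames(ht$class, ht$species)
}

#' Cross-classify prey taxa by habitat association and predator
#'
#' Counts, for every (habitat class, predator) cell, the distinct prey taxa
#' of that class consumed by that predator; a taxon consumed by both
#' predators increments both columns. With `specialistsOnly = TRUE`
#' (default) generalists and unknowns are excluded, leaving the
#' grassland/woodland specialist contrast.
#'
#' @param um A [UtilizationMatrix-class]; resources are matched to the
#'   habitat table by the `species` column of their annotation when
#'   present, otherwise by resource name.
#' @param habitat Named character vector from [readHabitatTable()] (species
#'   to class).
#' @param specialistsOnly Drop generalist and unknown taxa before testing.
#' @return Integer matrix (habitat classes x predators).
#' @export
classifyDiet <- function(um, habitat, specialistsOnly = TRUE) {
  stopifnot(all(habitat %in% .HABITAT_CLASSES))
  info <- resourceInfo(um)
  key <- if ("species" %in% names(info)) info$species else resourceNames(um)
  cls <- unname(habitat[key])
  cls[is.na(cls)] <- "unknown"
  keep <- if (specialistsOnly)
    cls %in% c("grassland_specialist", "woodland_specialist")
  else rep(TRUE, length(cls))
  counts <- occurrenceCounts(um)
  classes <- intersect(.HABITAT_CLASSES, unique(cls[keep]))
  if (length(classes) == 0L)
    stop("no taxa left after habitat filtering")
  out <- vapply(colnames(counts), function(p) {
    vapply(classes, function(cl) {
      sum(keep & cls == cl & counts[, p] > 0)
    }, integer(1))
  }, integer(length(classes)))
  out <- matrix(out, nrow = length(classes),
                dimnames = list(classes, colnames(counts)))
  out
}

#' Pearson chi-square test of independence
#'
#' Tests whether predator identity and prey habitat class are independent:
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with \eqn{(r-1)(c-1)} degrees of
#' freedom. The default is Pearson's statistic without continuity
#' correction; set `yates = TRUE` for the Yates-corrected 2x2 variant.
#'
#' @param table Integer contingency matrix, at least 2x2, with positive row
#'   and column totals.
#' @param yates Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p.value` and `expected`.
#' @examples
#' chiSquareIndependence(matrix(c(10, 0, 0, 10), 2))$statistic  # 20
#' @export
chiSquareIndependence <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  if (any(res$expected <= 0))
    stop("all expected counts must be positive")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}
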