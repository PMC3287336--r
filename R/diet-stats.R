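#' Build a utilization matrix from per-sample resource presence
#'
#' Entry (i, j) of the result counts the fecal samples of predator j in
#' which resource i was detected. Every sample must belong to exactly one
#' predator. Resources never observed do not appear (no all-zero rows).
#'
#' @param presence `data.frame` with columns `sample`, `predator`,
#'   `resource`; one row per (sample, resource) detection (duplicates are
#'   collapsed).
#' @param resourceInfo Optional `data.frame` of per-resource annotation
#'   (rownames or a `resource` column matching the resource labels;
#'   `order`/`family` columns feed the order- and family-level summaries).
#' @return A [UtilizationMatrix-class].
#' @examples
#' presence <- data.frame(
#'   sample = c("f1", "f1", "f2", "f3"),
#'   predator = c("P1", "P1", "P1", "P2"),
#'   resource = c("R1", "R2", "R1", "R2"))
#' occurrenceCounts(buildUtilizationMatrix(presence))
#' @export
buildUtilizationMatrix <- function(presence, resourceInfo = NULL) {
  stopifnot(all(c("sample", "predator", "resource") %in% names(presence)))
  if (nrow(presence) == 0L)
    return(UtilizationMatrix(matrix(0L, 0, 0,
                                    dimnames = list(character(0), character(0)))))
  sp <- unique(presence[, c("sample", "predator")])
  if (anyDuplicated(sp$sample))
    stop("every sample must belong to exactly one predator")
  presence <- unique(presence[, c("sample", "predator", "resource")])
  counts <- table(resource = presence$resource, predator = presence$predator)
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  if (!is.null(resourceInfo)) {
    key <- if ("resource" %in% names(resourceInfo))
      resourceInfo$resource else rownames(resourceInfo)
    resourceInfo <- resourceInfo[match(rownames(m), key), , drop = FALSE]
  }
  UtilizationMatrix(m, resourceInfo)
}

#' Percent frequency of occurrence by prey order
#'
#' For one predator, the number of fecal samples containing each prey order
#' divided by the total occurrences of all orders, as a percentage. Values
#' sum to 100 up to rounding.
#'
#' @param sampleOrders `data.frame` with columns `sample`, `predator`,
#'   `order`; one row per (sample, order) detection.
#' @param predator Predator label to summarize.
#' @return Named numeric vector of percentages, one per order.
#' @examples
#' so <- data.frame(sample = c("f1", "f1", "f2", "f3"),
#'                  predator = "P1",
#'                  order = c("Lepidoptera", "Diptera", "Lepidoptera",
#'                            "Lepidoptera"))
#' percentFoByOrder(so, "P1")  # Lepidoptera 75, Diptera 25
#' @export
percentFoByOrder <- function(sampleOrders, predator) {
  stopifnot(all(c("sample", "predator", "order") %in% names(sampleOrders)))
  x <- unique(sampleOrders[sampleOrders$predator == predator,
                           c("sample", "order")])
  if (nrow(x) == 0L)
    stop("predator '", predator, "' has no order occurrences")
  occ <- table(x$order)
  setNames(100 * as.numeric(occ) / sum(occ), names(occ))
}

#' Levins' niche breadth, standardized
#'
#' \eqn{B = 1 / \sum_i p_i^2} with \eqn{p_i} the proportion resource i is
#' of the predator's total occurrences, and the standardized form
#' \eqn{B_A = (B - 1)/(n - 1)} in `[0, 1]` where n is the number of
#' resource states. Occurrence counts are normalized to proportions summing
#' to 1; the raw occurrence fractions (count / total occurrences) are the
#' same quantities, so no information is lost. By default n is the number
#' of resources observed in this predator's diet; pass `nResources` to
#' standardize against a wider resource pool.
#'
#' @param counts Non-negative occurrence counts for one predator (at least
#'   one positive).
#' @param nResources Number of possible resource states (defaults to the
#'   number of positive counts; must be at least that).
#' @return List with `B`, `BA` and `nResources`.
#' @examples
#' levinsBreadth(c(2, 1, 1))  # B = 8/3, BA = 5/6
#' @export
levinsBreadth <- function(counts, nResources = NULL) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), any(counts > 0))
  nUsed <- sum(counts > 0)
  n <- if (is.null(nResources)) nUsed else .assertCount(nResources, "nResources")
  if (n < nUsed) stop("nResources must be at least the number of used resources")
  p <- counts[counts > 0] / sum(counts)
  B <- 1 / sum(p^2)
  BA <- if (n == 1L) 0 else (B - 1) / (n - 1)
  list(B = B, BA = BA, nResources = n)
}

#' Shannon diversity of resource use
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the positive resource-use
#' proportions.
#'
#' @param counts Non-negative occurrence counts (at least one positive).
#' @return Non-negative real, at most `ln(number of used resources)`.
#' @examples
#' shannonDiversity(c(1, 1, 1, 1))  # log(4)
#' @export
shannonDiversity <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), any(counts > 0))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Pianka's niche overlap
#'
#' \deqn{O_{jk} = \frac{\sum_i P_{ij} P_{ik}}
#'   {\sqrt{\sum_i P_{ij}^2 \sum_i P_{ik}^2}}}
#' where \eqn{P_{ij}} is the proportion resource i is of the total
#' resources used by species j. Symmetric, in `[0, 1]`, and invariant to
#' rescaling either count vector (so raw occurrence counts can be passed
#' directly).
#'
#' Called on a [UtilizationMatrix-class], computes the overlap between two
#' of its predator columns (by default the first two).
#'
#' @param x Either a numeric count vector for predator j, or a
#'   [UtilizationMatrix-class].
#' @param y Numeric count vector for predator k (when `x` is a vector).
#' @param predators When `x` is a [UtilizationMatrix-class]: two predator
#'   labels (default the first two columns).
#' @return Overlap in `[0, 1]`.
#' @examples
#' piankaOverlap(c(2, 1, 1, 0), c(1, 1, 0, 2))  # 0.5
#' @export
piankaOverlap <- function(x, y = NULL, predators = NULL) {
  if (methods::is(x, "UtilizationMatrix")) {
    m <- occurrenceCounts(x)
    predators <- predators %||% colnames(m)[1:2]
    stopifnot(length(predators) == 2L, all(predators %in% colnames(m)))
    return(piankaOverlap(m[, predators[1]], m[, predators[2]]))
  }
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 || sum(y) == 0)
    stop("both predators must use at least one resource")
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Share of an order's occurrences contributed by one family
#'
#' For the given predator, 100 times the occurrence counts summed over the
#' family's resources divided by the sum over the whole order's resources.
#' Requires `order` and `family` columns in the matrix's resource
#' annotation.
#'
#' @param um A [UtilizationMatrix-class] with order/family annotation.
#' @param predator Predator label.
#' @param order Prey order label.
#' @param family Prey family label within that order.
#' @return Percentage (unrounded).
#' @export
familyShare <- function(um, predator, order, family) {
  info <- resourceInfo(um)
  stopifnot(all(c("order", "family") %in% names(info)),
            predator %in% predatorNames(um))
  counts <- occurrenceCounts(um)[, predator]
  inOrder <- info$order == order
  tot <- sum(counts[inOrder])
  if (tot == 0) stop("order '", order, "' absent from this predator's diet")
  100 * sum(counts[inOrder & info$family == family]) / tot
}

#' Distinct prey orders per predator
#'
#' @param um A [UtilizationMatrix-class] with an `order` column in its
#'   resource annotation.
#' @return Named integer vector: number of distinct prey orders with at
#'   least one occurrence, per predator.
#' @export
ordersPerPredator <- function(um) {
  info <- resourceInfo(um)
  stopifnot("order" %in% names(info))
  counts <- occurrenceCounts(um)
  vapply(colnames(counts), function(p) {
    length(unique(info$order[counts[, p] > 0]))
  }, integer(1))
}

#' Per-sample prey-richness summary
#'
#' Number of distinct resources (MOTUs) per fecal sample, with mean,
#' standard deviation, minimum and maximum. The default SD uses the sample
#' (n - 1) convention of "mean +/- SD" reporting; `convention =
#' "population"` divides by n (a single sample then has SD 0).
#'
#' @param presence `data.frame` with columns `sample` and `resource`.
#' @param convention `"sample"` or `"population"`.
#' @return List with `perSample` (named integer vector), `mean`, `sd`,
#'   `min`, `max`.
#' @export
sampleSummary <- function(presence, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  stopifnot(all(c("sample", "resource") %in% names(presence)),
            nrow(presence) > 0)
  x <- unique(presence[, c("sample", "resource")])
  cnt <- table(x$sample)
  v <- as.integer(cnt)
  s <- if (length(v) == 1L) {
    if (convention == "population") 0 else NA_real_
  } else if (convention == "population") {
    sqrt(mean((v - mean(v))^2))
  } else {
    sd(v)
  }
  list(perSample = setNames(v, names(cnt)), mean = mean(v), sd = s,
       min = min(v), max = max(v))
}

#' Niche descriptors for every predator of a utilization matrix
#'
#' @param um A [UtilizationMatrix-class].
#' @param nResources Optional global resource-pool size for the
#'   standardized Levins measure (default: per-predator observed richness).
#' @return `data.frame` with one row per predator: `predator`,
#'   `n_resources`, `levins_B`, `levins_BA`, `shannon_H`.
#' @export
nicheDescriptors <- function(um, nResources = NULL) {
  counts <- occurrenceCounts(um)
  rows <- lapply(colnames(counts), function(p) {
    lv <- levinsBreadth(counts[, p], nResources)
    data.frame(predator = p, n_resources = lv$nResources,
               levins_B = lv$B, levins_BA = lv$BA,
               shannon_H = shannonDiversity(counts[, p]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a utilization matrix as TSV
#'
#' Columns: `resource`, the annotation columns, then one count column per
#' predator — the same layout as the packaged worked-example table.
#'
#' @param um A [UtilizationMatrix-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeUtilizationMatrix <- function(um, file) {
  df <- cbind(data.frame(resource = resourceNames(um)), resourceInfo(um),
              as.data.frame(occurrenceCounts(um), check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
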