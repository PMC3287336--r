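.TABLE1_MD5 <- "a5383981a7973a1c06cf02064ce606e6"

#' Load the packaged worked-example prey-count matrix
#'
#' The package ships the published per-taxon consumer-count table for two
#' cryptic long-eared bat predators: 79 arthropod prey taxa (order, family,
#' species, identification confidence level) with, for each, the number of
#' individual bats of each species whose feces contained it (28 *Plecotus
#' austriacus* and 24 *P. auritus* individuals). It is the worked-example
#' input for the niche-overlap statistics and null models.
#'
#' The fixture file is checksum-verified at load time and never modified.
#'
#' @return A [UtilizationMatrix-class] with predators `"P. austriacus"` and
#'   `"P. auritus"` and resource annotation columns `order`, `family`,
#'   `species`, `confidence_level`.
#' @examples
#' um <- loadTable1Fixture()
#' occurrenceCounts(um)["Lepidoptera|Noctuidae|Noctua pronuba", ]
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_prey_counts.tsv",
                      package = "motuDiet", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .TABLE1_MD5))
    stop("worked-example fixture checksum mismatch: expected ", .TABLE1_MD5,
         ", found ", md5)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, c("P. austriacus", "P. auritus")])
  rownames(counts) <- paste(df$order, df$family, df$species, sep = "|")
  info <- df[, c("order", "family", "species", "confidence_level")]
  rownames(info) <- rownames(counts)
  UtilizationMatrix(counts, info)
}
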