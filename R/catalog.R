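#' Load the marker-reaction and primer catalog
#'
#' Loads the built-in catalog of 22 protein-metabolism marker reactions
#' (12 numerator, 10 denominator) and the qPCR primer catalog (4 primer pairs
#' for each of the 4 qPCR marker reactions plus the universal 16S pair).
#' An override TSV may replace or add marker rows, keyed by \code{ec_number};
#' this is intended for sensitivity analyses (e.g. alternative stoichiometric
#' weights), not for routine use.
#'
#' The marker TSV schema is
#' \code{ec_number  kegg_ids(comma-sep)  role  stoich_weight  qpcr_marker(0/1)}
#' with optional trailing \code{representative_genes} and
#' \code{representative_enzymes} columns; the primer TSV schema is
#' \code{ec_number  pair_id  forward  reverse}.
#'
#' @param markerOverride optional path to a marker TSV whose rows replace
#'   built-in entries with the same \code{ec_number} (new EC numbers are
#'   appended)
#' @param primerOverride optional path to a primer TSV that fully replaces the
#'   built-in primer table
#' @return a validated \linkS4class{MarkerCatalog}
#' @examples
#' cat22 <- loadCatalog()
#' numeratorSet(cat22)
#' @export
loadCatalog <- function(markerOverride = NULL, primerOverride = NULL) {
  mk <- .readMarkerTsv(system.file("extdata", "marker_reactions.tsv",
                                   package = "mpmindex", mustWork = TRUE))
  if (!is.null(markerOverride)) {
    ov <- .readMarkerTsv(markerOverride)
    hit <- match(ov$ec_number, mk$ec_number)
    replace <- !is.na(hit)
    if (any(replace))
      mk[hit[replace], colnames(ov)] <- ov[replace, ]
    if (any(!replace))
      mk <- rbind(mk, ov[!replace, ])
  }
  prPath <- if (is.null(primerOverride)) {
    system.file("extdata", "primer_pairs.tsv", package = "mpmindex",
                mustWork = TRUE)
  } else primerOverride
  pr <- utils::read.delim(prPath, stringsAsFactors = FALSE,
                          colClasses = "character")
  mk$suspect_kegg <- vapply(strsplit(mk$kegg_ids, ","), function(k)
    any(!grepl("^K[0-9]{5}$", trimws(k))), logical(1))
  new("MarkerCatalog", markers = DataFrame(mk), primers = DataFrame(pr))
}

.readMarkerTsv <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ec_number", "kegg_ids", "role", "stoich_weight", "qpcr_marker")
  miss <- setdiff(need, colnames(mk))
  if (length(miss))
    stop("marker TSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!grepl(.EC_PATTERN, mk$ec_number))
  if (length(bad))
    stop("malformed EC number '", mk$ec_number[bad[1]], "' at marker TSV row ",
         bad[1])
  bad <- which(!mk$role %in% c("N", "D"))
  if (length(bad))
    stop("unknown role token '", mk$role[bad[1]], "' at marker TSV row ",
         bad[1], " (expected N or D)")
  dup <- which(duplicated(mk$ec_number))
  if (length(dup))
    stop("duplicate ec_number '", mk$ec_number[dup[1]], "' at marker TSV row ",
         dup[1])
  mk$stoich_weight <- as.numeric(mk$stoich_weight)
  mk$qpcr_marker <- as.integer(mk$qpcr_marker) == 1L
  if (!"representative_genes" %in% colnames(mk)) mk$representative_genes <- ""
  if (!"representative_enzymes" %in% colnames(mk)) mk$representative_enzymes <- ""
  mk
}

#' Write a catalog back to its TSV serialization
#'
#' Inverse of [loadCatalog()]; the marker and primer tables round-trip
#' bit-identically through this writer.
#'
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param markerPath,primerPath output TSV paths (either may be NULL to skip)
#' @return invisibly, the catalog
#' @export
writeCatalog <- function(catalog, markerPath = NULL, primerPath = NULL) {
  if (!is.null(markerPath)) {
    mk <- as.data.frame(catalog@markers)
    mk$suspect_kegg <- NULL
    mk$qpcr_marker <- as.integer(mk$qpcr_marker)
    mk$stoich_weight <- sprintf("%.1f", mk$stoich_weight)
    utils::write.table(mk, markerPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(primerPath))
    utils::write.table(as.data.frame(catalog@primers), primerPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(catalog)
}

#' Catalog accessors
#'
#' \code{markerTable()} returns the marker-reaction table;
#' \code{numeratorSet()} / \code{denominatorSet()} return the EC numbers whose
#' normalized abundances enter the MPMI numerator ("favorable" protein
#' assimilation reactions) and denominator ("unfavorable" putrefaction
#' reactions). The two sets are disjoint and together cover the catalog.
#' \code{qpcrMarkers()} returns the roles of the qPCR marker reactions as a
#' named character vector; \code{koToEcMap()} expands the catalog's KO
#' memberships into a KO -> EC set mapping usable by [regroupKoToEc()].
#'
#' @param catalog a \linkS4class{MarkerCatalog}
#' @return see individual descriptions
#' @examples
#' cat22 <- loadCatalog()
#' qpcrMarkers(cat22)
#' @export
markerTable <- function(catalog) catalog@markers

#' @rdname markerTable
#' @export
numeratorSet <- function(catalog)
  catalog@markers$ec_number[catalog@markers$role == "N"]

#' @rdname markerTable
#' @export
denominatorSet <- function(catalog)
  catalog@markers$ec_number[catalog@markers$role == "D"]

#' @rdname markerTable
#' @export
qpcrMarkers <- function(catalog) {
  mk <- catalog@markers[catalog@markers$qpcr_marker, ]
  stats::setNames(as.character(mk$role), mk$ec_number)
}

#' @rdname markerTable
#' @export
koToEcMap <- function(catalog) {
  mk <- catalog@markers
  kos <- strsplit(mk$kegg_ids, ",")
  map <- list()
  for (i in seq_len(nrow(mk))) {
    for (ko in trimws(kos[[i]]))
      map[[ko]] <- c(map[[ko]], mk$ec_number[i])
  }
  map
}

#' Primer pairs for a marker reaction
#'
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param marker an EC number carrying the qPCR-marker flag, or \code{"16S"}
#'   for the universal pair; NULL returns the full primer table
#' @return a data.frame with columns \code{ec_number}, \code{pair_id},
#'   \code{forward}, \code{reverse}
#' @export
primerPairs <- function(catalog, marker = NULL) {
  pr <- as.data.frame(catalog@primers)
  if (is.null(marker)) return(pr)
  pr[pr$ec_number == marker, , drop = FALSE]
}

#' Sanity-check a primer pair
#'
#' Report-only guard for user-supplied primer overrides: checks that both
#' sequences are non-empty, uppercase, and drawn from the accepted IUPAC
#' alphabet (A/C/G/T plus the two-fold degeneracies S/Y/R/M). Does not
#' attempt melting-temperature prediction.
#'
#' @param forward,reverse primer sequences (5'->3')
#' @return a list with elements \code{valid} (logical), \code{lengths}
#'   (integer 2-vector), \code{issues} (character vector, empty when valid)
#' @examples
#' validatePrimer("CGGTGCTGGAGAAAGAAGGT", "CAGTTGTGCGGCGGTTAAAA")
#' @export
validatePrimer <- function(forward, reverse) {
  issues <- character()
  for (side in c("forward", "reverse")) {
    s <- get(side)
    if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
      issues <- c(issues, paste("empty", side, "sequence"))
    } else if (s != toupper(s)) {
      issues <- c(issues, paste(side, "sequence is not uppercase"))
    } else if (!grepl(.PRIMER_ALPHABET, s)) {
      badChars <- setdiff(strsplit(s, "")[[1]], c("A","C","G","T","S","Y","R","M"))
      issues <- c(issues, paste0(side, " sequence has non-DNA character(s): ",
                                 paste(unique(badChars), collapse = ", ")))
    }
  }
  list(valid = length(issues) == 0L,
       lengths = c(forward = nchar(forward), reverse = nchar(reverse)),
       issues = issues)
}

#' Default glycolysis/TCA-cycle normalization set
#'
#' The internal normalization of functional profiles divides each sample by
#' the summed gene abundance of a housekeeping reference: the glycolysis/TCA
#' cycle module. This returns the EC numbers (and one representative KO per
#' step) the package ships as that reference set; the set is configurable
#' everywhere it is consumed.
#'
#' @return data.frame with columns \code{ec_number}, \code{kegg_ids},
#'   \code{step}
#' @export
glycolysisTcaSet <- function() {
  utils::read.delim(system.file("extdata", "glycolysis_tca_ecs.tsv",
                                package = "mpmindex", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
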