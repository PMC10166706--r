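#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"
# IUPAC subset the primer catalog uses: the four bases plus the two-fold
# degeneracies S/Y/R/M carried by the universal 16S pair
.PRIMER_ALPHABET <- "^[ACGTSYRM]+$"

#' MarkerCatalog: the marker-reaction and primer catalog
#'
#' Holds the protein-metabolism marker reactions (EC numbers with their
#' numerator/denominator role in the MPMI, KEGG Orthology memberships and an
#' optional qPCR-marker flag) and the qPCR primer pairs attached to the four
#' qPCR marker reactions plus the universal 16S pair (reserved marker id
#' \code{"16S"}).
#'
#' @slot markers \code{DataFrame} with columns \code{ec_number},
#'   \code{kegg_ids} (comma-separated KO ids), \code{role} (\code{"N"} or
#'   \code{"D"}), \code{stoich_weight}, \code{qpcr_marker} (logical),
#'   \code{representative_genes}, \code{representative_enzymes},
#'   \code{suspect_kegg} (logical; TRUE when a KO id does not match the
#'   \code{K} + 5 digits pattern and is stored verbatim).
#' @slot primers \code{DataFrame} with columns \code{ec_number},
#'   \code{pair_id}, \code{forward}, \code{reverse}.
#'
#' @seealso [loadCatalog()], [numeratorSet()], [primerPairs()]
#' @exportClass MarkerCatalog
setClass("MarkerCatalog",
         representation(markers = "DataFrame", primers = "DataFrame"))

setValidity("MarkerCatalog", function(object) {
  mk <- object@markers
  pr <- object@primers
  msgs <- character()
  need <- c("ec_number", "kegg_ids", "role", "stoich_weight", "qpcr_marker")
  if (!all(need %in% colnames(mk)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  bad <- which(!grepl(.EC_PATTERN, mk$ec_number))
  if (length(bad))
    msgs <- c(msgs, sprintf("malformed EC number '%s' (marker row %d)",
                            mk$ec_number[bad[1]], bad[1]))
  bad <- which(!mk$role %in% c("N", "D"))
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown role token '%s' (marker row %d)",
                            as.character(mk$role[bad[1]]), bad[1]))
  dup <- which(duplicated(mk$ec_number))
  if (length(dup))
    msgs <- c(msgs, sprintf("duplicate ec_number '%s' (marker row %d)",
                            mk$ec_number[dup[1]], dup[1]))
  bad <- which(!(mk$stoich_weight > 0))
  if (length(bad))
    msgs <- c(msgs, sprintf("stoich_weight must be > 0 (marker row %d)", bad[1]))
  if (nrow(pr)) {
    known <- c(mk$ec_number, "16S")
    bad <- which(!pr$ec_number %in% known)
    if (length(bad))
      msgs <- c(msgs, sprintf("primer row %d references unknown marker '%s'",
                              bad[1], pr$ec_number[bad[1]]))
    bad <- which(!grepl(.PRIMER_ALPHABET, pr$forward) |
                 !grepl(.PRIMER_ALPHABET, pr$reverse))
    if (length(bad))
      msgs <- c(msgs, sprintf("primer row %d has a non-IUPAC sequence", bad[1]))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn MarkerCatalog compact summary of catalog contents
#' @param object a \code{MarkerCatalog}
#' @export
setMethod("show", "MarkerCatalog", function(object) {
  mk <- object@markers
  cat("MarkerCatalog with", nrow(mk), "marker reactions (",
      sum(mk$role == "N"), "N /", sum(mk$role == "D"), "D ),",
      sum(mk$qpcr_marker), "qPCR markers,",
      nrow(object@primers), "primer pairs\n")
  invisible(NULL)
})

#' ECAbundanceMatrix: normalized EC-number functional profiles
#'
#' A \linkS4class{SummarizedExperiment} with EC numbers as rows and samples
#' as columns. The \code{"abundance"} assay holds per-sample internally
#' normalized abundances (each sample divided by the summed pre-normalization
#' counts of a reference EC set, by default the glycolysis/TCA-cycle module).
#' \code{colData()$norm_denominator} records that per-sample denominator;
#' \code{rowData()$pathways} carries up to five KEGG pathway ids per EC as a
#' comma-separated string once [annotatePathways()] has run.
#'
#' @seealso [normalizeAbundance()], [computeMpmi()]
#' @exportClass ECAbundanceMatrix
setClass("ECAbundanceMatrix", contains = "SummarizedExperiment")

setValidity("ECAbundanceMatrix", function(object) {
  if (!"abundance" %in% names(assays(object)))
    return("assay 'abundance' is required")
  a <- assay(object, "abundance")
  if (any(!is.finite(a)))
    return("abundance values must be finite")
  if (any(a < 0))
    return("abundance values must be >= 0")
  if (!"norm_denominator" %in% colnames(colData(object)))
    return("colData column 'norm_denominator' is required")
  d <- colData(object)$norm_denominator
  if (any(!is.finite(d)) || any(d <= 0))
    return("normalization denominators must be finite and > 0")
  TRUE
})

#' @describeIn ECAbundanceMatrix summary with normalization info
#' @param object an \code{ECAbundanceMatrix}
#' @export
setMethod("show", "ECAbundanceMatrix", function(object) {
  cat("ECAbundanceMatrix:", nrow(object), "EC numbers x", ncol(object),
      "samples\n")
  d <- colData(object)$norm_denominator
  cat("  normalization denominators: median", signif(stats::median(d), 4),
      " range [", signif(min(d), 4), ",", signif(max(d), 4), "]\n")
  if ("pathways" %in% colnames(rowData(object))) {
    ann <- sum(nzchar(rowData(object)$pathways))
    cat("  pathway annotation:", ann, "of", nrow(object), "ECs annotated\n")
  }
  invisible(NULL)
})

#' CalibrationFit: per-primer-set qPCR calibration
#'
#' Log-linear calibration of cycle threshold against template amount,
#' \eqn{Ct = m \log_{10}(D) + b + s(S)}, fitted by least squares on a serial
#' dilution series with additive per-source intercept offsets (first source is
#' the reference level). The slope is shared across sources.
#'
#' @slot key marker EC number or \code{"16S"}
#' @slot slope fitted slope \eqn{m} (expected negative; near -3.32 at 100\%
#'   amplification efficiency)
#' @slot intercept fitted reference-source intercept \eqn{b}
#' @slot sourceOffsets named numeric of per-source additive offsets (reference
#'   source = 0)
#' @slot rSquared coefficient of determination of the fit
#' @slot nLevels number of distinct dilution levels used
#'
#' @seealso [fitCalibration()], [relativeAbundance()]
#' @exportClass CalibrationFit
setClass("CalibrationFit",
         representation(key = "character", slope = "numeric",
                        intercept = "numeric", sourceOffsets = "numeric",
                        rSquared = "numeric", nLevels = "integer"))

setValidity("CalibrationFit", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope))
    return("slope must be a single finite number")
  if (object@slope == 0)
    return("slope must be nonzero")
  if (!is.finite(object@rSquared))
    return("rSquared must be finite")
  TRUE
})

#' @describeIn CalibrationFit one-line fit summary
#' @param object a \code{CalibrationFit}
#' @export
setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit[%s]: Ct = %.4f log10(D) + %.4f  (R2 = %.4f, %d dilution levels, %d source(s))\n",
              object@key, object@slope, object@intercept, object@rSquared,
              object@nLevels, length(object@sourceOffsets)))
  invisible(NULL)
})

#' @rdname CalibrationFit-accessors
#' @param fit a \code{CalibrationFit}
#' @return \code{calibrationSlope()}: the fitted slope;
#'   \code{calibrationIntercept()}: the reference intercept;
#'   \code{calibrationR2()}: the fit's R-squared.
#' @export
calibrationSlope <- function(fit) fit@slope

#' @rdname CalibrationFit-accessors
#' @export
calibrationIntercept <- function(fit) fit@intercept

#' @rdname CalibrationFit-accessors
#' @export
calibrationR2 <- function(fit) fit@rSquared
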