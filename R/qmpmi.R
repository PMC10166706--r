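#' Fit a qPCR calibration curve for one primer set
#'
#' Least-squares fit of the log-linear model
#' \eqn{Ct = m \log_{10}(D) + b + s(S)} on a serial dilution series, where D
#' is the dilution factor and S labels the source of the template DNA (model
#' \code{lm(ct ~ log10(dilution) + factor(source))}). The slope is shared
#' across sources; per-source additive intercept offsets absorb source DNA
#' bias (first source = reference, offset 0).
#'
#' @param series data.frame with columns \code{source}, \code{dilution}
#'   (positive), \code{ct}
#' @param key marker EC number or \code{"16S"}, stored on the fit
#' @return a \linkS4class{CalibrationFit}
#' @examples
#' s <- data.frame(source = "A", dilution = 10^-(0:4),
#'                 ct = -3.32 * -(0:4) + 25)
#' fitCalibration(s, "2.3.1.109")
#' @export
fitCalibration <- function(series, key) {
  stopifnot(all(c("source", "dilution", "ct") %in% colnames(series)))
  if (any(series$dilution <= 0)) stop("dilution factors must be positive")
  nLevels <- length(unique(series$dilution))
  if (nLevels < 3L)
    stop("need at least 3 distinct dilution levels, got ", nLevels)
  series$source <- factor(series$source)
  df <- data.frame(ct = series$ct, logD = log10(series$dilution),
                   source = series$source)
  fit <- if (nlevels(series$source) > 1L) stats::lm(ct ~ logD + source, df)
         else stats::lm(ct ~ logD, df)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("collinear calibration design; fit is rank-deficient")
  offsets <- stats::setNames(0, levels(series$source)[1])
  if (nlevels(series$source) > 1L) {
    extra <- cf[grep("^source", names(cf))]
    names(extra) <- sub("^source", "", names(extra))
    offsets <- c(offsets, extra)
  }
  # summary.lm warns on exact (zero-residual) fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # zero residual AND zero total variance cannot occur past the level check
  new("CalibrationFit", key = key, slope = unname(cf[["logD"]]),
      intercept = unname(cf[["(Intercept)"]]), sourceOffsets = offsets,
      rSquared = r2, nLevels = as.integer(nLevels))
}

#' Relative abundance of a marker from paired Ct values
#'
#' Converts a marker-reaction Ct and the matching universal-16S Ct of the
#' same template into the marker's 16S-normalized relative abundance,
#' \eqn{A = 10^{(Ct_m/m_m - Ct_{16S}/m_{16S})}}: the ratio of template coding
#' for the marker reaction to total bacterial 16S rDNA. Uniform template
#' dilution shifts both terms equally, so A is dilution-invariant.
#'
#' @param ctMarker,ct16s cycle-threshold values
#' @param fitMarker,fit16s \linkS4class{CalibrationFit}s for the marker
#'   primer set and the universal 16S pair
#' @return the relative abundance (positive scalar)
#' @export
relativeAbundance <- function(ctMarker, fitMarker, ct16s, fit16s) {
  if (calibrationSlope(fitMarker) == 0 || calibrationSlope(fit16s) == 0)
    stop("calibration slope must be nonzero")
  10^(ctMarker / calibrationSlope(fitMarker) -
        ct16s / calibrationSlope(fit16s))
}

#' Per-replicate relative abundances from a qPCR plate
#'
#' Joins each marker well with the universal-16S well of the same sample and
#' replicate and applies [relativeAbundance()]. Wells sharing a (sample,
#' marker, replicate) key (e.g. the individual pairs of a blended set run
#' separately) are first averaged on the Ct scale.
#'
#' Non-detects (no amplification within \code{maxCycles} cycles) follow
#' \code{policy}: \code{"floor"} (default) assigns the abundance implied by
#' \code{ct = maxCycles}, keeping the index finite and ordered; \code{"censor"}
#' drops the replicate and flags it; \code{"zero"} sets A = 0. A sample whose
#' 16S well is undetected gets NA and a flag under every policy.
#'
#' @param plate data.frame with columns \code{sample}, \code{marker},
#'   \code{replicate}, \code{ct}, \code{detected} (logical; \code{ct} is
#'   ignored where \code{detected} is FALSE)
#' @param fits named list of \linkS4class{CalibrationFit}s, keyed by marker
#'   EC number, including a \code{"16S"} entry
#' @param policy non-detect policy (see above)
#' @param maxCycles qPCR cycle ceiling (default 40)
#' @return data.frame with \code{sample}, \code{marker}, \code{replicate},
#'   \code{a_value}, \code{detected}
#' @export
relativeAbundanceTable <- function(plate, fits,
                                   policy = c("floor", "censor", "zero"),
                                   maxCycles = 40) {
  policy <- match.arg(policy)
  stopifnot(all(c("sample", "marker", "replicate", "ct", "detected") %in%
                  colnames(plate)))
  if (!"16S" %in% names(fits)) stop("fits must include a '16S' entry")
  agg <- stats::aggregate(cbind(ct = ifelse(plate$detected, plate$ct, NA)) ~
                            sample + marker + replicate, plate, function(v)
                              if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  s16 <- agg[agg$marker == "16S", ]
  mk <- agg[agg$marker != "16S", ]
  key16 <- paste(s16$sample, s16$replicate)
  ct16 <- stats::setNames(s16$ct, key16)
  rows <- lapply(seq_len(nrow(mk)), function(i) {
    marker <- mk$marker[i]
    fit <- fits[[marker]]
    if (is.null(fit)) stop("no calibration fit for marker '", marker, "'")
    c16 <- ct16[[paste(mk$sample[i], mk$replicate[i])]]
    ctm <- mk$ct[i]
    detected <- !is.na(ctm)
    if (is.null(c16) || is.na(c16)) {       # 16S failure: unusable well
      a <- NA_real_
    } else if (detected) {
      a <- relativeAbundance(ctm, fit, c16, fits[["16S"]])
    } else {
      a <- switch(policy,
                  floor = relativeAbundance(maxCycles, fit, c16, fits[["16S"]]),
                  censor = NA_real_,
                  zero = 0)
    }
    data.frame(sample = mk$sample[i], marker = marker,
               replicate = mk$replicate[i], a_value = a, detected = detected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average relative abundances across PCR replicates
#'
#' Arithmetic mean of per-replicate A values for each (sample, marker);
#' averaging happens on the abundance scale, not the Ct scale. Censored
#' (NA) replicates are dropped from the mean and flagged via
#' \code{all_detected}.
#'
#' @param aTable data.frame from [relativeAbundanceTable()]
#' @return data.frame with \code{sample}, \code{marker}, \code{a_value},
#'   \code{n_replicates}, \code{all_detected}
#' @export
averageReplicates <- function(aTable) {
  stopifnot(all(c("sample", "marker", "a_value") %in% colnames(aTable)))
  if (!"detected" %in% colnames(aTable)) aTable$detected <- TRUE
  keys <- unique(aTable[, c("sample", "marker")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- aTable$sample == keys$sample[i] & aTable$marker == keys$marker[i]
    a <- aTable$a_value[sel]
    data.frame(sample = keys$sample[i], marker = keys$marker[i],
               a_value = if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE),
               n_replicates = sum(!is.na(a)),
               all_detected = all(aTable$detected[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantitative MPMI from marker relative abundances
#'
#' The targeted-assay estimate of the protein metabolism index:
#' \deqn{qMPMI = (A_{2.3.1.109} + A_{2.6.1.19}) / (A_{3.5.3.12} + A_{2.8.3.18})}
#' generalized to whatever qPCR-marker roles the catalog declares (numerator
#' markers summed over denominator markers). A sample whose denominator sum
#' is 0 or whose markers are all missing is flagged with an NA index.
#'
#' @param aMeans data.frame from [averageReplicates()] (or any table with
#'   \code{sample}, \code{marker}, \code{a_value})
#' @param catalog a \linkS4class{MarkerCatalog}
#' @return data.frame with \code{sample}, \code{numerator_sum},
#'   \code{denominator_sum}, \code{qmpmi}, \code{flagged}
#' @export
computeQmpmi <- function(aMeans, catalog) {
  roles <- qpcrMarkers(catalog)
  nMk <- names(roles)[roles == "N"]
  dMk <- names(roles)[roles == "D"]
  samples <- unique(aMeans$sample)
  rows <- lapply(samples, function(s) {
    tab <- aMeans[aMeans$sample == s & !is.na(aMeans$a_value), ]
    av <- stats::setNames(tab$a_value, tab$marker)
    num <- sum(av[intersect(nMk, names(av))])
    den <- sum(av[intersect(dMk, names(av))])
    ok <- length(intersect(nMk, names(av))) >= 1L &&
      length(intersect(dMk, names(av))) >= 1L && den > 0
    data.frame(sample = s, numerator_sum = num, denominator_sum = den,
               qmpmi = if (ok) num / den else NA_real_, flagged = !ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read qPCR plate and calibration TSVs
#'
#' Plate TSV schema: \code{sample  marker  pair_id  replicate  ct  detected};
#' calibration TSV schema: \code{source  dilution  marker  ct}.
#'
#' @param path TSV path
#' @return data.frame in the documented schema
#' @export
readPlate <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "marker", "replicate", "ct", "detected")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("plate TSV missing column(s): ", paste(miss, collapse = ", "))
  df$detected <- as.logical(df$detected) | df$detected == 1
  df
}

#' @rdname readPlate
#' @export
readCalibration <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "dilution", "marker", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("calibration TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}
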