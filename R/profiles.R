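#' Read a KO gene-count table
#'
#' Reads a samples-by-KO count TSV: header row of KO identifiers, first
#' column the sample id. Counts must be non-negative integers; violations are
#' reported with their line number.
#'
#' @param path TSV path
#' @return integer matrix, samples in rows, KO ids in columns
#' @export
readCounts <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("count table '", path, "' has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  kos <- header[-1]
  if (anyDuplicated(kos)) stop("duplicate KO column in '", path, "'")
  ncols <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  samples <- character(length(rows))
  mat <- matrix(0L, nrow = length(rows), ncol = length(kos))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncols)
      stop("ragged row at line ", i + 1L, " of '", path, "' (", length(r),
           " fields, expected ", ncols, ")")
    samples[i] <- r[1]
    v <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(v)))
      stop("non-numeric count at line ", i + 1L, " of '", path, "'")
    if (any(v < 0))
      stop("negative count at line ", i + 1L, " of '", path, "'")
    if (any(v != round(v)))
      stop("non-integer count at line ", i + 1L, " of '", path, "'")
    mat[i, ] <- as.integer(v)
  }
  if (anyDuplicated(samples)) stop("duplicate sample id in '", path, "'")
  dimnames(mat) <- list(samples, kos)
  mat
}

#' @rdname readCounts
#' @param counts samples-by-KO integer matrix with dimnames
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a KO -> EC mapping TSV
#'
#' Two-column TSV \code{ko  ec}; a KO may appear on several rows when it maps
#' to several EC numbers.
#'
#' @param path TSV path
#' @return named list, KO id -> character vector of EC numbers
#' @export
readKoEcMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          col.names = c("ko", "ec"))
  split(df$ec, df$ko)
}

#' Regroup KO-annotated gene counts by EC number
#'
#' Sums gene counts over the KOs annotated to each EC number. A KO mapping to
#' several ECs contributes its full count to each of them (sum-regrouping, the
#' default); fractional splitting (count divided evenly across the mapped
#' ECs) is available via \code{split = "fractional"}. KOs with nonzero counts
#' absent from the mapping are tallied as unmapped mass per sample.
#'
#' @param counts samples-by-KO matrix (see [readCounts()])
#' @param koToEc named list KO -> character vector of EC numbers
#' @param split \code{"full"} (default) or \code{"fractional"}
#' @return list with \code{counts} (samples-by-EC numeric matrix),
#'   \code{unmappedMass} (named numeric, per-sample counts on unmapped KOs),
#'   \code{unmappedKos} (character vector)
#' @export
regroupKoToEc <- function(counts, koToEc, split = c("full", "fractional")) {
  split <- match.arg(split)
  if (!length(koToEc)) stop("empty KO -> EC mapping")
  if (!ncol(counts) || !nrow(counts)) {
    return(list(counts = matrix(0, nrow(counts), 0,
                                dimnames = list(rownames(counts), NULL)),
                unmappedMass = stats::setNames(rep(0, nrow(counts)),
                                               rownames(counts)),
                unmappedKos = character()))
  }
  kos <- colnames(counts)
  mapped <- kos %in% names(koToEc)
  unmappedKos <- kos[!mapped & colSums(counts) > 0]
  unmappedMass <- rowSums(counts[, !mapped, drop = FALSE])
  ecAll <- sort(unique(unlist(koToEc[kos[mapped]], use.names = FALSE)))
  out <- matrix(0, nrow = nrow(counts), ncol = length(ecAll),
                dimnames = list(rownames(counts), ecAll))
  for (ko in kos[mapped]) {
    ecs <- koToEc[[ko]]
    w <- if (split == "fractional") 1 / length(ecs) else 1
    for (ec in ecs)
      out[, ec] <- out[, ec] + counts[, ko] * w
  }
  list(counts = out,
       unmappedMass = stats::setNames(unmappedMass, rownames(counts)),
       unmappedKos = unmappedKos)
}

#' Internally normalize an EC count matrix
#'
#' Divides each sample's EC counts by the summed counts of a per-sample
#' reference set — by default the glycolysis/TCA-cycle module
#' ([glycolysisTcaSet()]) — so profiles are comparable across sequencing
#' depths. A sample whose reference total is zero is an error (naming the
#' sample) unless \code{pseudocount = TRUE}, which adds 1 to the reference
#' total of every sample.
#'
#' @param rawEc samples-by-EC matrix (e.g. \code{regroupKoToEc()$counts})
#' @param normalizationEcs character vector of reference EC numbers
#' @param pseudocount add 1 to every reference total (robustness experiments
#'   only; default FALSE)
#' @return an \linkS4class{ECAbundanceMatrix} (ECs in rows, samples in
#'   columns) with per-sample denominators in
#'   \code{colData()$norm_denominator}
#' @export
normalizeAbundance <- function(rawEc,
                               normalizationEcs = glycolysisTcaSet()$ec_number,
                               pseudocount = FALSE) {
  present <- intersect(normalizationEcs, colnames(rawEc))
  if (!length(present))
    stop("none of the normalization ECs are present in the matrix")
  denom <- rowSums(rawEc[, present, drop = FALSE])
  if (pseudocount) denom <- denom + 1
  zero <- which(denom <= 0)
  if (length(zero))
    stop("zero normalization denominator for sample(s): ",
         paste(rownames(rawEc)[zero], collapse = ", "))
  norm <- sweep(rawEc, 1, denom, "/")
  se <- SummarizedExperiment(
    assays = list(abundance = t(norm)),
    colData = DataFrame(sample_id = rownames(rawEc),
                        norm_denominator = unname(denom),
                        row.names = rownames(rawEc)))
  new("ECAbundanceMatrix", se)
}

#' Read an EC -> KEGG pathway annotation TSV
#'
#' Three-column TSV \code{ec  pathway  rank}; the pathways of an EC are
#' ordered by rank. When the same (ec, rank) slot occurs twice the last row
#' wins and a warning is raised.
#'
#' @param path TSV path
#' @return named list, EC -> ordered character vector of pathway ids
#' @export
readPathwayMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          col.names = c("ec", "pathway", "rank"))
  key <- paste(df$ec, df$rank)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (ec, rank) row(s) in '", path,
            "'; keeping the last occurrence")
    df <- df[!duplicated(key, fromLast = TRUE), ]
  }
  df <- df[order(df$ec, df$rank), ]
  split(df$pathway, df$ec)
}

#' Attach KEGG pathway annotations to an abundance matrix
#'
#' Attaches up to the top 5 pathway ids per EC, in the given order. ECs
#' absent from the annotation get an empty annotation; their count is stored
#' in \code{metadata(x)$unannotated_ecs}.
#'
#' @param x an \linkS4class{ECAbundanceMatrix}
#' @param ecToPathways named list EC -> ordered pathway ids (see
#'   [readPathwayMap()])
#' @param maxPathways per-EC cap (default 5)
#' @return \code{x} with \code{rowData()$pathways} filled (comma-separated)
#' @export
annotatePathways <- function(x, ecToPathways, maxPathways = 5L) {
  ecs <- rownames(x)
  ann <- vapply(ecs, function(ec) {
    p <- ecToPathways[[ec]]
    if (is.null(p)) "" else paste(utils::head(p, maxPathways), collapse = ",")
  }, character(1))
  rowData(x)$pathways <- unname(ann)
  metadata(x)$unannotated_ecs <- sum(!nzchar(ann))
  if (metadata(x)$unannotated_ecs > 0)
    warning(metadata(x)$unannotated_ecs, " EC number(s) had no pathway annotation")
  x
}

#' Pathway annotation as a list
#'
#' @param x an annotated \linkS4class{ECAbundanceMatrix}
#' @return named list EC -> character vector of pathway ids
#' @export
pathwayAnnotation <- function(x) {
  p <- rowData(x)$pathways
  if (is.null(p)) stop("matrix has no pathway annotation; run annotatePathways()")
  out <- strsplit(p, ",", fixed = TRUE)
  names(out) <- rownames(x)
  out
}

#' Write a normalized abundance matrix with its JSON sidecar
#'
#' Writes the samples-by-EC normalized matrix as TSV and a JSON sidecar
#' recording the per-sample normalization denominators (and, when supplied,
#' the unmapped-KO mass report from [regroupKoToEc()]).
#'
#' @param x an \linkS4class{ECAbundanceMatrix}
#' @param path output TSV path; the sidecar goes to \code{<path>.json}
#' @param unmapped optional named numeric of per-sample unmapped mass
#' @return invisibly, the TSV path
#' @export
writeAbundance <- function(x, path, unmapped = NULL) {
  m <- t(assay(x, "abundance"))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(norm_denominator = as.list(stats::setNames(
    colData(x)$norm_denominator, colnames(x))))
  if (!is.null(unmapped)) sidecar$unmapped_mass <- as.list(unmapped)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Accept either an ECAbundanceMatrix or a plain samples-by-features matrix
# and return samples-by-features.
.sampleMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) t(assay(x, "abundance")) else as.matrix(x)
}
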