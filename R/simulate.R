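#' Simulation configuration
#'
#' One config drives every generator, and each generator is a pure function
#' of it: the same config always yields byte-identical data. Defaults encode
#' the study conditions the package's analyses assume: 21 cecal samples per
#' treatment, duplicate qPCR wells, serial dilutions spanning 4 orders of
#' magnitude, 21 pens of 40 birds per treatment, pen effect sizes of +75 g
#' body weight gain and -0.069 FCR against between-pen dispersions matched to
#' standard errors of 17.59 g and 0.01 at 21 pens.
#'
#' @param seed integer RNG seed
#' @param nSamplesPerGroup cecal samples per treatment group
#' @param nEc total number of EC features to simulate (must cover the marker
#'   catalog plus the glycolysis/TCA normalization set)
#' @param markerEffectFold fold-enrichment of numerator-marker genes in the
#'   treated (PB) group at the KO level
#' @param abundanceLognormalSigma log-normal sigma of the per-KO baseline
#' @param depthRange min/max per-sample sequencing depth (gene counts)
#' @param ctNoiseSd Gaussian noise sd on simulated Ct values
#' @param trueSlopes named calibration slopes per qPCR key (4 markers + 16S)
#' @param trueIntercepts named calibration intercepts; keeping b/m identical
#'   across keys makes the relative-abundance formula exact (see the methods
#'   vignette)
#' @param sourceOffsets per-source Ct offsets for the calibration series
#' @param qpcrEnrichment fold-enrichment of numerator-marker template in the
#'   treated group of the simulated plate
#' @param penEffects list with \code{bwgShiftG} and \code{fcrShift}
#' @param penSd list with \code{bwg} and \code{fcr} between-pen standard
#'   deviations
#' @param mortalityProb per-bird mortality probability over the grow-out
#' @param scfaDetectionLimit,scfaPbFold SCFA generator settings (mM; fold)
#' @return list of class \code{"simulationConfig"}
#' @export
simulationConfig <- function(seed = 1L,
                             nSamplesPerGroup = 21L,
                             nEc = 200L,
                             markerEffectFold = 3,
                             abundanceLognormalSigma = 1,
                             depthRange = c(5e4, 2e5),
                             ctNoiseSd = 0.15,
                             trueSlopes = c("2.3.1.109" = -3.32,
                                            "2.6.1.19" = -3.32,
                                            "3.5.3.12" = -3.32,
                                            "2.8.3.18" = -3.32,
                                            "16S" = -3.32),
                             trueIntercepts = c("2.3.1.109" = 20,
                                                "2.6.1.19" = 20,
                                                "3.5.3.12" = 20,
                                                "2.8.3.18" = 20,
                                                "16S" = 20),
                             sourceOffsets = c(src1 = 0, src2 = 1.5),
                             qpcrEnrichment = 100,
                             penEffects = list(bwgShiftG = 75,
                                               fcrShift = -0.069),
                             penSd = list(bwg = 17.59 * sqrt(21),
                                          fcr = 0.01 * sqrt(21)),
                             mortalityProb = 0.03,
                             scfaDetectionLimit = 0.5,
                             scfaPbFold = 2) {
  stopifnot(nSamplesPerGroup >= 2, nEc >= 1, markerEffectFold > 0,
            abundanceLognormalSigma > 0, length(depthRange) == 2,
            depthRange[1] > 0, depthRange[2] >= depthRange[1],
            ctNoiseSd >= 0, qpcrEnrichment > 0,
            mortalityProb >= 0, mortalityProb <= 1)
  structure(list(seed = as.integer(seed),
                 nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 nEc = as.integer(nEc),
                 markerEffectFold = markerEffectFold,
                 abundanceLognormalSigma = abundanceLognormalSigma,
                 depthRange = depthRange, ctNoiseSd = ctNoiseSd,
                 trueSlopes = trueSlopes, trueIntercepts = trueIntercepts,
                 sourceOffsets = sourceOffsets,
                 qpcrEnrichment = qpcrEnrichment,
                 penEffects = penEffects, penSd = penSd,
                 mortalityProb = mortalityProb,
                 scfaDetectionLimit = scfaDetectionLimit,
                 scfaPbFold = scfaPbFold),
            class = "simulationConfig")
}

#' Simulate a KO gene-count table with a known treatment effect
#'
#' Emulates shallow-shotgun KO count tables: each KO gets a log-normal
#' baseline relative abundance, each sample a uniform sequencing depth, and
#' counts are Poisson draws from the depth-scaled composition. In treated
#' ("PB") samples every KO mapped to a numerator marker reaction is enriched
#' \code{markerEffectFold}-fold before depth scaling, so the effect is
#' injected at the KO level and must survive KO-to-EC regrouping to be
#' recovered. The KO universe is the marker catalog's KOs, one KO per
#' glycolysis/TCA normalization EC, and synthetic background KOs/ECs filling
#' up to \code{nEc} features.
#'
#' @param config a [simulationConfig()]
#' @param catalog a \linkS4class{MarkerCatalog}
#' @return list with \code{counts} (samples-by-KO integer matrix),
#'   \code{labels} (Control/PB factor), \code{koToEc} (mapping list covering
#'   every simulated KO), \code{normalizationEcs}, and \code{truth} (the
#'   generating enrichment fold)
#' @export
simulateCounts <- function(config = simulationConfig(),
                           catalog = loadCatalog()) {
  glyco <- glycolysisTcaSet()
  map <- koToEcMap(catalog)
  for (i in seq_len(nrow(glyco)))
    map[[glyco$kegg_ids[i]]] <- c(map[[glyco$kegg_ids[i]]], glyco$ec_number[i])
  coreEc <- unique(unlist(map, use.names = FALSE))
  nBackground <- config$nEc - length(coreEc)
  if (nBackground < 0)
    stop("nEc (", config$nEc, ") is smaller than the catalog plus ",
         "normalization set (", length(coreEc), " ECs)")
  if (nBackground > 0) {
    bgEc <- sprintf("9.9.%d.%d", seq_len(nBackground) %/% 100,
                    seq_len(nBackground) %% 100)
    bgKo <- sprintf("K9%04d", seq_len(nBackground))
    for (i in seq_len(nBackground)) map[[bgKo[i]]] <- bgEc[i]
  }
  kos <- names(map)
  nMarkerEc <- numeratorSet(catalog)
  isNKo <- vapply(map, function(ecs) any(ecs %in% nMarkerEc), logical(1))
  n <- config$nSamplesPerGroup
  samples <- c(paste0("Control_", seq_len(n)), paste0("PB_", seq_len(n)))
  labels <- factor(rep(c("Control", "PB"), each = n),
                   levels = c("Control", "PB"))
  counts <- withSeed(config$seed, {
    baseline <- stats::rlnorm(length(kos), meanlog = 0,
                              sdlog = config$abundanceLognormalSigma)
    names(baseline) <- kos
    depth <- round(stats::runif(2 * n, config$depthRange[1],
                                config$depthRange[2]))
    out <- matrix(0L, nrow = 2 * n, ncol = length(kos),
                  dimnames = list(samples, kos))
    for (s in seq_len(2 * n)) {
      lam <- baseline
      if (labels[s] == "PB") lam[isNKo] <- lam[isNKo] * config$markerEffectFold
      p <- lam / sum(lam)
      out[s, ] <- stats::rpois(length(kos), depth[s] * p)
    }
    out
  })
  list(counts = counts, labels = labels, koToEc = map,
       normalizationEcs = glyco$ec_number,
       truth = list(markerEffectFold = config$markerEffectFold))
}

#' Simulate a labeled EC abundance matrix with injected signal features
#'
#' Desk-scale generator for exercising the classifier pipeline directly: a
#' log-normal samples-by-features matrix in which the first \code{nSignal}
#' features carry a \code{fold}-fold mean shift in the second class.
#'
#' @param nPerGroup samples per class
#' @param nFeatures number of EC features (named EC-like)
#' @param nSignal number of shifted features
#' @param fold class-2 fold shift on the signal features
#' @param sigma log-normal sigma
#' @param seed RNG seed
#' @return list with \code{matrix} (samples x features), \code{labels},
#'   \code{signal} (names of the shifted features)
#' @export
simulateLabeledMatrix <- function(nPerGroup = 20L, nFeatures = 100L,
                                  nSignal = 5L, fold = 4, sigma = 1,
                                  seed = 1L) {
  stopifnot(nSignal <= nFeatures)
  feats <- sprintf("8.8.%d.%d", seq_len(nFeatures) %/% 100,
                   seq_len(nFeatures) %% 100)
  samples <- c(paste0("a_", seq_len(nPerGroup)),
               paste0("b_", seq_len(nPerGroup)))
  labels <- factor(rep(c("a", "b"), each = nPerGroup))
  m <- withSeed(seed, {
    base <- matrix(stats::rlnorm(2 * nPerGroup * nFeatures, 0, sigma),
                   nrow = 2 * nPerGroup, ncol = nFeatures,
                   dimnames = list(samples, feats))
    base[labels == "b", seq_len(nSignal)] <-
      base[labels == "b", seq_len(nSignal)] * fold
    base
  })
  list(matrix = m, labels = labels, signal = feats[seq_len(nSignal)])
}

#' Simulate qPCR calibration series and sample plates
#'
#' Calibration: for each qPCR key (4 markers + 16S), Ct values over a serial
#' dilution spanning 4 orders of magnitude (5 levels, duplicate wells) from
#' multiple template sources, generated from the log-linear model
#' \eqn{Ct = m \log_{10}(D) + b + s(S) + N(0, sd)}. Plate: per-sample true
#' marker template ratios (numerator markers enriched
#' \code{qpcrEnrichment}-fold in the treated group), converted to Ct through
#' the same model, in duplicate; any well whose true Ct exceeds
#' \code{maxCycles} is emitted as a non-detect.
#'
#' @param config a [simulationConfig()]
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param maxCycles detection ceiling (default 40 cycles)
#' @return list with \code{calibration} (source, dilution, marker, ct),
#'   \code{plate} (sample, marker, pair_id, replicate, ct, detected),
#'   \code{labels}, and \code{truth} (per-sample true marker/16S ratios and
#'   the generating slopes)
#' @export
simulateQpcr <- function(config = simulationConfig(),
                         catalog = loadCatalog(), maxCycles = 40) {
  keys <- names(config$trueSlopes)
  roles <- qpcrMarkers(catalog)
  markers <- names(roles)
  stopifnot(all(markers %in% keys), "16S" %in% keys)
  n <- config$nSamplesPerGroup
  samples <- c(paste0("Control_", seq_len(n)), paste0("PB_", seq_len(n)))
  labels <- factor(rep(c("Control", "PB"), each = n),
                   levels = c("Control", "PB"))
  dilutions <- 10^-(0:4)
  withSeed(config$seed, {
    cal <- do.call(rbind, lapply(keys, function(k) {
      do.call(rbind, lapply(names(config$sourceOffsets), function(src) {
        do.call(rbind, lapply(dilutions, function(d) {
          ct <- config$trueSlopes[[k]] * log10(d) + config$trueIntercepts[[k]] +
            config$sourceOffsets[[src]] +
            stats::rnorm(2, 0, config$ctNoiseSd)
          data.frame(source = src, dilution = d, marker = k, ct = ct,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    # true per-sample template ratios relative to 16S (fixed at 1)
    truth <- matrix(NA_real_, nrow = 2 * n, ncol = length(markers),
                    dimnames = list(samples, markers))
    plate <- list()
    for (s in seq_len(2 * n)) {
      r16 <- stats::rlnorm(1, meanlog = 0, sdlog = 0.25)
      for (k in c(markers, "16S")) {
        if (k == "16S") {
          rTrue <- r16
        } else {
          base <- stats::rlnorm(1, meanlog = log(1e-3), sdlog = 0.5)
          if (labels[s] == "PB" && roles[[k]] == "N")
            base <- base * config$qpcrEnrichment
          truth[s, k] <- base
          rTrue <- base * r16
        }
        for (rep_ in 1:2) {
          ct <- config$trueSlopes[[k]] * log10(rTrue) +
            config$trueIntercepts[[k]] + stats::rnorm(1, 0, config$ctNoiseSd)
          detected <- ct <= maxCycles
          plate[[length(plate) + 1L]] <-
            data.frame(sample = samples[s], marker = k, pair_id = "blend",
                       replicate = rep_, ct = if (detected) ct else NA_real_,
                       detected = detected, stringsAsFactors = FALSE)
        }
      }
    }
    list(calibration = cal, plate = do.call(rbind, plate), labels = labels,
         truth = list(ratios = truth, slopes = config$trueSlopes))
  })
}

#' Simulate pen-level grow-out records
#'
#' Pen body weight gain is Normal(control mean + treatment shift, between-pen
#' sd); feed intake is derived from a Normal feed-conversion draw so that
#' [penMetrics()] recovers the generating FCR; mortality is Binomial per pen.
#' Defaults put the control at 2,463 g gain and 1.855 FCR over 0-42 d.
#'
#' @param config a [simulationConfig()]
#' @param nPens pens per treatment (default 21)
#' @param birdsPerPen birds placed per pen (default 40)
#' @param controlBwg,controlFcr control-group generating means
#' @param bw0 placement weight, g
#' @return data.frame in the [readPens()] schema, plus a \code{true_fcr}
#'   column retained for recovery tests
#' @export
simulatePens <- function(config = simulationConfig(), nPens = 21L,
                         birdsPerPen = 40L, controlBwg = 2463,
                         controlFcr = 1.855, bw0 = 40) {
  trts <- c("Control", "PB")
  withSeed(childSeed(config$seed, 3L), {
    rows <- lapply(seq_len(2 * nPens), function(i) {
      trt <- trts[(i - 1) %/% nPens + 1]
      shiftB <- if (trt == "PB") config$penEffects$bwgShiftG else 0
      shiftF <- if (trt == "PB") config$penEffects$fcrShift else 0
      bwg <- stats::rnorm(1, controlBwg + shiftB, config$penSd$bwg)
      fcr <- stats::rnorm(1, controlFcr + shiftF, config$penSd$fcr)
      mort <- stats::rbinom(1, birdsPerPen, config$mortalityProb)
      alive <- birdsPerPen - mort
      totalGain <- alive * bwg + mort * bwg / 2
      data.frame(pen = sprintf("%s_p%02d", trt, (i - 1) %% nPens + 1),
                 treatment = trt, block = ((i - 1) %% nPens) + 1,
                 n0 = birdsPerPen, bw0 = bw0,
                 bw10 = round(bw0 + 0.115 * bwg), bw24 = round(bw0 + 0.48 * bwg),
                 bw42 = bw0 + bwg, fi_total = fcr * totalGain,
                 mortality = mort, true_fcr = fcr, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate ex vivo SCFA concentration tables
#'
#' Acetate is present in every group; propionate and butyrate are drawn below
#' the detection limit in the control group (and flagged non-detected) and at
#' quantifiable concentrations under treatment, mirroring supernatant
#' measurements where those acids appear only after incubation with the
#' glycan supplement.
#'
#' @param config a [simulationConfig()]
#' @param nPerGroup samples per treatment-by-cohort cell (default 6)
#' @return data.frame with \code{sample}, \code{treatment}, \code{cohort},
#'   \code{acid}, \code{concentration_mM}, \code{detected}
#' @export
simulateScfa <- function(config = simulationConfig(), nPerGroup = 6L) {
  cells <- expand.grid(treatment = c("Control", "PB"),
                       cohort = c("Low", "High"), idx = seq_len(nPerGroup),
                       stringsAsFactors = FALSE)
  acids <- c(acetate = 20, propionate = 4, butyrate = 3)
  withSeed(childSeed(config$seed, 4L), {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      trt <- cells$treatment[i]
      do.call(rbind, lapply(names(acids), function(acid) {
        if (acid == "acetate") {
          mu <- acids[[acid]] * if (trt == "PB") config$scfaPbFold else 1
          conc <- stats::rlnorm(1, log(mu), 0.2)
          det <- TRUE
        } else if (trt == "PB") {
          conc <- stats::rlnorm(1, log(acids[[acid]]), 0.3)
          det <- conc >= config$scfaDetectionLimit
        } else {
          conc <- stats::runif(1, 0, config$scfaDetectionLimit)
          det <- FALSE
        }
        data.frame(sample = sprintf("%s_%s_%d", trt, cells$cohort[i],
                                    cells$idx[i]),
                   treatment = trt, cohort = cells$cohort[i], acid = acid,
                   concentration_mM = conc, detected = det,
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}
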