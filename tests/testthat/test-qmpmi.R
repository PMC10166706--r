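noiseFreeSeries <- function(m = -3.32, b = 25, dilutions = 10^-(0:4),
                            source = "A", offset = 0) {
  data.frame(source = source, dilution = dilutions,
             ct = m * log10(dilutions) + b + offset)
}

test_that("calibration fitting recovers a noise-free log-linear model exactly", {
  fit <- fitCalibration(noiseFreeSeries(), "2.3.1.109")
  expect_equal(calibrationSlope(fit), -3.32, tolerance = 1e-9)
  expect_equal(calibrationIntercept(fit), 25, tolerance = 1e-9)
  expect_equal(calibrationR2(fit), 1, tolerance = 1e-9)
  expect_error(fitCalibration(noiseFreeSeries(dilutions = 0.1), "x"),
               "3 distinct dilution levels")
  # collinear design: source perfectly confounded with dilution
  conf <- rbind(noiseFreeSeries(dilutions = c(1, 0.1), source = "A"),
                noiseFreeSeries(dilutions = c(0.01, 0.001), source = "B"))
  fitC <- fitCalibration(conf, "x")  # estimable here; degenerate case below
  one <- data.frame(source = c("A", "B", "C"), dilution = c(1, 0.1, 0.01),
                    ct = c(25, 28, 31))
  expect_error(fitCalibration(one, "x"), "collinear|rank")
})

test_that("per-source intercept offsets are recovered under Ct noise", {
  recovered <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    ser <- rbind(noiseFreeSeries(source = "A"),
                 noiseFreeSeries(source = "B", offset = 1.5))
    ser$ct <- ser$ct + rnorm(nrow(ser), 0, 0.15)
    fitCalibration(ser, "x")@sourceOffsets[["B"]]
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 1.5), 0.05)
  # and slopes stay within +/- 0.05 of truth on average
  slopes <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    ser <- noiseFreeSeries()
    ser$ct <- ser$ct + rnorm(nrow(ser), 0, 0.15)
    calibrationSlope(fitCalibration(ser, "x"))
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 3.32), 0.05)
})

test_that("relative abundance follows the delta-Ct-over-slope identity", {
  fm <- fitCalibration(noiseFreeSeries(m = -3.32, b = 20), "mk")
  f16 <- fitCalibration(noiseFreeSeries(m = -3.32, b = 20), "16S")
  # equal Ct/m terms -> A = 1; exponent difference of 1 -> A = 10
  expect_equal(relativeAbundance(33.2, fm, 33.2, f16), 1, tolerance = 1e-12)
  expect_equal(relativeAbundance(29.88, fm, 33.2, f16), 10, tolerance = 1e-9)
  # uniform template dilution shifts both Ct terms equally -> A unchanged
  for (d in 10^c(-2, -1, 1, 2)) {
    ctM <- -3.32 * log10(0.005) + 20
    ct16 <- -3.32 * log10(0.8) + 20
    dCtM <- -3.32 * log10(0.005 * d) + 20
    dCt16 <- -3.32 * log10(0.8 * d) + 20
    expect_equal(relativeAbundance(dCtM, fm, dCt16, f16),
                 relativeAbundance(ctM, fm, ct16, f16), tolerance = 1e-9)
  }
  zero <- fm; zero@slope <- 1e-300
  expect_error(relativeAbundance(30, methods::new("CalibrationFit", key = "x",
    slope = 0, intercept = 0, sourceOffsets = c(A = 0), rSquared = 1,
    nLevels = 3L), 30, f16))
})

test_that("replicates average on the abundance scale with non-detect policies", {
  aTab <- data.frame(sample = "s1", marker = "2.3.1.109", replicate = 1:2,
                     a_value = c(2, 4), detected = TRUE)
  av <- averageReplicates(aTab)
  expect_equal(av$a_value, 3)
  expect_equal(av$n_replicates, 2L)
  single <- averageReplicates(aTab[1, ])
  expect_equal(single$a_value, 2)
  # censor policy: a detected + censored pair keeps the detected value, flagged
  cens <- data.frame(sample = "s1", marker = "2.3.1.109", replicate = 1:2,
                     a_value = c(2, NA), detected = c(TRUE, FALSE))
  avc <- averageReplicates(cens)
  expect_equal(avc$a_value, 2)
  expect_false(avc$all_detected)
  expect_equal(avc$n_replicates, 1L)
})

test_that("plate processing applies the configured non-detect policy", {
  fits <- list("2.3.1.109" = fitCalibration(noiseFreeSeries(b = 20), "2.3.1.109"),
               "16S" = fitCalibration(noiseFreeSeries(b = 20), "16S"))
  plate <- data.frame(sample = "s1", marker = c("2.3.1.109", "16S"),
                      pair_id = "blend", replicate = 1L,
                      ct = c(NA, 20), detected = c(FALSE, TRUE))
  floorA <- relativeAbundanceTable(plate, fits, policy = "floor")
  expect_equal(floorA$a_value, relativeAbundance(40, fits[[1]], 20, fits[[2]]))
  expect_false(floorA$detected)
  expect_true(is.na(relativeAbundanceTable(plate, fits, "censor")$a_value))
  expect_equal(relativeAbundanceTable(plate, fits, "zero")$a_value, 0)
})

test_that("qMPMI is the N-marker over D-marker abundance ratio", {
  a4 <- data.frame(sample = "s1",
                   marker = c("2.3.1.109", "2.6.1.19", "3.5.3.12", "2.8.3.18"),
                   a_value = 1)
  expect_equal(computeQmpmi(a4, theCatalog)$qmpmi, 1)
  a4$a_value <- c(2, 2, 1, 1)
  expect_equal(computeQmpmi(a4, theCatalog)$qmpmi, 2)
  # missing D markers flag the sample
  aN <- a4[1:2, ]
  res <- computeQmpmi(aN, theCatalog)
  expect_true(res$flagged)
  expect_true(is.na(res$qmpmi))
})

test_that("noise-free simulated plates recover template ratios to numerical precision", {
  cfg <- simulationConfig(seed = 21, nSamplesPerGroup = 4, ctNoiseSd = 0)
  q <- simulateQpcr(cfg)
  fits <- lapply(split(q$calibration, q$calibration$marker),
                 function(d) fitCalibration(d, d$marker[1]))
  aTab <- relativeAbundanceTable(q$plate, fits)
  av <- averageReplicates(aTab)
  det <- av[av$all_detected, ]
  for (i in seq_len(nrow(det)))
    expect_equal(det$a_value[i], q$truth$ratios[det$sample[i], det$marker[i]],
                 tolerance = 1e-6)
})

test_that("a 100-fold numerator enrichment is recovered through the full qPCR pipeline", {
  cfg <- simulationConfig(seed = 33, nSamplesPerGroup = 6, ctNoiseSd = 0.2,
                          qpcrEnrichment = 100)
  q <- simulateQpcr(cfg)
  fits <- lapply(split(q$calibration, q$calibration$marker),
                 function(d) fitCalibration(d, d$marker[1]))
  qm <- computeQmpmi(averageReplicates(relativeAbundanceTable(q$plate, fits)),
                     theCatalog)
  ratio <- median(qm$qmpmi[q$labels == "PB"], na.rm = TRUE) /
    median(qm$qmpmi[q$labels == "Control"], na.rm = TRUE)
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
})

test_that("qMPMI is dilution-invariant and monotone in marker concentrations", {
  fits <- lapply(c("2.3.1.109", "2.6.1.19", "3.5.3.12", "2.8.3.18", "16S"),
                 function(k) fitCalibration(noiseFreeSeries(b = 20), k))
  names(fits) <- c("2.3.1.109", "2.6.1.19", "3.5.3.12", "2.8.3.18", "16S")
  concs <- c("2.3.1.109" = 2e-3, "2.6.1.19" = 5e-4, "3.5.3.12" = 1e-3,
             "2.8.3.18" = 3e-3)
  mkPlate <- function(concs, dilution = 1) {
    rows <- lapply(c(names(concs), "16S"), function(k) {
      r <- if (k == "16S") 1 else concs[[k]]
      data.frame(sample = "s1", marker = k, pair_id = "blend", replicate = 1L,
                 ct = -3.32 * log10(r * dilution) + 20, detected = TRUE)
    })
    do.call(rbind, rows)
  }
  qm <- function(p) computeQmpmi(averageReplicates(
    relativeAbundanceTable(p, fits)), theCatalog)$qmpmi
  base <- qm(mkPlate(concs))
  for (d in 10^c(-2, -1, 1, 2))
    expect_equal(qm(mkPlate(concs, dilution = d)), base, tolerance = 1e-9)
  up <- concs; up["2.3.1.109"] <- up["2.3.1.109"] * 2
  expect_gt(qm(mkPlate(up)), base)
  dn <- concs; dn["2.8.3.18"] <- dn["2.8.3.18"] * 2
  expect_lt(qm(mkPlate(dn)), base)
})
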