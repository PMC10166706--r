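test_that("KO-to-EC regrouping sums counts and conserves per-KO mass", {
  counts <- matrix(c(10L, 3L, 5L, 7L), nrow = 1,
                   dimnames = list("s1", c("K00129", "K01956", "K01955",
                                           "K99999")))
  map <- list(K00129 = "1.2.1.5", K01956 = "6.3.5.5", K01955 = "6.3.5.5",
              K99999 = c("1.1.1.1", "2.2.2.2"))
  rg <- regroupKoToEc(counts, map)
  expect_equal(rg$counts["s1", "1.2.1.5"], 10)
  expect_equal(rg$counts["s1", "6.3.5.5"], 8)
  # a KO mapped to 2 ECs contributes its full count to each
  expect_equal(rg$counts["s1", "1.1.1.1"], 7)
  expect_equal(rg$counts["s1", "2.2.2.2"], 7)
  # brute-force oracle over the toy table: total EC mass per KO is
  # count x (number of mapped ECs)
  expect_equal(sum(rg$counts), 10 + 8 + 7 * 2)

  frac <- regroupKoToEc(counts, map, split = "fractional")
  expect_equal(frac$counts["s1", "1.1.1.1"], 3.5)
  expect_equal(sum(frac$counts), 10 + 8 + 7)
})

test_that("unmapped KO mass is reported and empty mappings are rejected", {
  counts <- matrix(c(4L, 6L), nrow = 1,
                   dimnames = list("s1", c("K00129", "Kxxxxx")))
  rg <- regroupKoToEc(counts, list(K00129 = "1.2.1.5"))
  expect_equal(unname(rg$unmappedMass["s1"]), 6)
  expect_equal(rg$unmappedKos, "Kxxxxx")
  expect_error(regroupKoToEc(counts, list()), "empty")
})

test_that("internal normalization divides by the reference-set total", {
  raw <- matrix(c(50, 60, 40, 30, 70), nrow = 1,
                dimnames = list("s1", c("EC_x", "g1", "g2", "g3", "other")))
  em <- normalizeAbundance(raw, c("g1", "g2", "g3"))
  expect_s4_class(em, "ECAbundanceMatrix")
  expect_equal(SummarizedExperiment::colData(em)$norm_denominator, 130)
  expect_equal(SummarizedExperiment::assay(em)["EC_x", "s1"], 50 / 130)
  # scaling one sample's counts leaves its normalized row unchanged
  em7 <- normalizeAbundance(raw * 7, c("g1", "g2", "g3"))
  expect_equal(SummarizedExperiment::assay(em7), SummarizedExperiment::assay(em))
})

test_that("normalized profiles are depth-invariant (property)", {
  sim <- simulatedEcMatrix(seed = 42, n = 4, nEc = 60)
  base <- t(SummarizedExperiment::assay(sim$ecmat))
  rg <- regroupKoToEc(sim$sim$counts, sim$sim$koToEc)
  set.seed(99)
  for (rep in 1:5) {
    scales <- runif(nrow(rg$counts), 0.1, 10)
    scaled <- normalizeAbundance(rg$counts * scales,
                                 sim$sim$normalizationEcs)
    expect_equal(t(SummarizedExperiment::assay(scaled)), base,
                 tolerance = 1e-12)
  }
})

test_that("renormalizing an already-normalized matrix changes it unless the reference total is 1", {
  sim <- simulatedEcMatrix(seed = 5, n = 3, nEc = 60)
  m1 <- t(SummarizedExperiment::assay(sim$ecmat))
  m2 <- normalizeAbundance(m1, sim$sim$normalizationEcs)
  # after one normalization the reference total is denominator/denominator = 1
  expect_equal(unname(SummarizedExperiment::colData(m2)$norm_denominator),
               rep(1, nrow(m1)))
  expect_equal(t(SummarizedExperiment::assay(m2)), m1, tolerance = 1e-12)
  # but dividing by a different reference subset is not idempotent
  oneEc <- sim$sim$normalizationEcs[1]
  m3 <- normalizeAbundance(m1, oneEc)
  expect_false(isTRUE(all.equal(t(SummarizedExperiment::assay(m3)), m1)))
})

test_that("zero reference totals fail fast naming the sample", {
  raw <- matrix(c(5, 0, 3, 2), nrow = 2,
                dimnames = list(c("good", "bad"), c("g1", "e1")))
  raw["bad", "g1"] <- 0
  raw["good", "g1"] <- 5
  expect_error(normalizeAbundance(raw, "g1"), "bad")
  expect_silent(normalizeAbundance(raw, "g1", pseudocount = TRUE))
})

test_that("pathway annotation keeps the top 5 in order and warns on gaps", {
  raw <- matrix(1:3, nrow = 1,
                dimnames = list("s1", c("1.1.1.1", "2.2.2.2", "g1")))
  em <- normalizeAbundance(raw, "g1")
  ann <- list("1.1.1.1" = paste0("map", 1:7))
  expect_warning(em2 <- annotatePathways(em, ann), "no pathway annotation")
  p <- pathwayAnnotation(em2)
  expect_equal(p[["1.1.1.1"]], paste0("map", 1:5))
  expect_equal(p[["2.2.2.2"]], character(0))
  expect_equal(S4Vectors::metadata(em2)$unannotated_ecs, 2L)
})

test_that("duplicate pathway-map rows resolve to the last occurrence", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ec\tpathway\trank",
               "1.1.1.1\tmapA\t1",
               "1.1.1.1\tmapB\t1",
               "1.1.1.1\tmapC\t2"), f)
  expect_warning(pm <- readPathwayMap(f), "duplicate")
  expect_equal(pm[["1.1.1.1"]], c("mapB", "mapC"))
})

test_that("count tables round-trip through TSV and invalid files are rejected", {
  counts <- matrix(c(0L, 5L, 2L, 7L), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("K00001", "K00002")))
  f <- tempfile(fileext = ".tsv")
  writeCounts(counts, f)
  expect_identical(readCounts(f), counts)

  writeLines(c("sample\tK00001", "s1\t-3"), f)
  expect_error(readCounts(f), "negative count at line 2")
  writeLines(c("sample\tK00001", "s1\t1\t2"), f)
  expect_error(readCounts(f), "ragged row at line 2")
  writeLines(c("sample\tK00001", "s1\t1.5"), f)
  expect_error(readCounts(f), "non-integer count at line 2")
})

test_that("abundance matrices write a TSV with a denominator sidecar", {
  sim <- simulatedEcMatrix(seed = 2, n = 3, nEc = 60)
  f <- tempfile(fileext = ".tsv")
  writeAbundance(sim$ecmat, f, unmapped = c(s1 = 0))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(length(side$norm_denominator), ncol(sim$ecmat))
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), ncol(sim$ecmat))
})
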