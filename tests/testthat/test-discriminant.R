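fastCfg <- classifierConfig(nTrees = 500L, seed = 11L)

test_that("importance ranking recovers injected signal features deterministically", {
  sim <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 100, nSignal = 5,
                               fold = 4, seed = 11)
  rk <- rankFeatures(sim$matrix, sim$labels, fastCfg)
  expect_equal(sort(rk$ec_id), sort(colnames(sim$matrix)))
  expect_equal(rk$rank, seq_len(100))
  # ranks are the descending-importance order with lexicographic tie-break
  expect_true(all(diff(rk$importance) <= 0))
  ties <- which(diff(rk$importance) == 0)
  if (length(ties))
    expect_true(all(rk$ec_id[ties] < rk$ec_id[ties + 1L]))
  expect_true(all(sim$signal %in% rk$ec_id[1:10]))
  # identical run, identical seed -> identical ranking
  rk2 <- rankFeatures(sim$matrix, sim$labels, fastCfg)
  expect_identical(rk, rk2)
})

test_that("degenerate classifier inputs are rejected", {
  sim <- simulateLabeledMatrix(nPerGroup = 5, nFeatures = 10, seed = 1)
  expect_error(rankFeatures(sim$matrix, rep("a", 10), fastCfg), "2 classes")
  expect_error(rankFeatures(sim$matrix, c("a", rep("b", 9)), fastCfg),
               "at least 3 samples")
  const <- matrix(1, 10, 4, dimnames = list(paste0("s", 1:10),
                                            paste0("f", 1:4)))
  expect_error(rankFeatures(const, sim$labels, fastCfg), "constant feature")
})

test_that("permuted labels leave out-of-bag accuracy near chance", {
  sim <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 100, nSignal = 5,
                               fold = 4, seed = 11)
  perm <- withr::with_seed(3, sample(sim$labels))
  rk <- rankFeatures(sim$matrix, perm, fastCfg)
  expect_lt(abs(attr(rk, "oob_accuracy") - 0.5), 0.2)
})

test_that("truncation retains the configured number of features and retrains", {
  sim <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 100, nSignal = 5,
                               fold = 4, seed = 11)
  rk <- rankFeatures(sim$matrix, sim$labels, fastCfg)
  tr <- truncateAndRetrain(sim$matrix, sim$labels, rk, fastCfg)
  expect_length(tr$retained, 30L)
  expect_identical(tr$retained, rk$ec_id[1:30])
  # strong signal: the truncated model classifies nearly perfectly
  for (s in c(21L, 22L, 23L)) {
    cfg <- classifierConfig(nTrees = 500L, seed = s)
    trS <- truncateAndRetrain(sim$matrix, sim$labels,
                              rankFeatures(sim$matrix, sim$labels, cfg), cfg)
    expect_gte(trS$oob_accuracy, 0.9)
  }
  allCfg <- classifierConfig(nTrees = 200L, truncationSize = 100L, seed = 11L)
  trAll <- truncateAndRetrain(sim$matrix, sim$labels, rk, allCfg)
  expect_setequal(trAll$retained, colnames(sim$matrix))
  tooBig <- classifierConfig(truncationSize = 101L)
  expect_error(truncateAndRetrain(sim$matrix, sim$labels, rk, tooBig),
               "exceeds")
})

test_that("ensemble validation separates signal from null data", {
  cfg <- classifierConfig(nTrees = 300L, truncationSize = 20L, seed = 5L)
  null <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 60, nSignal = 0,
                                seed = 8)
  ev0 <- ensembleValidate(null$matrix, null$labels, cfg, nModels = 10L)
  expect_length(ev0$accuracies, 10L)
  expect_gt(mean(ev0$accuracies), 0.3)
  expect_lt(mean(ev0$accuracies), 0.7)

  sig <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 60, nSignal = 5,
                               fold = 4, seed = 9)
  ev1 <- ensembleValidate(sig$matrix, sig$labels, cfg, nModels = 10L)
  expect_true(all(ev1$selectionFrequency[sig$signal] >= 0.8))
  expect_gt(mean(ev1$accuracies), mean(ev0$accuracies))

  expect_error(ensembleValidate(sig$matrix, sig$labels, cfg, nModels = 1L),
               "at least 2 models")
})

test_that("LFDA embedding separates shifted classes and is functionally deterministic", {
  sim <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 40, nSignal = 8,
                               fold = 4, seed = 13)
  emb <- lfdaEmbed(sim$matrix, sim$labels)
  expect_equal(nrow(emb), 40L)
  expect_true(all(is.finite(as.matrix(emb[, c("LFDA1", "LFDA2")]))))
  expect_gt(meanSilhouette(emb), 0.5)

  # null check at feature counts well below the sample count: supervised
  # embeddings fit spurious structure as dimension approaches n (see the
  # methods vignette), so the chance-level contract is asserted at d << n
  null <- simulateLabeledMatrix(nPerGroup = 20, nFeatures = 10, nSignal = 0,
                                seed = 77)
  perm <- withr::with_seed(4, sample(null$labels))
  embPerm <- lfdaEmbed(null$matrix, perm)
  expect_lt(meanSilhouette(embPerm), 0.25)

  # duplicate samples map to identical coordinates
  dup <- rbind(sim$matrix, dup1 = sim$matrix[1, ])
  embDup <- lfdaEmbed(dup, c(as.character(sim$labels),
                             as.character(sim$labels[1])))
  expect_equal(unlist(embDup[41, c("LFDA1", "LFDA2")]),
               unlist(embDup[1, c("LFDA1", "LFDA2")]))
  expect_identical(lfdaEmbed(sim$matrix, sim$labels), emb)
  expect_error(lfdaEmbed(sim$matrix[1:2, ], sim$labels[1:2]), "class")
})

test_that("pathway importance aggregates with full-count regrouping and control-relative sign", {
  rk <- data.frame(ec_id = c("1.1.1.1", "2.2.2.2", "3.3.3.3"),
                   importance = c(0.4, 0.3, 0.2), rank = 1:3)
  ann <- list("1.1.1.1" = c("mapA", "mapB"),
              "2.2.2.2" = c("mapB"),
              "3.3.3.3" = c("mapA", "mapC"))
  pi0 <- pathwayImportance(rk, ann)
  expect_equal(pi0$importance[pi0$pathway == "mapA"], 0.4 + 0.2)
  expect_equal(pi0$importance[pi0$pathway == "mapB"], 0.4 + 0.3)
  expect_equal(pi0$importance[pi0$pathway == "mapC"], 0.2)
  # sign relative to the control class mean
  m <- matrix(c(1, 1, 2, 2,   # 1.1.1.1 higher under treatment
                2, 2, 1, 1,   # 2.2.2.2 lower under treatment
                1, 1, 3, 3),
              nrow = 4, dimnames = list(paste0("s", 1:4),
                                        c("1.1.1.1", "2.2.2.2", "3.3.3.3")))
  lab <- factor(c("Control", "Control", "PB", "PB"))
  ps <- pathwayImportance(rk, ann, m, lab, controlLabel = "Control")
  expect_equal(ps$importance[ps$pathway == "mapB"], 0.4 - 0.3)
  expect_equal(ps$importance[ps$pathway == "mapA"], 0.4 + 0.2)
  expect_warning(pe <- pathwayImportance(rk, list()), "no ranked EC")
  expect_equal(nrow(pe), 0L)
})
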