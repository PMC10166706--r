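#' Random-forest classifier configuration
#'
#' Defaults follow the profiling procedure: \code{mtry = 2}, 10,000 trees,
#' truncation to the 30 most important features, 60\% training subsamples for
#' ensemble robustness checks. \code{mtry = 2} is unusually small for a
#' 30-feature space but is kept as the procedure's stated setting; override
#' it here for sensitivity analyses.
#'
#' @param mtry variables tried at each split (default 2)
#' @param nTrees trees per forest (default 10000)
#' @param truncationSize features kept after importance ranking (default 30)
#' @param subsampleFraction training fraction for ensemble validation
#'   (default 0.6)
#' @param seed RNG seed making every stochastic step reproducible
#' @return a list of class \code{"classifierConfig"}
#' @export
classifierConfig <- function(mtry = 2L, nTrees = 10000L, truncationSize = 30L,
                             subsampleFraction = 0.6, seed = 1L) {
  stopifnot(mtry >= 1, nTrees >= 1, truncationSize >= 1,
            subsampleFraction > 0, subsampleFraction <= 1)
  structure(list(mtry = as.integer(mtry), nTrees = as.integer(nTrees),
                 truncationSize = as.integer(truncationSize),
                 subsampleFraction = subsampleFraction,
                 seed = as.integer(seed)),
            class = "classifierConfig")
}

.checkDiscriminantInput <- function(m, labels) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 3L)) stop("each class needs at least 3 samples")
  if (all(apply(m, 2, function(v) length(unique(v)) == 1L)))
    stop("constant feature matrix: no feature varies")
  labels
}

.rfFit <- function(m, labels, config, seed = config$seed) {
  withSeed(seed,
    randomForest::randomForest(x = m, y = labels, mtry = config$mtry,
                               ntree = config$nTrees, importance = TRUE))
}

.oobAccuracy <- function(fit, labels)
  mean(fit$predicted == labels)

#' Rank EC features by mean decrease in accuracy
#'
#' Trains a random-forest classifier on the normalized EC abundances and
#' ranks every feature by its permutation importance (mean decrease in
#' out-of-bag accuracy when the feature's values are shuffled). Ties are
#' broken lexicographically by EC id, so rankings are fully deterministic
#' under a fixed seed.
#'
#' @param x \linkS4class{ECAbundanceMatrix} or samples-by-EC matrix
#' @param labels class labels (e.g. Control vs treatment), one per sample
#' @param config a [classifierConfig()]
#' @return data.frame with \code{ec_id}, \code{importance} (mean decrease in
#'   accuracy), \code{rank}; attribute \code{oob_accuracy} gives the full
#'   model's out-of-bag accuracy
#' @export
rankFeatures <- function(x, labels, config = classifierConfig()) {
  m <- .sampleMatrix(x)
  labels <- .checkDiscriminantInput(m, labels)
  fit <- .rfFit(m, labels, config)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp), method = "radix")
  out <- data.frame(ec_id = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  attr(out, "oob_accuracy") <- .oobAccuracy(fit, labels)
  out
}

#' Truncate the ranking and retrain
#'
#' Keeps the \code{truncationSize} most important features from a
#' [rankFeatures()] ranking and retrains the forest on that submatrix with
#' otherwise identical parameters, limiting overfitting to the full EC space.
#'
#' @inheritParams rankFeatures
#' @param ranking a data.frame from [rankFeatures()]
#' @return list with \code{retained} (character vector, length
#'   \code{truncationSize}), \code{model} (the retrained
#'   \code{randomForest}), \code{oob_accuracy}
#' @export
truncateAndRetrain <- function(x, labels, ranking,
                               config = classifierConfig()) {
  m <- .sampleMatrix(x)
  labels <- .checkDiscriminantInput(m, labels)
  if (!all(ranking$ec_id %in% colnames(m)))
    stop("ranking refers to features absent from the matrix")
  if (config$truncationSize > nrow(ranking))
    stop("truncation size (", config$truncationSize,
         ") exceeds the number of ranked features (", nrow(ranking), ")")
  retained <- ranking$ec_id[seq_len(config$truncationSize)]
  fit <- .rfFit(m[, retained, drop = FALSE], labels, config)
  list(retained = retained, model = fit,
       oob_accuracy = .oobAccuracy(fit, labels))
}

#' Ensemble robustness validation
#'
#' Trains \code{nModels} rank-and-truncate models, each on an independent
#' stratified subsample (\code{subsampleFraction} of the samples), and
#' evaluates each on its held-out complement. Reports per-model held-out
#' accuracies and, per EC, the fraction of models whose truncated feature set
#' selected it.
#'
#' @inheritParams rankFeatures
#' @param nModels number of ensemble members (at least 2)
#' @param seeds optional integer vector of per-model seeds (defaults derive
#'   from \code{config$seed})
#' @return list with \code{accuracies} (numeric, length \code{nModels}) and
#'   \code{selectionFrequency} (named numeric over all ECs ever selected)
#' @export
ensembleValidate <- function(x, labels, config = classifierConfig(),
                             nModels = 10L, seeds = NULL) {
  if (nModels < 2L) stop("ensemble validation needs at least 2 models")
  m <- .sampleMatrix(x)
  labels <- .checkDiscriminantInput(m, labels)
  if (is.null(seeds))
    seeds <- vapply(seq_len(nModels), function(i) childSeed(config$seed, i),
                    numeric(1))
  acc <- numeric(nModels)
  selected <- vector("list", nModels)
  for (i in seq_len(nModels)) {
    trainIdx <- withSeed(seeds[i], unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(config$subsampleFraction * length(idx))))
    })))
    testIdx <- setdiff(seq_len(nrow(m)), trainIdx)
    if (!length(testIdx)) stop("subsample fraction leaves an empty test set")
    cfg <- config
    cfg$seed <- as.integer(seeds[i] %% 2147483647)
    trLab <- droplevels(labels[trainIdx])
    rk <- rankFeatures(m[trainIdx, , drop = FALSE], trLab, cfg)
    cfg$truncationSize <- min(cfg$truncationSize, nrow(rk))
    tr <- truncateAndRetrain(m[trainIdx, , drop = FALSE], trLab, rk, cfg)
    pred <- stats::predict(tr$model, m[testIdx, tr$retained, drop = FALSE])
    acc[i] <- mean(as.character(pred) == as.character(labels[testIdx]))
    selected[[i]] <- tr$retained
  }
  allSel <- sort(unique(unlist(selected)))
  freq <- vapply(allSel, function(ec)
    mean(vapply(selected, function(s) ec %in% s, logical(1))), numeric(1))
  list(accuracies = acc, selectionFrequency = freq)
}

#' Embed samples by local Fisher discriminant analysis
#'
#' Fits the LFDA transform on the truncated feature submatrix and returns the
#' top-2 (by default) discriminant coordinates per sample, the functional
#' clustering view of the treatment groups.
#'
#' @inheritParams rankFeatures
#' @param retained character vector of features to embed on (typically
#'   \code{truncateAndRetrain()$retained}); NULL uses all features
#' @param embeddingRank number of coordinates kept (default 2)
#' @param knn within-class neighbor index for the local-scaling affinity
#'   (default 7)
#' @return data.frame with \code{sample_id}, \code{LFDA1}, \code{LFDA2}, ...,
#'   \code{class_label}
#' @export
lfdaEmbed <- function(x, labels, retained = NULL, embeddingRank = 2L,
                      knn = 7L) {
  m <- .sampleMatrix(x)
  labels <- .checkDiscriminantInput(m, labels)
  if (!is.null(retained)) {
    if (!all(retained %in% colnames(m)))
      stop("retained features absent from the matrix")
    m <- m[, retained, drop = FALSE]
  }
  fit <- .lfda(m, labels, r = embeddingRank, knn = knn)
  z <- sweep(m, 2, fit$center) %*% fit$transform
  if (any(!is.finite(z))) stop("non-finite embedding coordinates")
  out <- data.frame(sample_id = rownames(m), z,
                    class_label = as.character(labels),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "eigenvalues") <- fit$eigenvalues
  out
}

#' Aggregate feature importance onto KEGG pathways
#'
#' Each ranked EC contributes its importance to each of its (at most 5)
#' annotated pathways, mirroring the full-count regrouping policy of the
#' profiling stage. When the abundance matrix and labels are supplied,
#' importances are signed relative to the control class: positive when the
#' EC's mean abundance is higher under treatment than control, so the control
#' baseline sits at 0.
#'
#' @param ranking data.frame from [rankFeatures()] (typically already
#'   truncated to the retained features)
#' @param ecToPathways named list EC -> ordered pathway ids
#' @param x,labels optional abundance matrix and class labels used to sign
#'   the importances
#' @param controlLabel label of the reference class (default: first factor
#'   level of \code{labels})
#' @return data.frame with \code{pathway} and summed \code{importance},
#'   sorted by decreasing absolute importance
#' @export
pathwayImportance <- function(ranking, ecToPathways, x = NULL, labels = NULL,
                              controlLabel = NULL) {
  if (!nrow(ranking)) stop("empty ranking")
  imp <- stats::setNames(ranking$importance, ranking$ec_id)
  if (!is.null(x) && !is.null(labels)) {
    m <- .sampleMatrix(x)
    labels <- as.factor(as.character(labels))
    if (is.null(controlLabel)) controlLabel <- levels(labels)[1]
    trt <- levels(labels)[levels(labels) != controlLabel][1]
    present <- intersect(names(imp), colnames(m))
    delta <- colMeans(m[labels == trt, present, drop = FALSE]) -
      colMeans(m[labels == controlLabel, present, drop = FALSE])
    imp[present] <- imp[present] * sign(delta)
  }
  rows <- lapply(names(imp), function(ec) {
    p <- ecToPathways[[ec]]
    if (is.null(p) || !length(p)) return(NULL)
    data.frame(pathway = utils::head(p, 5L), importance = imp[[ec]],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    warning("no ranked EC had a pathway annotation")
    return(data.frame(pathway = character(), importance = numeric()))
  }
  agg <- stats::aggregate(importance ~ pathway, rows, sum)
  agg[order(-abs(agg$importance)), , drop = FALSE]
}
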