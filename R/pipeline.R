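#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates simulate -> profile -> index -> discriminate -> qpcr ->
#' performance -> report over a single configuration. The config is a named
#' list (or a YAML file path) with top-level keys \code{seed}, \code{outDir},
#' \code{stages} (subset of the above, in any order; executed in dependency
#' order) and optional per-stage parameter blocks \code{simulate} (arguments
#' to [simulationConfig()]), \code{discriminate} (arguments to
#' [classifierConfig()]), \code{mpmi} (\code{a}, \code{outlierK}), and
#' \code{performance} (\code{targetBw}). Unknown top-level keys are rejected.
#'
#' Every output TSV carries a provenance header line (package version, seed,
#' config hash); numeric outputs are byte-identical across runs with the same
#' config. Inputs are never mutated; all artifacts go under \code{outDir}.
#'
#' @param config named list or path to a YAML file
#' @return invisibly, the run report: per-stage status, artifact paths,
#'   parameter echo and package version
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "outDir", "stages", "simulate", "discriminate", "mpmi",
             "performance")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) stop("config needs 'outDir'")
            else config$outDir
  allStages <- c("simulate", "profile", "index", "discriminate", "qpcr",
                 "performance", "report")
  stages <- if (is.null(config$stages)) allStages else config$stages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- allStages[allStages %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # hash only the analysis-relevant keys, so runs into different directories
  # with identical parameters share a provenance id
  cfgHash <- substr(.configHash(config[setdiff(names(config), "outDir")]), 1, 12)
  version <- as.character(utils::packageVersion("mpmindex"))
  header <- sprintf("# mpmindex %s seed=%d config=%s", version, seed, cfgHash)
  writeTsv <- function(df, name) {
    path <- file.path(outDir, name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(format(df, trim = TRUE, digits = 12), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  simArgs <- config$simulate
  simArgs$seed <- seed
  simCfg <- do.call(simulationConfig, simArgs)
  catalog <- loadCatalog()
  report <- list(version = version, seed = seed, config_hash = cfgHash,
                 stages = list())
  state <- list()

  for (stage in stages) {
    res <- tryCatch({
      artifacts <- switch(stage,
        simulate = {
          state$sim <- simulateCounts(simCfg, catalog)
          state$qpcr <- simulateQpcr(simCfg, catalog)
          state$pens <- simulatePens(simCfg)
          c(counts = writeTsv(data.frame(sample = rownames(state$sim$counts),
                                         state$sim$counts,
                                         check.names = FALSE), "counts.tsv"),
            pens = writeTsv(state$pens, "pens.tsv"),
            calibration = writeTsv(state$qpcr$calibration, "calibration.tsv"),
            plate = writeTsv(state$qpcr$plate, "plate.tsv"))
        },
        profile = {
          if (is.null(state$sim)) stop("profile stage needs simulate outputs")
          rg <- regroupKoToEc(state$sim$counts, state$sim$koToEc)
          state$ecmat <- normalizeAbundance(rg$counts,
                                             state$sim$normalizationEcs)
          m <- t(assay(state$ecmat, "abundance"))
          c(abundance = writeTsv(data.frame(sample = rownames(m), m,
                                            check.names = FALSE),
                                 "ec_abundance.tsv"))
        },
        index = {
          if (is.null(state$ecmat)) stop("index stage needs profile outputs")
          a <- if (is.null(config$mpmi$a)) 1 else config$mpmi$a
          state$mpmi <- computeMpmi(state$ecmat, catalog, a = a)
          state$mpmi$group <- as.character(state$sim$labels)
          c(mpmi = writeTsv(state$mpmi, "mpmi.tsv"))
        },
        discriminate = {
          if (is.null(state$ecmat)) stop("discriminate stage needs profile outputs")
          dArgs <- config$discriminate
          dArgs$seed <- seed
          dCfg <- do.call(classifierConfig, dArgs)
          rk <- rankFeatures(state$ecmat, state$sim$labels, dCfg)
          tr <- truncateAndRetrain(state$ecmat, state$sim$labels, rk, dCfg)
          emb <- lfdaEmbed(state$ecmat, state$sim$labels, tr$retained)
          state$discriminant <- list(ranking = rk, retained = tr$retained,
                                      embedding = emb)
          c(ranking = writeTsv(rk, "feature_ranking.tsv"),
            retained = writeTsv(data.frame(ec_id = tr$retained),
                                "retained_features.tsv"),
            embedding = writeTsv(emb, "lfda_embedding.tsv"))
        },
        qpcr = {
          if (is.null(state$qpcr)) stop("qpcr stage needs simulate outputs")
          cal <- state$qpcr$calibration
          fits <- lapply(split(cal, cal$marker), fitCalibration,
                         key = "per-marker")
          for (k in names(fits)) fits[[k]]@key <- k
          aTab <- relativeAbundanceTable(state$qpcr$plate, fits)
          aMeans <- averageReplicates(aTab)
          state$qmpmi <- computeQmpmi(aMeans, catalog)
          fitDf <- do.call(rbind, lapply(fits, function(f)
            data.frame(marker = f@key, slope = f@slope,
                       intercept = f@intercept, r_squared = f@rSquared)))
          c(fits = writeTsv(fitDf, "calibration_fits.tsv"),
            abundances = writeTsv(aMeans, "relative_abundances.tsv"),
            qmpmi = writeTsv(state$qmpmi, "qmpmi.tsv"))
        },
        performance = {
          if (is.null(state$pens)) stop("performance stage needs simulate outputs")
          targetBw <- if (is.null(config$performance$targetBw)) 2900
                      else config$performance$targetBw
          pm <- penMetrics(state$pens, targetBw = targetBw)
          state$penMetrics <- pm
          c(pen_metrics = writeTsv(pm, "pen_metrics.tsv"))
        },
        report = {
          txt <- pipelineReport(state)
          path <- file.path(outDir, "summary.md")
          writeLines(c(header, txt), path)
          c(summary = path)
        })
      list(status = "ok", artifacts = as.list(artifacts))
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    report$stages[[stage]] <- res
    if (res$status == "error")
      stop("pipeline stage '", stage, "' failed: ", res$message)
  }
  report$parameters <- list(simulate = unclass(simCfg),
                            mpmi = config$mpmi,
                            discriminate = config$discriminate,
                            performance = config$performance)
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a results bundle
#'
#' Renders a markdown summary of whichever analysis outputs are present in
#' the bundle: MPMI group medians with rank-test p-values, qMPMI by group,
#' and the growth-performance table with percent improvements (computed by
#' [percentImprovement()]). Sections whose inputs are absent are omitted; an
#' empty bundle is an error.
#'
#' @param bundle named list with any of \code{mpmi} (data.frame with a
#'   \code{group} column), \code{qmpmi}, \code{penMetrics}
#' @return character vector of markdown lines
#' @export
pipelineReport <- function(bundle) {
  sections <- character()
  if (!is.null(bundle$mpmi)) {
    m <- bundle$mpmi[!bundle$mpmi$flagged, ]
    med <- tapply(m$mpmi, m$group, stats::median)
    cmp <- compareGroups(m$mpmi, m$group)
    sections <- c(sections, "## MPMI", "",
                  sprintf("- median MPMI [%s]: %.2f", names(med), med),
                  sprintf("- %s p = %.4g", cmp$test_name, cmp$p_value), "")
  }
  if (!is.null(bundle$qmpmi)) {
    q <- bundle$qmpmi[!bundle$qmpmi$flagged, ]
    grp <- sub("_.*$", "", q$sample)
    med <- tapply(q$qmpmi, grp, stats::median)
    sections <- c(sections, "## qMPMI", "",
                  sprintf("- median qMPMI [%s]: %.4g", names(med), med), "")
  }
  if (!is.null(bundle$penMetrics)) {
    pm <- bundle$penMetrics
    mean_ <- function(v) tapply(v, pm$treatment, mean)
    bwg <- mean_(pm$bwg); cfcr <- mean_(pm$cfcr); ep <- mean_(pm$epef)
    trts <- names(bwg)
    ctl <- trts[1]; trt <- trts[length(trts)]
    sections <- c(sections, "## Growth performance", "",
      sprintf("- BWG [%s]: %.0f g", trts, bwg),
      sprintf("- cFCR [%s]: %.3f", trts, cfcr),
      sprintf("- EPEF [%s]: %.0f", trts, ep),
      sprintf("- BWG improvement: %.1f%%",
              percentImprovement(bwg[[ctl]], bwg[[trt]])),
      sprintf("- cFCR improvement: %.1f%%",
              percentImprovement(cfcr[[ctl]], cfcr[[trt]],
                                 betterIsLower = TRUE)),
      sprintf("- EPEF improvement: %.1f%%",
              percentImprovement(ep[[ctl]], ep[[trt]])), "")
  }
  if (!length(sections)) stop("empty results bundle: nothing to report")
  c("# mpmindex run summary", "", sections)
}
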