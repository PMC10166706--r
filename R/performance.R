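#' Per-pen growth-performance metrics
#'
#' From pen records over the 0-42 d grow-out computes, per bird: body weight
#' gain (BWG = BW42 - BW0), average daily gain (ADG = BWG / 42), feed intake,
#' the mortality-corrected feed conversion ratio, the target-BW-corrected FCR
#' (cFCR), livability, and the European Poultry Efficiency Factor.
#'
#' Mortality correction credits the gain of dead birds to the denominator of
#' the FCR: at their recorded removal weight when \code{removal_wt_sum} is
#' present, otherwise at half the pen's per-bird gain (linear-interpolation
#' assumption: deaths occur uniformly over the phase). The target-BW
#' correction is linear, \code{cFCR = FCR + fcrCorrectionPerG * (targetBw -
#' meanBw42)}; the default coefficient of 0 leaves cFCR = mortality-corrected
#' FCR, since no universally agreed coefficient exists across strains.
#'
#' @param pens data.frame with columns \code{pen}, \code{treatment},
#'   \code{n0} (birds placed), \code{bw0}, \code{bw42} (per-bird g),
#'   \code{fi_total} (pen feed intake, g), \code{mortality} (dead birds);
#'   optional \code{block}, \code{bw10}, \code{bw24}, \code{removal_wt_sum}
#' @param targetBw strain target body weight at d 42, g
#' @param fcrCorrectionPerG FCR points added per gram below target (default 0)
#' @param days phase length in days (default 42)
#' @return data.frame, one row per pen, with columns \code{bwg}, \code{adg},
#'   \code{fi_per_bird}, \code{fcr}, \code{cfcr}, \code{livability},
#'   \code{epef} alongside the pen identifiers
#' @export
penMetrics <- function(pens, targetBw = 2900, fcrCorrectionPerG = 0,
                       days = 42) {
  need <- c("pen", "treatment", "n0", "bw0", "bw42", "fi_total", "mortality")
  miss <- setdiff(need, colnames(pens))
  if (length(miss))
    stop("pen table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(pens$bw42)) || any(!is.finite(pens$bw0)))
    stop("missing body weights")
  if (any(pens$fi_total <= 0)) stop("feed intake must be positive")
  if (any(pens$mortality > pens$n0)) stop("mortality exceeds birds placed")
  gainPerBird <- pens$bw42 - pens$bw0
  alive <- pens$n0 - pens$mortality
  deadGain <- if ("removal_wt_sum" %in% colnames(pens) &&
                  !all(is.na(pens$removal_wt_sum))) {
    ifelse(is.na(pens$removal_wt_sum), pens$mortality * gainPerBird / 2,
           pens$removal_wt_sum - pens$mortality * pens$bw0)
  } else {
    pens$mortality * gainPerBird / 2
  }
  totalGain <- alive * gainPerBird + deadGain
  fcr <- pens$fi_total / totalGain
  cfcr <- fcr + fcrCorrectionPerG * (targetBw - pens$bw42)
  livability <- 100 * alive / pens$n0
  adg <- gainPerBird / days
  out <- data.frame(pen = pens$pen, treatment = pens$treatment,
                    bwg = gainPerBird, adg = adg,
                    fi_per_bird = pens$fi_total / pens$n0,
                    fcr = fcr, cfcr = cfcr, livability = livability,
                    stringsAsFactors = FALSE)
  if ("block" %in% colnames(pens)) out$block <- pens$block
  out$epef <- mapply(epef, adg, cfcr, livability)
  out
}

#' European Poultry Efficiency Factor
#'
#' \deqn{EPEF = ADG / (FCR_{mc} \times 10) \times livability}
#' with ADG in g/day, the mortality-corrected feed conversion ratio, and
#' livability in percent (100 - mortality\%). Homogeneous of degree 1 in ADG
#' and livability and of degree -1 in FCR.
#'
#' @param adg average daily gain, g/bird/day
#' @param mcFcr mortality-corrected feed conversion ratio
#' @param livabilityPct percent of placed birds alive at the end of the phase
#' @return the efficiency factor (dimensionless)
#' @examples
#' epef(60, 2, 100)   # 300
#' @export
epef <- function(adg, mcFcr, livabilityPct) {
  if (any(adg <= 0) || any(livabilityPct <= 0) || livabilityPct > 100)
    stop("adg must be positive and livability in (0, 100]")
  if (any(mcFcr <= 0)) stop("FCR must be positive")
  adg / (mcFcr * 10) * livabilityPct
}

#' Percent improvement of a treatment over control
#'
#' For metrics where lower is better (FCR), improvement is
#' \code{100 * (control - treated) / control}; for higher-is-better metrics
#' (BWG, EPEF), \code{100 * (treated - control) / control}.
#'
#' @param control,treated group means
#' @param betterIsLower TRUE for FCR-like metrics
#' @return signed percent improvement
#' @examples
#' percentImprovement(1.855, 1.786, betterIsLower = TRUE)  # ~3.7
#' @export
percentImprovement <- function(control, treated, betterIsLower = FALSE) {
  if (any(control == 0)) stop("zero control value")
  if (betterIsLower) 100 * (control - treated) / control
  else 100 * (treated - control) / control
}

#' One-way ANOVA on pen means
#'
#' Treatment contrast with pen as the experimental unit; an optional block
#' term absorbs the randomized-block structure. The reported SEM is the
#' pooled residual standard error of a treatment mean,
#' \eqn{\sqrt{MSE / n}} at the smallest per-treatment pen count.
#'
#' @param values per-pen metric (e.g. \code{penMetrics()$bwg})
#' @param treatment treatment labels, one per pen
#' @param block optional block labels
#' @return list with \code{f_statistic}, \code{p_value}, \code{means} (named
#'   per-treatment means), \code{sem}, and the fitted \code{aov} object
#' @export
treatmentAnova <- function(values, treatment, block = NULL) {
  treatment <- as.factor(treatment)
  if (any(table(treatment) < 2L))
    stop("each treatment needs at least 2 pens")
  df <- data.frame(y = values, treatment = treatment)
  if (!is.null(block)) {
    df$block <- as.factor(block)
    fit <- stats::aov(y ~ block + treatment, df)
  } else {
    fit <- stats::aov(y ~ treatment, df)
  }
  tab <- summary(fit)[[1]]
  i <- grep("^treatment", trimws(rownames(tab)))
  mse <- tab["Residuals", "Mean Sq"]
  list(f_statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"],
       means = tapply(values, treatment, mean),
       sem = sqrt(mse / min(table(treatment))),
       fit = fit)
}

#' Read a pen-record TSV
#'
#' Schema: \code{pen  treatment  block  n0  bw0  bw10  bw24  bw42  fi_total
#' mortality  removal_wt_sum} (trailing columns optional).
#'
#' @param path TSV path
#' @return data.frame of pen records
#' @export
readPens <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pen", "treatment", "n0", "bw0", "bw42", "fi_total", "mortality")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("pen TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}
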