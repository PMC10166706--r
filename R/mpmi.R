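#' Compute the Microbiome Protein Metabolism Index
#'
#' For each sample, MPMI = 100 * a * (sum of weighted normalized abundances
#' over numerator reactions) / (sum over denominator reactions), where the
#' numerator reactions capture favorable microbial protein assimilation and
#' the denominator reactions capture putrefactive protein fermentation. With
#' the default stoichiometric constant \code{a = 1} and unit per-reaction
#' weights, an index of 100 marks the balance point between the two sums.
#'
#' Catalog reactions absent from the matrix contribute 0 and are listed in
#' the \code{coverage} attribute; a sample with zero denominator abundance is
#' flagged (\code{excluded_as_outlier} stays FALSE, \code{mpmi} is NA) rather
#' than dropped.
#'
#' @param x an \linkS4class{ECAbundanceMatrix} or samples-by-EC matrix
#' @param catalog a \linkS4class{MarkerCatalog}
#' @param a stoichiometric normalization constant (default 1)
#' @return data.frame with columns \code{sample_id}, \code{numerator_sum},
#'   \code{denominator_sum}, \code{mpmi}, \code{flagged}; attribute
#'   \code{coverage} lists catalog ECs missing from the matrix
#' @examples
#' cat22 <- loadCatalog()
#' m <- matrix(1, 1, 22, dimnames = list("s1", markerTable(cat22)$ec_number))
#' computeMpmi(m, cat22)$mpmi  # balanced sums at unit weights -> depends on set sizes
#' @export
computeMpmi <- function(x, catalog, a = 1) {
  stopifnot(a > 0)
  m <- .sampleMatrix(x)
  mk <- markerTable(catalog)
  w <- stats::setNames(mk$stoich_weight, mk$ec_number)
  sumSide <- function(ecs) {
    present <- intersect(ecs, colnames(m))
    if (!length(present)) return(rep(0, nrow(m)))
    as.numeric(m[, present, drop = FALSE] %*% w[present])
  }
  num <- sumSide(numeratorSet(catalog))
  den <- sumSide(denominatorSet(catalog))
  flagged <- den <= 0
  mpmi <- ifelse(flagged, NA_real_, 100 * a * num / den)
  out <- data.frame(sample_id = rownames(m), numerator_sum = num,
                    denominator_sum = den, mpmi = mpmi, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- list(
    missing = setdiff(mk$ec_number, colnames(m)),
    n_present = length(intersect(mk$ec_number, colnames(m))))
  out
}

#' Exclude outliers by quartile fences
#'
#' Excludes values outside \eqn{[Q1 - k \cdot IQR, Q3 + k \cdot IQR]} with
#' \code{k = 2} by default (a wide Tukey fence). Quartiles use the
#' linear-interpolation convention (\code{stats::quantile} type 7). The
#' alternative reading of "outside twice the interquartile range" — a fence
#' of half-width \code{k * IQR} centered on the median — is available via
#' \code{method = "median"}.
#'
#' With fewer than 4 values no exclusion is attempted (warning).
#'
#' @param values numeric vector
#' @param k fence multiplier (default 2); \code{Inf} keeps everything
#' @param method \code{"tukey"} (quartile-anchored, default) or
#'   \code{"median"} (median-centered)
#' @return list with \code{kept}, \code{excluded}, and the logical
#'   \code{keep} mask
#' @export
excludeOutliers <- function(values, k = 2, method = c("tukey", "median")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outlier exclusion performed")
    return(list(kept = values, excluded = numeric(), keep = rep(TRUE, length(values))))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  fence <- if (method == "tukey") c(q[1] - k * iqr, q[3] + k * iqr)
           else c(q[2] - k * iqr, q[2] + k * iqr)
  keep <- if (is.infinite(k)) rep(TRUE, length(values))
          else values >= fence[1] & values <= fence[2]
  list(kept = values[keep], excluded = values[!keep], keep = keep)
}

#' Nonparametric group comparison
#'
#' Two groups are compared by the two-sided Wilcoxon rank-sum (Mann-Whitney
#' U) test; three or more by the Kruskal-Wallis rank test. The exact
#' small-sample null is used when both groups have at most 8 observations
#' and no ties; otherwise the normal approximation with tie correction.
#'
#' @param values numeric vector of observations
#' @param groups group labels, same length as \code{values}
#' @return data.frame with \code{test_name}, \code{statistic}, \code{p_value}
#'   and the group labels compared
#' @examples
#' compareGroups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
compareGroups <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 values")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nlevels(groups) == 2) {
    va <- values[groups == levels(groups)[1]]
    vb <- values[groups == levels(groups)[2]]
    exact <- length(va) <= 8 && length(vb) <= 8 &&
      !anyDuplicated(c(va, vb))
    ht <- stats::wilcox.test(va, vb, alternative = "two.sided", exact = exact,
                             correct = !exact)
    data.frame(test_name = "mann_whitney",
               group_a = levels(groups)[1], group_b = levels(groups)[2],
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  } else {
    ht <- stats::kruskal.test(values, groups)
    data.frame(test_name = "kruskal_wallis",
               group_a = levels(groups)[1],
               group_b = levels(groups)[nlevels(groups)],
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  }
}

#' Split samples into Low/High body-weight cohorts
#'
#' \code{mode = "mean"}: birds below the mean weight are Low, above are High;
#' a weight exactly at the mean goes to the side named by \code{tie}
#' (default Low). \code{mode = "10pct"} reproduces the ex vivo cohort rule:
#' at most 90\% of the mean is Low, at least 110\% is High, and weights in
#' between are unlabeled (NA).
#'
#' @param weights positive numeric bird weights
#' @param mode \code{"mean"} or \code{"10pct"}
#' @param tie side receiving weights exactly at the mean under
#'   \code{mode = "mean"} (\code{"Low"} or \code{"High"})
#' @return factor with levels Low/High (NA where unlabeled)
#' @export
cohortSplit <- function(weights, mode = c("mean", "10pct"),
                        tie = c("Low", "High")) {
  mode <- match.arg(mode)
  tie <- match.arg(tie)
  if (!length(weights)) stop("empty weight vector")
  if (any(weights <= 0)) stop("weights must be positive")
  mu <- mean(weights)
  lab <- rep(NA_character_, length(weights))
  if (mode == "mean") {
    lab[weights < mu] <- "Low"
    lab[weights > mu] <- "High"
    lab[weights == mu] <- tie
  } else {
    lab[weights <= 0.9 * mu] <- "Low"
    lab[weights >= 1.1 * mu] <- "High"
  }
  factor(lab, levels = c("Low", "High"))
}
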