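#' Local Fisher discriminant analysis
#'
#' Supervised linear embedding that maximizes local between-class scatter
#' relative to local within-class scatter, where "local" weights come from a
#' local-scaling affinity: the kernel width of sample i is its distance to
#' its \code{knn}-th nearest within-class neighbor. Unlike classical Fisher
#' discriminant analysis the embedding is not limited to (classes - 1)
#' dimensions and preserves multimodal within-class structure.
#'
#' The transform solves the generalized eigenproblem
#' \eqn{S^{(lb)} v = \lambda S^{(lw)} v} on the local between/within scatter
#' matrices; the within-scatter is ridge-regularized before inversion so
#' rank-deficient (wide) feature submatrices remain usable.
#'
#' @param x samples-by-features numeric matrix
#' @param labels class labels, length \code{nrow(x)}
#' @param r embedding dimension (default 2)
#' @param knn neighbor index used for local scaling (default 7)
#' @param reg ridge added to the within-class scatter, as a fraction of its
#'   mean diagonal (default 1e-6)
#' @return list with \code{transform} (features-by-r matrix), \code{center}
#'   (feature means), \code{eigenvalues}
#' @keywords internal
.lfda <- function(x, labels, r = 2L, knn = 7L, reg = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("LFDA needs at least 2 classes")
  if (n < r + 1L) stop("need more samples than embedding dimensions")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)

  Wlw <- matrix(0, n, n)
  Wlb <- matrix(1 / n, n, n)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    nc <- length(idx)
    xi <- xc[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(xi))^2
    # local scaling: sigma_i = distance to the knn-th within-class neighbor
    kEff <- max(1L, min(knn, nc - 1L))
    sigma <- apply(d2, 1, function(row) sqrt(sort(row)[kEff + 1L]))
    sigma[sigma == 0] <- 1
    aff <- exp(-d2 / outer(sigma, sigma))
    Wlw[idx, idx] <- aff / nc
    Wlb[idx, idx] <- aff * (1 / n - 1 / nc)
  }
  scatter <- function(W) {
    L <- diag(rowSums(W)) - W
    crossprod(xc, L %*% xc)
  }
  Slw <- scatter(Wlw)
  Slb <- scatter(Wlb)
  ridge <- reg * mean(diag(Slw)) + 1e-12
  ev <- eigen(solve(Slw + diag(ridge, ncol(xc)), Slb))
  ord <- order(Re(ev$values), decreasing = TRUE)
  V <- Re(ev$vectors[, ord[seq_len(r)], drop = FALSE])
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  dimnames(V) <- list(colnames(x), paste0("LFDA", seq_len(r)))
  list(transform = V, center = center,
       eigenvalues = Re(ev$values[ord[seq_len(r)]]))
}
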