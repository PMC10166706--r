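# Shared fixtures, all built in code.

theCatalog <- loadCatalog()

# One-sample abundance matrix whose weighted numerator and denominator sums
# are equal: every N reaction gets 1/nN, every D reaction 1/nD.
balancedSampleMatrix <- function(catalog = theCatalog) {
  ns <- numeratorSet(catalog)
  ds <- denominatorSet(catalog)
  m <- matrix(c(rep(1 / length(ns), length(ns)),
                rep(1 / length(ds), length(ds))),
              nrow = 1, dimnames = list("s1", c(ns, ds)))
  m
}

# Independent MPMI oracle: plain loops over the catalog table, no shared code
# with computeMpmi().
oracleMpmi <- function(m, catalog, a = 1) {
  tab <- as.data.frame(markerTable(catalog))
  vapply(seq_len(nrow(m)), function(s) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(tab))) {
      ec <- tab$ec_number[i]
      if (!ec %in% colnames(m)) next
      v <- tab$stoich_weight[i] * m[s, ec]
      if (tab$role[i] == "N") num <- num + v else den <- den + v
    }
    100 * a * num / den
  }, numeric(1))
}

# A small normalized matrix derived from simulated counts.
simulatedEcMatrix <- function(seed = 1, n = 8, nEc = 80, fold = 1) {
  sim <- simulateCounts(simulationConfig(seed = seed, nSamplesPerGroup = n,
                                         nEc = nEc, markerEffectFold = fold))
  rg <- regroupKoToEc(sim$counts, sim$koToEc)
  list(ecmat = normalizeAbundance(rg$counts, sim$normalizationEcs),
       labels = sim$labels, sim = sim)
}

meanSilhouette <- function(emb) {
  d <- dist(emb[, grep("^LFDA", colnames(emb))])
  mean(cluster::silhouette(as.integer(factor(emb$class_label)), d)[, 3])
}
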