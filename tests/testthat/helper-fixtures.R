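# Shared fixtures, built in code.

# Small labelled count experiment with deterministic values.
makeTinyExperiment <- function(nGenes = 6, nNormal = 5, nDisease = 4,
                               seed = 11) {
  withr::local_seed(seed)
  n <- nNormal + nDisease
  m <- matrix(rpois(nGenes * n, lambda = 60), nGenes, n,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n))))
  lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(nNormal, nDisease)),
                              colnames(m)), "Normal")
  GSNExperiment(m, lab)
}

# All gene pairs of an experiment as a two-column data.frame.
allGenePairs <- function(gse) {
  g <- rownames(gse)
  p <- t(combn(g, 2))
  data.frame(geneA = p[, 1], geneB = p[, 2])
}

# Hand-rolled SampleNetwork with given edges (already significant).
makeSSN <- function(sampleId, geneA, geneB, deltaPCC,
                    pValue = rep(0.01, length(geneA)), alpha = 0.05,
                    nRef = 10L) {
  new("SampleNetwork", sampleId = sampleId,
      edges = data.frame(geneA = geneA, geneB = geneB,
                         deltaPCC = deltaPCC, pValue = pValue),
      alpha = alpha, nRef = as.integer(nRef))
}

emptySSN <- function(sampleId, alpha = 0.05, nRef = 10L) {
  makeSSN(sampleId, character(), character(), numeric(), numeric(),
          alpha = alpha, nRef = nRef)
}

makeGSN <- function(group, geneA, geneB, weight, nSamples = 3L) {
  new("GroupNetwork", group = group, nSamples = as.integer(nSamples),
      edges = data.frame(geneA = geneA, geneB = geneB, weight = weight))
}

# Feature matrix with groups, direct construction.
makeFeatureMatrix <- function(values, groups) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  new("EdgeFeatureMatrix", values = values, groups = factor(groups))
}

# The published per-threshold F1/CBR tables shipped with the package.
readThresholdTables <- function() {
  path <- system.file("extdata", "threshold_tables.tsv",
                      package = "gsnSelect")
  read.delim(path, stringsAsFactors = FALSE)
}
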