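# Per-sample differential-correlation networks.
#
# The reference network holds pairwise Pearson correlations (PCC_n) over
# the reference (normal) cohort for a fixed pair set.  Adding one disease
# sample and recomputing gives PCC_{n+1}; the edge statistic is
# deltaPCC = PCC_{n+1} - PCC_n.  Correlations are computed from running
# sums on reference-mean-centered data, which makes appending one sample
# an O(1)-per-pair update and keeps the arithmetic numerically equivalent
# to a from-scratch computation on the concatenated matrix.

# Precompute centered sums for a pair set.  X: genes x nRef matrix
# (reference samples); ia/ib: row indices of the paired genes.
.refSums <- function(X, ia, ib) {
  mu <- rowMeans(X)
  Xc <- X - mu
  list(n = ncol(X), mu = unname(mu),
       sa = unname(rowSums(Xc[ia, , drop = FALSE])),
       sb = unname(rowSums(Xc[ib, , drop = FALSE])),
       saa = unname(rowSums(Xc[ia, , drop = FALSE]^2)),
       sbb = unname(rowSums(Xc[ib, , drop = FALSE]^2)),
       sab = unname(rowSums(Xc[ia, , drop = FALSE] * Xc[ib, , drop = FALSE])),
       ia = ia, ib = ib)
}

# Pearson correlation from sums of (arbitrarily centered) data.
.pccFromSums <- function(n, sa, sb, saa, sbb, sab) {
  num <- n * sab - sa * sb
  den2 <- (n * saa - sa^2) * (n * sbb - sb^2)
  out <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  pmin(pmax(out, -1), 1)
}

# PCC_{n+1} for one appended sample, vectorized over the pair set.
# x: the sample's expression vector over all genes (same row order as X).
.augmentedPCC <- function(rs, x) {
  xc <- unname(x) - rs$mu
  u <- xc[rs$ia]
  v <- xc[rs$ib]
  .pccFromSums(rs$n + 1, rs$sa + u, rs$sb + v,
               rs$saa + u^2, rs$sbb + v^2, rs$sab + u * v)
}

# p-value of deltaPCC given the reference correlation r0 over n samples.
.deltaPValue <- function(delta, r0, n, nullModel) {
  z <- delta * (n - 1) / pmax(1 - r0^2, .Machine$double.eps)
  if (nullModel == "gaussian") 2 * stats::pnorm(-abs(z))
  else .pProductNormal(z)
}

.exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' Build the reference correlation network
#'
#' Computes pairwise gene-gene Pearson correlations over the reference
#' (normal) samples for a fixed set of gene pairs --- in practice the PPI
#' edge set, since only PPI edges survive downstream.  Pairs involving a
#' zero-variance gene are recorded as undefined (`NA`) with a warning and
#' excluded downstream.
#'
#' @param gse A [GSNExperiment-class].
#' @param pairs Pair set: a [PPINetwork-class], a two-column
#'   data.frame/matrix of gene identifiers, or a character vector of
#'   `"geneA|geneB"` keys.  Pairs with genes absent from `gse` are dropped.
#' @return A [ReferenceNetwork-class].
#' @examples
#' sim <- simulateGSNData(simulationSpec(nGenes = 10,
#'   groupSizes = c(Normal = 10, A = 5)), seed = 1)
#' ref <- buildReferenceNetwork(sim$experiment, sim$ppi)
#' head(networkEdges(ref))
#' @export
buildReferenceNetwork <- function(gse, pairs) {
  stopifnot(is(gse, "GSNExperiment"))
  refIds <- referenceSamples(gse)
  if (length(refIds) < 3L)
    stop("reference group needs >= 3 samples, found ", length(refIds))
  p <- .asPairs(pairs)
  p <- p[p$geneA %in% rownames(gse) & p$geneB %in% rownames(gse), ,
         drop = FALSE]
  if (!nrow(p)) stop("no pairs left after restricting to genes in the matrix")
  X <- .exprMatrix(gse)[, refIds, drop = FALSE]
  ia <- match(p$geneA, rownames(X)); ib <- match(p$geneB, rownames(X))
  rs <- .refSums(X, ia, ib)
  pcc <- .pccFromSums(rs$n, rs$sa, rs$sb, rs$saa, rs$sbb, rs$sab)
  if (anyNA(pcc))
    warning(sum(is.na(pcc)),
            " pair(s) with zero variance in the reference excluded")
  new("ReferenceNetwork", nRef = length(refIds),
      edges = data.frame(geneA = p$geneA, geneB = p$geneB, pcc = pcc,
                         row.names = NULL))
}

#' Perturbed correlation after adding one sample
#'
#' Returns `PCC_{n+1}`, the Pearson correlation over the reference samples
#' plus the given (non-reference) sample, for each pair of the reference
#' network.
#'
#' @param ref A [ReferenceNetwork-class] built on `gse`.
#' @param gse The [GSNExperiment-class] that `ref` was built from.
#' @param sample A non-reference sample identifier.
#' @return Numeric vector of perturbed correlations aligned with
#'   `networkEdges(ref)`; `NA` where undefined.
#' @export
perturbedPCC <- function(ref, gse, sample) {
  stopifnot(is(ref, "ReferenceNetwork"), is(gse, "GSNExperiment"))
  g <- sampleGroups(gse)
  if (!sample %in% names(g)) stop("unknown sample: ", sample)
  if (g[[sample]] == referenceGroup(gse))
    stop("sample '", sample, "' belongs to the reference group; ",
         "perturbation networks are built for non-reference samples only")
  X <- .exprMatrix(gse)
  refIds <- referenceSamples(gse)
  e <- networkEdges(ref)
  ia <- match(e$geneA, rownames(X)); ib <- match(e$geneB, rownames(X))
  rs <- .refSums(X[, refIds, drop = FALSE], ia, ib)
  .augmentedPCC(rs, X[, sample])
}

# Shared worker: SSN edge tables for many samples against one reference.
# Returns a list of data.frames (geneA, geneB, deltaPCC, pValue), one per
# sample, containing significant defined edges only.
.ssnEdgeTables <- function(X, refIds, samples, pairs, alpha, nullModel) {
  ia <- match(pairs$geneA, rownames(X)); ib <- match(pairs$geneB, rownames(X))
  rs <- .refSums(X[, refIds, drop = FALSE], ia, ib)
  r0 <- .pccFromSums(rs$n, rs$sa, rs$sb, rs$saa, rs$sbb, rs$sab)
  lapply(samples, function(s) {
    r1 <- .augmentedPCC(rs, X[, s])
    delta <- r1 - r0
    pv <- .deltaPValue(delta, r0, rs$n, nullModel)
    keep <- which(!is.na(delta) & !is.na(pv) & pv < alpha)
    data.frame(geneA = pairs$geneA[keep], geneB = pairs$geneB[keep],
               deltaPCC = delta[keep], pValue = pv[keep], row.names = NULL)
  })
}

#' Build the sample-specific network of one disease sample
#'
#' For each defined pair, the change in correlation when the sample is
#' appended to the reference cohort is tested against the null of no
#' perturbation; edges with p < `alpha` are retained with their delta-PCC
#' as the edge value.
#'
#' The test statistic is `z = deltaPCC * (n - 1) / (1 - PCC_n^2)`.  Its
#' asymptotic null is the distribution of a product of two independent
#' standard normals, which is the default reference
#' (`nullModel = "product-normal"`); `"gaussian"` applies the classical
#' standard-normal reference instead (anti-conservative in moderate
#' cohorts; see the methods vignette).
#'
#' @param ref A [ReferenceNetwork-class] built on `gse`.
#' @param gse The [GSNExperiment-class] that `ref` was built from.
#' @param sample A non-reference sample identifier.
#' @param alpha Significance level (default 0.05).
#' @param nullModel `"product-normal"` (default) or `"gaussian"`.
#' @return A [SampleNetwork-class] holding the significant edges.
#' @examples
#' sim <- simulateGSNData(simulationSpec(nGenes = 10,
#'   groupSizes = c(Normal = 20, A = 5)), seed = 1)
#' ref <- buildReferenceNetwork(sim$experiment, sim$ppi)
#' buildSSN(ref, sim$experiment, diseaseSamples(sim$experiment)[1])
#' @export
buildSSN <- function(ref, gse, sample, alpha = 0.05,
                     nullModel = c("product-normal", "gaussian")) {
  nullModel <- match.arg(nullModel)
  stopifnot(is(ref, "ReferenceNetwork"), is(gse, "GSNExperiment"))
  g <- sampleGroups(gse)
  if (!sample %in% names(g)) stop("unknown sample: ", sample)
  if (g[[sample]] == referenceGroup(gse))
    stop("SSNs are built for non-reference samples only")
  e <- networkEdges(ref)
  tab <- .ssnEdgeTables(.exprMatrix(gse), referenceSamples(gse), sample,
                        e[, c("geneA", "geneB")], alpha, nullModel)[[1L]]
  new("SampleNetwork", sampleId = sample, edges = tab,
      alpha = alpha, nRef = ref@nRef)
}

#' Build sample-specific networks for many samples at once
#'
#' Efficient batch version of [buildSSN()]: the reference sums are computed
#' once and each sample is an O(pairs) update.
#'
#' @param gse A [GSNExperiment-class].
#' @param pairs Pair set (see [buildReferenceNetwork()]); supplying the PPI
#'   edge set makes the PPI intersection implicit.
#' @param samples Sample identifiers; default all non-reference samples.
#' @param referenceIds Reference sample identifiers to compute the
#'   reference network from; default all reference-group samples.  (Inside
#'   cross-validation, pass the training-fold normals.)
#' @param alpha Significance level (default 0.05).
#' @param nullModel `"product-normal"` (default) or `"gaussian"`.
#' @return Named list of [SampleNetwork-class] objects.
#' @export
buildAllSSNs <- function(gse, pairs, samples = diseaseSamples(gse),
                         referenceIds = referenceSamples(gse),
                         alpha = 0.05,
                         nullModel = c("product-normal", "gaussian")) {
  nullModel <- match.arg(nullModel)
  stopifnot(is(gse, "GSNExperiment"))
  g <- sampleGroups(gse)
  bad <- samples[g[samples] == referenceGroup(gse)]
  if (length(bad))
    stop("reference samples never receive SSNs: ",
         paste(head(bad, 3L), collapse = ", "))
  if (length(referenceIds) < 3L) stop("need >= 3 reference samples")
  p <- .asPairs(pairs)
  p <- p[p$geneA %in% rownames(gse) & p$geneB %in% rownames(gse), ,
         drop = FALSE]
  X <- .exprMatrix(gse)
  tabs <- .ssnEdgeTables(X, referenceIds, samples, p, alpha, nullModel)
  stats::setNames(lapply(seq_along(samples), function(i)
    new("SampleNetwork", sampleId = samples[i], edges = tabs[[i]],
        alpha = alpha, nRef = length(referenceIds))), samples)
}
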