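# Group-specific networks: PPI intersection of per-sample networks and
# group-wise aggregation of delta-PCC edge weights.

#' Restrict a sample network to PPI edges
#'
#' Keeps only the edges of the sample-specific network that are present in
#' the protein-protein interaction network, with their delta-PCC values
#' unchanged.
#'
#' @param ssn A [SampleNetwork-class].
#' @param ppi A [PPINetwork-class].
#' @return A [SampleNetwork-class] restricted to PPI edges.
#' @export
intersectPPI <- function(ssn, ppi) {
  stopifnot(is(ssn, "SampleNetwork"), is(ppi, "PPINetwork"))
  keep <- edgeKeys(ssn) %in% edgeKeys(ppi)
  e <- networkEdges(ssn)[keep, , drop = FALSE]
  rownames(e) <- NULL
  methods::initialize(ssn, edges = e)
}

#' Aggregate per-sample networks into one group-specific network
#'
#' The weight of an edge is the mean of its delta-PCC values over all N
#' samples of the group, counting 0 for samples whose network lacks the
#' edge; edges present in no sample are omitted.  The denominator is
#' always the group size N, never the number of samples carrying the edge.
#'
#' @param ssns List of (PPI-intersected) [SampleNetwork-class] objects, one
#'   per sample of the group.
#' @param group Group name.
#' @return A [GroupNetwork-class].
#' @examples
#' # one SSN carries edge a|b with deltaPCC 0.4, the other lacks it:
#' s1 <- new("SampleNetwork", sampleId = "s1", alpha = 0.05, nRef = 10L,
#'   edges = data.frame(geneA = "a", geneB = "b", deltaPCC = 0.4,
#'                      pValue = 0.01))
#' s2 <- new("SampleNetwork", sampleId = "s2", alpha = 0.05, nRef = 10L,
#'   edges = data.frame(geneA = character(), geneB = character(),
#'                      deltaPCC = numeric(), pValue = numeric()))
#' networkEdges(aggregateGroup(list(s1, s2), "I"))  # weight 0.2
#' @export
aggregateGroup <- function(ssns, group) {
  if (!length(ssns)) stop("empty sample-network list")
  stopifnot(all(vapply(ssns, is, logical(1), "SampleNetwork")))
  n <- length(ssns)
  keys <- unlist(lapply(ssns, edgeKeys), use.names = FALSE)
  delta <- unlist(lapply(ssns, function(s) networkEdges(s)$deltaPCC),
                  use.names = FALSE)
  if (!length(keys)) {
    e <- data.frame(geneA = character(), geneB = character(),
                    weight = numeric())
  } else {
    sums <- rowsum(delta, keys)            # per-edge sum over carriers
    w <- sums[, 1L] / n                    # zero-fill: absent = 0
    pr <- .splitKey(rownames(sums))
    ord <- order(pr$geneA, pr$geneB)
    e <- data.frame(geneA = pr$geneA[ord], geneB = pr$geneB[ord],
                    weight = unname(w[ord]), row.names = NULL)
  }
  new("GroupNetwork", group = as.character(group), nSamples = as.integer(n),
      edges = e)
}

#' Average group networks across cross-validation folds
#'
#' Per edge, the mean of the per-fold weights with 0 substituted for folds
#' lacking the edge.  Used to derive the single reported network per group
#' after fold-wise construction.
#'
#' @param gsns List of [GroupNetwork-class] objects for the same group,
#'   one per fold.
#' @return A [GroupNetwork-class]; `nSamples` is the largest per-fold
#'   sample count (descriptive only).
#' @export
averageFoldGSNs <- function(gsns) {
  if (!length(gsns)) stop("empty group-network list")
  stopifnot(all(vapply(gsns, is, logical(1), "GroupNetwork")))
  grp <- unique(vapply(gsns, function(g) g@group, ""))
  if (length(grp) != 1L)
    stop("all networks must belong to one group, found: ",
         paste(grp, collapse = ", "))
  nf <- length(gsns)
  keys <- unlist(lapply(gsns, edgeKeys), use.names = FALSE)
  w <- unlist(lapply(gsns, function(g) networkEdges(g)$weight),
              use.names = FALSE)
  if (!length(keys)) {
    e <- data.frame(geneA = character(), geneB = character(),
                    weight = numeric())
  } else {
    sums <- rowsum(w, keys)
    pr <- .splitKey(rownames(sums))
    ord <- order(pr$geneA, pr$geneB)
    e <- data.frame(geneA = pr$geneA[ord], geneB = pr$geneB[ord],
                    weight = unname(sums[ord, 1L] / nf), row.names = NULL)
  }
  new("GroupNetwork", group = grp,
      nSamples = max(vapply(gsns, function(g) g@nSamples, 1L)), edges = e)
}

#' Build one group-specific network per non-reference group
#'
#' Partitions the per-sample networks by group and aggregates each
#' partition with [aggregateGroup()].  When `ppi` is supplied the networks
#' are intersected with it first and the output edge sets are asserted to
#' be PPI subsets.
#'
#' @param ssns Named list of [SampleNetwork-class] objects (names =
#'   sample ids).
#' @param groups Factor or named vector of group memberships covering the
#'   samples in `ssns`.
#' @param ppi Optional [PPINetwork-class] to intersect with.
#' @return Named list of [GroupNetwork-class] objects, one per group
#'   present among the samples.
#' @export
buildGroupNetworks <- function(ssns, groups, ppi = NULL) {
  if (!length(ssns)) stop("empty sample-network list")
  ids <- vapply(ssns, function(s) s@sampleId, "")
  grp <- as.character(groups[ids])
  if (anyNA(grp)) stop("missing group for sample(s): ",
                       paste(ids[is.na(grp)][1:3], collapse = ", "))
  if (!is.null(ppi)) ssns <- lapply(ssns, intersectPPI, ppi = ppi)
  parts <- split(ssns, grp)
  out <- stats::setNames(
    lapply(names(parts), function(g) aggregateGroup(parts[[g]], g)),
    names(parts))
  if (!is.null(ppi)) {
    ok <- vapply(out, function(g) all(edgeKeys(g) %in% edgeKeys(ppi)),
                 logical(1))
    stopifnot("group-network edges must be a subset of the PPI" = all(ok))
  }
  out[order(names(out))]
}

#' Write a group network as TSV
#'
#' @param gsn A [GroupNetwork-class].
#' @param path Output path (columns `gene_a`, `gene_b`, `weight`).
#' @return `path`, invisibly.
#' @export
writeGroupNetwork <- function(gsn, path) {
  e <- networkEdges(gsn)
  utils::write.table(
    data.frame(gene_a = e$geneA, gene_b = e$geneB, weight = e$weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
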