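# First selection round: rank group-network edges, assemble the
# samples x edges feature matrix, and keep the top candidates by
# random-forest impurity importance.

#' Top edges of a group network
#'
#' Edges sorted by descending absolute weight (ties broken by
#' lexicographic pair order), truncated to the top `k`.  Ranking by
#' absolute weight keeps strongly *lost* correlations (negative
#' delta-PCC), which are as informative as gained ones; `signed = TRUE`
#' ranks by the signed weight instead.
#'
#' @param gsn A [GroupNetwork-class].
#' @param k Number of edges to keep; all edges if fewer exist.
#' @param signed Rank by signed weight instead of |weight| (default
#'   `FALSE`).
#' @return Character vector of edge keys (`"geneA|geneB"`), best first.
#' @examples
#' g <- new("GroupNetwork", group = "I", nSamples = 3L,
#'   edges = data.frame(geneA = c("a", "b", "c"), geneB = c("b", "c", "d"),
#'                      weight = c(0.5, -0.7, 0.1)))
#' rankEdges(g, 2)  # "b|c" then "a|b"
#' @export
rankEdges <- function(gsn, k, signed = FALSE) {
  stopifnot(is(gsn, "GroupNetwork"), k >= 1)
  e <- networkEdges(gsn)
  score <- if (signed) e$weight else abs(e$weight)
  ord <- order(-score, e$geneA, e$geneB)
  .pairKey(e$geneA, e$geneB)[ord][seq_len(min(k, nrow(e)))]
}

#' Candidate edge set across groups
#'
#' Union of the top-`k` edges of each group network, deduplicated; the
#' order is deterministic (groups in list order, then rank, first
#' occurrence kept).
#'
#' @param gsns List of [GroupNetwork-class] objects, one per group.
#' @param k Edges taken per group (default 50).
#' @param signed Passed to [rankEdges()].
#' @return Character vector of candidate edge keys.
#' @export
buildCandidateSet <- function(gsns, k = 50L, signed = FALSE) {
  stopifnot(length(gsns) >= 1L)
  unique(unlist(lapply(gsns, rankEdges, k = k, signed = signed),
                use.names = FALSE))
}

#' Assemble the samples x candidate-edge feature matrix
#'
#' The value of (sample, edge) is the sample's significant delta-PCC for
#' that edge, or 0 when the edge is absent from the sample's network
#' (mirroring the zero-fill used in group aggregation).  Reference-group
#' samples are excluded unless `includeReference = TRUE` --- the classifier
#' discriminates among the non-reference groups.
#'
#' @param candidates Character vector of edge keys.
#' @param ssns Named list of (PPI-intersected) [SampleNetwork-class]
#'   objects.
#' @param groups Named vector/factor of group memberships covering the
#'   samples.
#' @param referenceGroup Reference group name (its samples are dropped by
#'   default); `NULL` to keep all samples.
#' @param includeReference Keep reference samples as a class
#'   (default `FALSE`).
#' @return An [EdgeFeatureMatrix-class].
#' @export
buildEdgeFeatures <- function(candidates, ssns, groups,
                              referenceGroup = NULL,
                              includeReference = FALSE) {
  stopifnot(length(candidates) >= 1L, length(ssns) >= 1L)
  ids <- unname(vapply(ssns, function(s) s@sampleId, ""))
  grp <- as.character(groups[ids])
  if (anyNA(grp)) stop("missing group for sample(s): ",
                       paste(ids[is.na(grp)][1:3], collapse = ", "))
  if (!is.null(referenceGroup) && !includeReference) {
    keep <- grp != referenceGroup
    ssns <- ssns[keep]; ids <- ids[keep]; grp <- grp[keep]
  }
  vals <- matrix(0, nrow = length(ssns), ncol = length(candidates),
                 dimnames = list(ids, candidates))
  for (i in seq_along(ssns)) {
    e <- networkEdges(ssns[[i]])
    hit <- match(.pairKey(e$geneA, e$geneB), candidates)
    ok <- !is.na(hit)
    vals[i, hit[ok]] <- e$deltaPCC[ok]
  }
  new("EdgeFeatureMatrix", values = vals, groups = factor(grp))
}

#' Gini impurity of a class-proportion vector
#'
#' `Gini = 1 - sum(p_i^2)`: zero for a pure node, maximal
#' (`1 - 1/n` for `n` classes) for uniform proportions.
#'
#' @param p Non-negative class proportions summing to 1 (within 1e-9).
#' @return The Gini impurity.
#' @examples
#' giniImpurity(c(1, 0))        # 0
#' giniImpurity(c(0.5, 0.5))    # 0.5
#' @export
giniImpurity <- function(p) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  1 - sum(p^2)
}

#' Impurity gain of a binary split
#'
#' The size-weighted improvement in Gini purity when a parent node with
#' class counts `parent` is split into children with counts `left` and
#' `right`:
#' `|L|/|D| * (Gini - Gini_L) + |R|/|D| * (Gini - Gini_R)`,
#' algebraically the parent impurity minus the size-weighted child
#' impurity.  Non-negative for every valid split.
#'
#' @param parent,left,right Non-negative class-count vectors with
#'   `left + right == parent` elementwise.
#' @return The impurity gain.
#' @examples
#' impurityGain(c(6, 4), c(4, 1), c(2, 3))  # 0.08
#' @export
impurityGain <- function(parent, left, right) {
  if (length(left) != length(parent) || length(right) != length(parent) ||
      any(left + right != parent))
    stop("child class counts must sum to the parent counts")
  if (any(parent < 0)) stop("counts must be non-negative")
  n <- sum(parent); nl <- sum(left); nr <- sum(right)
  if (n == 0) stop("parent node is empty")
  g <- giniImpurity(parent / n)
  gl <- if (nl > 0) giniImpurity(left / nl) else 0
  gr <- if (nr > 0) giniImpurity(right / nr) else 0
  nl / n * (g - gl) + nr / n * (g - gr)
}

# Feature matrices carry edge keys like "a|b"; keep them verbatim as
# data.frame column names so importances and predictions match by key.
.asForestData <- function(vals) {
  df <- as.data.frame(vals, optional = TRUE)
  colnames(df) <- colnames(vals)
  df
}

# Fit one random forest on a feature matrix; shared by screening,
# RFECV scoring, and test-fold prediction.
.fitForest <- function(vals, y, nTrees, seed, importance = FALSE, ...) {
  ranger::ranger(
    x = .asForestData(vals), y = y, num.trees = nTrees,
    importance = if (importance) "impurity" else "none",
    num.threads = 1L, seed = as.integer(seed %% 2147483647), ...)
}

#' Pre-screen candidate edges by random-forest Gini importance
#'
#' Trains a random-forest ensemble on the feature matrix and ranks the
#' candidate edges by impurity importance: the total Gini impurity gain
#' accumulated over every node split on the feature, across all trees
#' (reported per sample, i.e. divided by the number of training samples).
#' The top `k` features are retained; ties break lexicographically.
#'
#' @param fm An [EdgeFeatureMatrix-class] with >= 2 groups represented.
#' @param k Number of features to retain (default 50; all if fewer).
#' @param nTrees Trees in the ensemble (default 200).
#' @param seed RNG seed for the forest (default 1).
#' @param ... Further arguments for [ranger::ranger()] (e.g. `max.depth`).
#' @return An [ImportanceRanking-class].
#' @export
prescreenFeatures <- function(fm, k = 50L, nTrees = 200L, seed = 1L, ...) {
  stopifnot(is(fm, "EdgeFeatureMatrix"))
  y <- droplevels(fm@groups)
  if (nlevels(y) < 2L)
    stop("pre-screening needs >= 2 groups represented in the feature matrix")
  fit <- .fitForest(fm@values, y, nTrees, seed, importance = TRUE, ...)
  sc <- fit$variable.importance / nrow(fm@values)
  sc <- pmax(sc, 0)
  ord <- order(-sc, names(sc))
  keep <- names(sc)[ord][seq_len(min(k, length(sc)))]
  new("ImportanceRanking", scores = sc, ranking = keep)
}
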