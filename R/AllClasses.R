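#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# GroupLabels
# ---------------------------------------------------------------------------

#' Sample-to-group assignments with a designated reference group
#'
#' Holds the mapping from sample identifiers to clinical group names
#' (e.g., pathological stages or molecular subtypes) together with the name
#' of the reference (normal) group against which per-sample
#' differential-correlation networks are computed.
#'
#' @slot assignments Named character vector: names are sample identifiers,
#'   values are group names.
#' @slot referenceGroup Single group name designating the reference cohort.
#'
#' @seealso [readGroupLabels()], [GSNExperiment()]
#' @export
setClass("GroupLabels",
  representation(assignments = "character", referenceGroup = "character"))

setValidity("GroupLabels", function(object) {
  a <- object@assignments
  if (is.null(names(a)) || any(names(a) == ""))
    return("assignments must be a named character vector (names = sample ids)")
  if (anyDuplicated(names(a)))
    return("duplicated sample identifiers in group assignments")
  if (length(object@referenceGroup) != 1L)
    return("referenceGroup must be a single group name")
  if (!object@referenceGroup %in% a)
    return(sprintf("reference group '%s' absent from the label table",
                   object@referenceGroup))
  if (sum(a == object@referenceGroup) < 3L)
    return("reference group needs >= 3 samples (Pearson correlation needs >= 3 points)")
  TRUE
})

#' Construct a GroupLabels object
#'
#' @param assignments Named character vector mapping sample ids to group
#'   names, or a two-column data.frame (sample id, group).
#' @param referenceGroup Name of the reference (normal) group.
#' @return A [GroupLabels-class] object.
#' @examples
#' GroupLabels(c(s1 = "Normal", s2 = "Normal", s3 = "Normal", s4 = "I"),
#'             referenceGroup = "Normal")
#' @export
GroupLabels <- function(assignments, referenceGroup) {
  if (is.data.frame(assignments)) {
    stopifnot(ncol(assignments) >= 2L)
    assignments <- stats::setNames(as.character(assignments[[2L]]),
                                   as.character(assignments[[1L]]))
  }
  new("GroupLabels", assignments = assignments,
      referenceGroup = as.character(referenceGroup))
}

# ---------------------------------------------------------------------------
# PPINetwork
# ---------------------------------------------------------------------------

#' Undirected protein-protein interaction network
#'
#' An undirected edge list with optional interaction scores.  Edges are
#' stored once, in canonical (lexicographic) order, with self-loops
#' removed.
#'
#' @slot edges data.frame with columns `geneA`, `geneB` (character,
#'   `geneA < geneB`) and `score` (numeric, `NA` when the source file
#'   carried none).
#' @seealso [readPPIEdges()]
#' @export
setClass("PPINetwork", representation(edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "score") %in% names(e)))
    return("edges must have columns geneA, geneB, score")
  if (any(e$geneA == e$geneB)) return("self-loops are not allowed")
  if (any(e$geneA > e$geneB)) return("edges must be in canonical order (geneA < geneB)")
  if (anyDuplicated(.pairKey(e$geneA, e$geneB)))
    return("duplicated edges")
  if (any(!is.na(e$score) & e$score < 0)) return("scores must be non-negative")
  TRUE
})

#' Construct a PPINetwork from an edge table
#'
#' Deduplicates, canonicalizes, and drops self-loops.
#'
#' @param geneA,geneB Character vectors of interacting gene identifiers.
#' @param score Optional numeric interaction scores.
#' @return A [PPINetwork-class] object.
#' @export
PPINetwork <- function(geneA, geneB, score = NULL) {
  p <- .canonicalPairs(geneA, geneB)
  p$score <- if (is.null(score)) NA_real_ else as.numeric(score)
  p <- p[p$geneA != p$geneB, , drop = FALSE]
  p <- p[!duplicated(.pairKey(p$geneA, p$geneB)), , drop = FALSE]
  p <- p[order(p$geneA, p$geneB), , drop = FALSE]
  rownames(p) <- NULL
  new("PPINetwork", edges = p)
}

# ---------------------------------------------------------------------------
# GSNExperiment: expression + labels in one container
# ---------------------------------------------------------------------------

#' Expression matrix with group labels, the pipeline's substrate
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a designated
#' reference group.  The single assay holds a genes x samples abundance
#' matrix; `colData(x)$group` carries the group of each sample; the unit of
#' the values (`"counts"`, `"cpm"` or `"normalized"`) is recorded in
#' `metadata(x)$unit`.  CPM-based low-expression filtering
#' ([cpmFilter()]) applies only when the unit is `"counts"`.
#'
#' @slot referenceGroup Name of the reference (normal) group.
#' @seealso [GSNExperiment()] constructor, [cpmFilter()], [runPipeline()]
#' @export
setClass("GSNExperiment", contains = "SummarizedExperiment",
         representation(referenceGroup = "character"))

setValidity("GSNExperiment", function(object) {
  if (nrow(object) > 0 || ncol(object) > 0) {
    if (length(SummarizedExperiment::assays(object)) < 1L)
      return("an assay is required")
    m <- SummarizedExperiment::assay(object)
    if (is.null(rownames(object)) || is.null(colnames(object)))
      return("gene and sample identifiers (dimnames) are required")
    if (anyDuplicated(rownames(object))) return("duplicated gene identifiers")
    if (anyDuplicated(colnames(object))) return("duplicated sample identifiers")
    if (!"group" %in% names(SummarizedExperiment::colData(object)))
      return("colData must contain a 'group' column")
    unit <- S4Vectors::metadata(object)$unit
    if (is.null(unit) || !unit %in% c("counts", "cpm", "normalized"))
      return("metadata(x)$unit must be one of 'counts', 'cpm', 'normalized'")
    if (any(!is.finite(m))) return("all expression values must be finite")
    if (unit == "counts" && any(m < 0))
      return("counts must be non-negative")
    grp <- as.character(SummarizedExperiment::colData(object)$group)
    if (length(object@referenceGroup) != 1L ||
        !object@referenceGroup %in% grp)
      return("referenceGroup must name a group present in colData$group")
    if (sum(grp == object@referenceGroup) < 3L)
      return("reference group needs >= 3 samples")
  }
  TRUE
})

#' Construct a GSNExperiment
#'
#' Combines an expression matrix (or `SummarizedExperiment`) with group
#' labels.  Samples present in the matrix but absent from the labels are
#' dropped with a warning; labelled samples missing from the matrix are an
#' error.
#'
#' @param counts Numeric genes x samples matrix with dimnames, or a
#'   `SummarizedExperiment` as returned by [readExpressionMatrix()].
#' @param labels A [GroupLabels-class] object, or a named character vector
#'   of group assignments.
#' @param referenceGroup Reference group name; defaults to the one carried
#'   by `labels` when that is a `GroupLabels` object.
#' @param unit Unit of the expression values: `"counts"` (default),
#'   `"cpm"`, or `"normalized"`.
#' @return A [GSNExperiment-class] object.
#' @examples
#' m <- matrix(rpois(40, 50), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' lab <- GroupLabels(setNames(rep(c("Normal", "I"), each = 5),
#'                             colnames(m)), "Normal")
#' gse <- GSNExperiment(m, lab)
#' @export
GSNExperiment <- function(counts, labels, referenceGroup = NULL,
                          unit = "counts") {
  if (is(counts, "SummarizedExperiment")) {
    if (!is.null(S4Vectors::metadata(counts)$unit))
      unit <- S4Vectors::metadata(counts)$unit
    counts <- SummarizedExperiment::assay(counts)
  }
  counts <- as.matrix(counts)
  if (is(labels, "GroupLabels")) {
    if (is.null(referenceGroup)) referenceGroup <- labels@referenceGroup
    labels <- labels@assignments
  }
  if (is.null(referenceGroup))
    stop("referenceGroup must be given (directly or through a GroupLabels object)")
  missingExpr <- setdiff(names(labels), colnames(counts))
  if (length(missingExpr))
    stop("labelled sample(s) absent from the expression matrix: ",
         paste(head(missingExpr, 5L), collapse = ", "))
  unlabelled <- setdiff(colnames(counts), names(labels))
  if (length(unlabelled)) {
    warning(length(unlabelled),
            " unlabelled sample(s) excluded from the analysis: ",
            paste(head(unlabelled, 5L), collapse = ", "))
    counts <- counts[, setdiff(colnames(counts), unlabelled), drop = FALSE]
  }
  grp <- labels[colnames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = counts),
    colData = S4Vectors::DataFrame(group = unname(grp),
                                   row.names = colnames(counts)),
    metadata = list(unit = unit))
  new("GSNExperiment", se, referenceGroup = as.character(referenceGroup))
}

# ---------------------------------------------------------------------------
# Network classes
# ---------------------------------------------------------------------------

#' Reference correlation network
#'
#' Pairwise Pearson correlations over the reference (normal) samples, for a
#' fixed set of gene pairs (in practice the PPI edge set).  Pairs for which
#' the correlation is undefined (zero variance) carry `NA` and are excluded
#' downstream.
#'
#' @slot nRef Number of reference samples the correlations are computed on.
#' @slot edges data.frame with columns `geneA`, `geneB`, `pcc`.
#' @seealso [buildReferenceNetwork()]
#' @export
setClass("ReferenceNetwork",
  representation(nRef = "integer", edges = "data.frame"))

setValidity("ReferenceNetwork", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "pcc") %in% names(e)))
    return("edges must have columns geneA, geneB, pcc")
  if (object@nRef < 3L) return("nRef must be >= 3")
  ok <- is.na(e$pcc) | abs(e$pcc) <= 1 + 1e-12
  if (!all(ok)) return("|pcc| must be <= 1")
  TRUE
})

#' Per-sample differential-correlation network
#'
#' The sample-specific network (SSN) of one non-reference sample: gene
#' pairs whose Pearson correlation changes significantly when the sample is
#' added to the reference cohort.  Only significant edges (p < alpha) are
#' stored; the stored value is delta-PCC, the change in correlation.
#'
#' @slot sampleId Sample identifier.
#' @slot edges data.frame with columns `geneA`, `geneB`, `deltaPCC`,
#'   `pValue`.
#' @slot alpha Significance level used for the edge filter.
#' @slot nRef Reference cohort size.
#' @seealso [buildSSN()]
#' @export
setClass("SampleNetwork",
  representation(sampleId = "character", edges = "data.frame",
                 alpha = "numeric", nRef = "integer"))

setValidity("SampleNetwork", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "deltaPCC", "pValue") %in% names(e)))
    return("edges must have columns geneA, geneB, deltaPCC, pValue")
  if (nrow(e) && any(e$pValue >= object@alpha))
    return("stored edges must satisfy pValue < alpha")
  if (nrow(e) && any(abs(e$deltaPCC) > 2 + 1e-12))
    return("|deltaPCC| must be <= 2")
  TRUE
})

#' Group-specific network
#'
#' One weighted network per clinical group: the weight of an edge is the
#' group mean of its per-sample delta-PCC values, counting 0 for samples
#' whose SSN lacks the edge, restricted to PPI edges.
#'
#' @slot group Group name.
#' @slot nSamples Number of samples aggregated (the denominator N).
#' @slot edges data.frame with columns `geneA`, `geneB`, `weight`.
#' @seealso [aggregateGroup()], [averageFoldGSNs()]
#' @export
setClass("GroupNetwork",
  representation(group = "character", nSamples = "integer",
                 edges = "data.frame"))

setValidity("GroupNetwork", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "weight") %in% names(e)))
    return("edges must have columns geneA, geneB, weight")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (nrow(e) && any(abs(e$weight) > 2 + 1e-12))
    return("|weight| must be <= 2")
  TRUE
})

# ---------------------------------------------------------------------------
# Feature-selection classes
# ---------------------------------------------------------------------------

#' Samples x candidate-edge feature matrix
#'
#' The feature representation fed to the classifiers: one row per
#' (non-reference) sample, one column per candidate edge; the value is the
#' sample's significant delta-PCC for that edge, or 0 when the edge is
#' absent from the sample's network.
#'
#' @slot values Numeric matrix, samples x edges; column names are canonical
#'   edge keys `"geneA|geneB"`.
#' @slot groups Factor of group memberships aligned with the rows.
#' @seealso [buildEdgeFeatures()]
#' @export
setClass("EdgeFeatureMatrix",
  representation(values = "matrix", groups = "factor"))

setValidity("EdgeFeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@groups))
    return("one group per sample row is required")
  if (is.null(colnames(object@values)) || is.null(rownames(object@values)))
    return("values must carry sample row names and edge column names")
  TRUE
})

#' Random-forest importance ranking of candidate edges
#'
#' @slot scores Named numeric vector of non-negative impurity-gain
#'   importances (mean per-sample Gini decrease), all candidates.
#' @slot ranking Character vector of the retained top edges, most important
#'   first; ties broken lexicographically.
#' @seealso [prescreenFeatures()]
#' @export
setClass("ImportanceRanking",
  representation(scores = "numeric", ranking = "character"))

setValidity("ImportanceRanking", function(object) {
  if (any(object@scores < -1e-12)) return("importances must be non-negative")
  if (anyDuplicated(object@ranking)) return("ranking must not repeat edges")
  if (!all(object@ranking %in% names(object@scores)))
    return("ranking must be a subset of the scored edges")
  TRUE
})

#' Result of recursive feature elimination with CBR-guided stopping
#'
#' @slot records data.frame with one row per evaluated feature-count
#'   threshold: `k`, cross-validated `f1` (percent), and `cbr`
#'   (`NA` at the smallest k, where no gain is defined).
#' @slot features Named list: retained edge keys at each evaluated `k`.
#' @slot optimalK Feature count chosen by the Cost-Benefit-Ratio rule.
#' @slot optimalFeatures Edge keys retained at `optimalK`.
#' @seealso [selectFeatures()], [rfecv()], [selectOptimalCount()]
#' @export
setClass("SelectionResult",
  representation(records = "data.frame", features = "list",
                 optimalK = "integer", optimalFeatures = "character"))

setValidity("SelectionResult", function(object) {
  r <- object@records
  if (!all(c("k", "f1", "cbr") %in% names(r)))
    return("records must have columns k, f1, cbr")
  if (!object@optimalK %in% r$k) return("optimalK must be an evaluated k")
  if (!identical(sort(object@optimalFeatures),
                 sort(object@features[[as.character(object@optimalK)]])))
    return("optimalFeatures must equal the feature set recorded at optimalK")
  if (any(r$f1 < 0 | r$f1 > 100)) return("f1 must lie in [0, 100]")
  TRUE
})

#' Cross-validated evaluation report
#'
#' @slot perFold data.frame with one row per outer fold: `fold`, `testF1`
#'   (macro F1 percent on the held-out fold), `innerF1` (the RFECV inner
#'   cross-validation estimate at the selected feature count), and
#'   `optimalK`.
#' @slot foldFeatures List of the edge sets selected in each fold.
#' @slot predictions List of per-fold data.frames (`sample`, `truth`,
#'   `predicted`) for the held-out samples.
#' @slot meanF1 Mean held-out macro F1 (percent) across folds.
#' @slot meanInnerF1 Mean inner RFECV F1 estimate (percent).
#' @slot finalSelection [SelectionResult-class] from the fold-averaged
#'   group networks on all data.
#' @slot finalBiomarkers data.frame `geneA`, `geneB`, `rank`: the reported
#'   edge biomarkers.
#' @seealso [runPipeline()]
#' @export
setClass("CrossValReport",
  representation(perFold = "data.frame", foldFeatures = "list",
                 predictions = "list", meanF1 = "numeric",
                 meanInnerF1 = "numeric", finalSelection = "SelectionResult",
                 finalBiomarkers = "data.frame"))

setValidity("CrossValReport", function(object) {
  if (nrow(object@perFold) != length(object@foldFeatures))
    return("one feature set per fold is required")
  if (abs(object@meanF1 - mean(object@perFold$testF1)) > 1e-8)
    return("meanF1 must be the arithmetic mean of the fold F1s")
  TRUE
})

# ---------------------------------------------------------------------------
# GSNParam
# ---------------------------------------------------------------------------

#' Pipeline parameters
#'
#' Bundle of all tunable parameters of the pipeline.  See [gsnParam()] for
#' the defaults and their meaning.
#'
#' @slot alpha Significance level for the per-sample edge test.
#' @slot cpmThreshold,cpmFraction CPM filter: keep genes with CPM strictly
#'   above `cpmThreshold` in at least `cpmFraction` of samples.
#' @slot scoreMin Minimum PPI interaction score.
#' @slot topEdges Edges kept per group network in the first screening round.
#' @slot topFeatures Features kept by importance pre-screening.
#' @slot cbrThreshold Cost-Benefit-Ratio balancing point.
#' @slot maxThreshold Largest feature-count threshold evaluated.
#' @slot outerFolds,innerFolds Outer evaluation folds / inner RFECV folds.
#' @slot rfTrees Trees per random forest.
#' @slot signedRank Rank edges by signed weight instead of |weight|.
#' @slot includeReference Include reference samples as a classifier class.
#' @slot f1Average F1 averaging: "macro", "weighted" or "micro".
#' @slot nullModel Null reference for the delta-PCC test:
#'   "product-normal" (calibrated) or "gaussian" (classical).
#' @slot seed Master seed; every random step derives from it.
#' @export
setClass("GSNParam",
  representation(alpha = "numeric", cpmThreshold = "numeric",
                 cpmFraction = "numeric", scoreMin = "numeric",
                 topEdges = "integer", topFeatures = "integer",
                 cbrThreshold = "numeric", maxThreshold = "integer",
                 outerFolds = "integer", innerFolds = "integer",
                 rfTrees = "integer", signedRank = "logical",
                 includeReference = "logical", f1Average = "character",
                 nullModel = "character", seed = "integer"))

setValidity("GSNParam", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (object@cpmFraction < 0 || object@cpmFraction > 1)
    return("cpmFraction must lie in [0, 1]")
  if (object@topEdges < 1L || object@topFeatures < 1L ||
      object@maxThreshold < 1L)
    return("topEdges, topFeatures and maxThreshold must be >= 1")
  if (object@outerFolds < 2L) return("outerFolds must be >= 2")
  if (object@innerFolds < 2L) return("innerFolds must be >= 2")
  if (object@rfTrees < 1L) return("rfTrees must be >= 1")
  if (!object@f1Average %in% c("macro", "weighted", "micro"))
    return("f1Average must be 'macro', 'weighted' or 'micro'")
  if (!object@nullModel %in% c("product-normal", "gaussian"))
    return("nullModel must be 'product-normal' or 'gaussian'")
  TRUE
})

#' Construct the pipeline parameter bundle
#'
#' @param alpha Significance level for retaining a perturbed edge in a
#'   sample's network (default 0.05).
#' @param cpmThreshold,cpmFraction Low-expression filter: a gene is kept
#'   when its CPM exceeds `cpmThreshold` (strictly) in at least
#'   `cpmFraction` of the samples (defaults 2 and 0.5).
#' @param scoreMin Minimum PPI score; edges below it are dropped on read
#'   (default 0, i.e. keep all edges of the physical-links file).
#' @param topEdges Top edges (by |weight|) taken from each group network to
#'   form the candidate set (default 50).
#' @param topFeatures Candidates retained by random-forest importance
#'   pre-screening (default 50).
#' @param cbrThreshold Balancing point of the Cost-Benefit Ratio: the
#'   optimal feature count precedes the first threshold whose CBR falls
#'   strictly below this value (default 0.5).
#' @param maxThreshold Feature-count thresholds 1..maxThreshold are
#'   evaluated (default 10).
#' @param outerFolds Outer stratified folds for evaluation (default 10).
#' @param innerFolds Inner stratified folds for RFECV scoring (default 5).
#' @param rfTrees Trees per random forest (default 200).
#' @param signedRank If `TRUE`, rank group-network edges by signed weight;
#'   the default `FALSE` ranks by absolute weight so that lost correlation
#'   (negative delta-PCC) is not discarded.
#' @param includeReference If `TRUE`, the reference group is one of the
#'   classifier's classes; default `FALSE` (the classifier discriminates
#'   among the non-reference groups).
#' @param f1Average F1 averaging variant (default "macro"; classes are
#'   typically imbalanced).
#' @param nullModel Null reference distribution for the delta-PCC edge
#'   test: `"product-normal"` (default; calibrated) or `"gaussian"`
#'   (classical sample-specific-network z-test).
#' @param seed Master seed for all randomized steps (default 1).
#' @return A [GSNParam-class] object.
#' @examples
#' gsnParam(alpha = 0.01, outerFolds = 5)
#' @export
gsnParam <- function(alpha = 0.05, cpmThreshold = 2, cpmFraction = 0.5,
                     scoreMin = 0, topEdges = 50L, topFeatures = 50L,
                     cbrThreshold = 0.5, maxThreshold = 10L,
                     outerFolds = 10L, innerFolds = 5L, rfTrees = 200L,
                     signedRank = FALSE, includeReference = FALSE,
                     f1Average = "macro", nullModel = "product-normal",
                     seed = 1L) {
  new("GSNParam", alpha = alpha, cpmThreshold = cpmThreshold,
      cpmFraction = cpmFraction, scoreMin = scoreMin,
      topEdges = as.integer(topEdges), topFeatures = as.integer(topFeatures),
      cbrThreshold = cbrThreshold, maxThreshold = as.integer(maxThreshold),
      outerFolds = as.integer(outerFolds), innerFolds = as.integer(innerFolds),
      rfTrees = as.integer(rfTrees), signedRank = signedRank,
      includeReference = includeReference, f1Average = f1Average,
      nullModel = nullModel, seed = as.integer(seed))
}
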