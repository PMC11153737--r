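# Accessor generics and show methods.

#' Edge table of a network object
#'
#' Returns the edge list of a network-like object as a `data.frame` in
#' canonical pair order.
#'
#' @param x A [PPINetwork-class], [ReferenceNetwork-class],
#'   [SampleNetwork-class] or [GroupNetwork-class] object.
#' @return A `data.frame` whose first two columns are `geneA`, `geneB`,
#'   plus the object's value columns (`score`, `pcc`, `deltaPCC`/`pValue`
#'   or `weight`).
#' @examples
#' networkEdges(PPINetwork(c("b", "a"), c("a", "c")))
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "PPINetwork", function(x) x@edges)
#' @rdname networkEdges
#' @export
setMethod("networkEdges", "ReferenceNetwork", function(x) x@edges)
#' @rdname networkEdges
#' @export
setMethod("networkEdges", "SampleNetwork", function(x) x@edges)
#' @rdname networkEdges
#' @export
setMethod("networkEdges", "GroupNetwork", function(x) x@edges)

#' @rdname networkEdges
#' @export
ppiEdges <- function(x) {
  stopifnot(is(x, "PPINetwork"))
  x@edges
}

#' Canonical edge keys of a network
#'
#' @param x A network object (see [networkEdges()]).
#' @return Character vector of `"geneA|geneB"` keys.
#' @export
edgeKeys <- function(x) {
  e <- networkEdges(x)
  .pairKey(e$geneA, e$geneB)
}

#' Reference group and group assignments
#'
#' `referenceGroup()` returns the designated reference (normal) group;
#' `sampleGroups()` the factor of group memberships (named by sample);
#' `referenceSamples()`/`diseaseSamples()` the corresponding sample ids.
#'
#' @param x A [GSNExperiment-class] or [GroupLabels-class] object.
#' @return See the individual descriptions.
#' @export
setGeneric("referenceGroup", function(x) standardGeneric("referenceGroup"))

#' @rdname referenceGroup
#' @export
setMethod("referenceGroup", "GSNExperiment", function(x) x@referenceGroup)
#' @rdname referenceGroup
#' @export
setMethod("referenceGroup", "GroupLabels", function(x) x@referenceGroup)

#' @rdname referenceGroup
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname referenceGroup
#' @export
setMethod("sampleGroups", "GSNExperiment", function(x) {
  grp <- as.character(SummarizedExperiment::colData(x)$group)
  stats::setNames(factor(grp), colnames(x))
})
#' @rdname referenceGroup
#' @export
setMethod("sampleGroups", "GroupLabels", function(x) {
  stats::setNames(factor(unname(x@assignments)), names(x@assignments))
})

#' @rdname referenceGroup
#' @export
referenceSamples <- function(x) {
  g <- sampleGroups(x)
  names(g)[g == referenceGroup(x)]
}

#' @rdname referenceGroup
#' @export
diseaseSamples <- function(x) {
  g <- sampleGroups(x)
  names(g)[g != referenceGroup(x)]
}

#' Accessors for feature-selection results
#'
#' `featureValues()`/`featureGroups()` access an
#' [EdgeFeatureMatrix-class]; `importanceScores()` the named importance
#' vector of an [ImportanceRanking-class]; `selectionRecords()`,
#' `optimalFeatureCount()` and `optimalFeatures()` the per-threshold table,
#' chosen count, and chosen edges of a [SelectionResult-class];
#' `foldResults()`, `meanF1()` and `finalBiomarkers()` the per-fold table,
#' mean held-out F1, and reported biomarker edges of a
#' [CrossValReport-class].
#'
#' @param x The object to access.
#' @return See the individual descriptions.
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "EdgeFeatureMatrix"))
  x@values
}

#' @rdname selection-accessors
#' @export
featureGroups <- function(x) {
  stopifnot(is(x, "EdgeFeatureMatrix"))
  stats::setNames(x@groups, rownames(x@values))
}

#' @rdname selection-accessors
#' @export
importanceScores <- function(x) {
  stopifnot(is(x, "ImportanceRanking"))
  x@scores
}

#' @rdname selection-accessors
#' @export
topFeatures <- function(x) {
  stopifnot(is(x, "ImportanceRanking"))
  x@ranking
}

#' @rdname selection-accessors
#' @export
selectionRecords <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@records
}

#' @rdname selection-accessors
#' @export
optimalFeatureCount <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@optimalK
}

#' @rdname selection-accessors
#' @export
optimalFeatures <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@optimalFeatures
}

#' @rdname selection-accessors
#' @export
thresholdFeatures <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@features
}

#' @rdname selection-accessors
#' @export
foldResults <- function(x) {
  stopifnot(is(x, "CrossValReport"))
  x@perFold
}

#' @rdname selection-accessors
#' @export
foldPredictions <- function(x) {
  stopifnot(is(x, "CrossValReport"))
  x@predictions
}

#' @rdname selection-accessors
#' @export
meanF1 <- function(x) {
  stopifnot(is(x, "CrossValReport"))
  x@meanF1
}

#' @rdname selection-accessors
#' @export
finalBiomarkers <- function(x) {
  stopifnot(is(x, "CrossValReport"))
  x@finalBiomarkers
}

#' @rdname selection-accessors
#' @export
finalSelection <- function(x) {
  stopifnot(is(x, "CrossValReport"))
  x@finalSelection
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "GroupLabels", function(object) {
  tab <- table(object@assignments)
  cat("GroupLabels:", length(object@assignments), "samples in",
      length(tab), "groups (reference:", object@referenceGroup, ")\n")
  print(tab)
})

setMethod("show", "PPINetwork", function(object) {
  e <- object@edges
  cat("PPINetwork:", nrow(e), "undirected edges over",
      length(unique(c(e$geneA, e$geneB))), "genes\n")
})

setMethod("show", "GSNExperiment", function(object) {
  callNextMethod()
  cat("unit:", S4Vectors::metadata(object)$unit,
      "| reference group:", object@referenceGroup, "\n")
})

setMethod("show", "ReferenceNetwork", function(object) {
  cat("ReferenceNetwork:", nrow(object@edges), "gene pairs over",
      object@nRef, "reference samples (",
      sum(is.na(object@edges$pcc)), "undefined )\n")
})

setMethod("show", "SampleNetwork", function(object) {
  cat("SampleNetwork for sample", object@sampleId, ":", nrow(object@edges),
      "significant edges at alpha =", object@alpha, "\n")
})

setMethod("show", "GroupNetwork", function(object) {
  cat("GroupNetwork for group", object@group, ":", nrow(object@edges),
      "edges aggregated over", object@nSamples, "samples\n")
})

setMethod("show", "EdgeFeatureMatrix", function(object) {
  cat("EdgeFeatureMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "candidate edges;",
      nlevels(object@groups), "groups\n")
})

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking:", length(object@ranking), "of",
      length(object@scores), "edges retained; top edge:",
      if (length(object@ranking)) object@ranking[1L] else "<none>", "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: optimal feature count", object@optimalK,
      "(F1 =", sprintf("%.4f", object@records$f1[
        match(object@optimalK, object@records$k)]), "% )\n")
  print(object@records, row.names = FALSE)
})

setMethod("show", "CrossValReport", function(object) {
  cat("CrossValReport:", nrow(object@perFold), "folds; mean held-out F1 =",
      sprintf("%.4f", object@meanF1), "% ; mean inner F1 =",
      sprintf("%.4f", object@meanInnerF1), "%\n")
  cat("final biomarkers:", nrow(object@finalBiomarkers), "edges\n")
})

setMethod("show", "GSNParam", function(object) {
  cat("GSNParam: alpha =", object@alpha,
      "| top edges/features =", object@topEdges, "/", object@topFeatures,
      "| CBR threshold =", object@cbrThreshold,
      "| folds =", object@outerFolds, "x", object@innerFolds,
      "| trees =", object@rfTrees, "| seed =", object@seed, "\n")
})
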