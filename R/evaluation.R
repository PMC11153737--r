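# Evaluation: F1 metrics, the outer cross-validated protocol, and the
# single-shot selection mode.

#' F1 score for multi-class predictions
#'
#' Per-class F1 is `2 * precision * recall / (precision + recall)`, with 0
#' substituted for empty denominators.  Classes are the union of labels
#' observed in truth or prediction.  `"macro"` (default) averages
#' per-class F1 unweighted, `"weighted"` weights by class support in the
#' truth, `"micro"` computes F1 from pooled counts.
#'
#' @param truth,predicted Equal-length label vectors/factors.
#' @param average `"macro"`, `"weighted"` or `"micro"`.
#' @return F1 in percent.
#' @examples
#' macroF1(c("I", "I", "II"), c("I", "II", "II"))
#' @export
macroF1 <- function(truth, predicted, average = c("macro", "weighted",
                                                  "micro")) {
  average <- match.arg(average)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  if (!length(classes)) stop("no labels supplied")
  tp <- vapply(classes, function(cl) sum(truth == cl & predicted == cl),
               numeric(1))
  fp <- vapply(classes, function(cl) sum(truth != cl & predicted == cl),
               numeric(1))
  fn <- vapply(classes, function(cl) sum(truth == cl & predicted != cl),
               numeric(1))
  if (average == "micro") {
    denom <- 2 * sum(tp) + sum(fp) + sum(fn)
    return(if (denom == 0) 0 else 100 * 2 * sum(tp) / denom)
  }
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  if (average == "macro") return(100 * mean(f1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  100 * sum(f1 * support) / sum(support)
}

# One fold's (or the whole data's) selection pass: SSNs for the given
# disease samples against the given reference samples, group networks,
# candidate edges, pre-screening, RFECV + CBR.  Returns everything the
# caller needs.
.selectionPass <- function(gse, ppi, param, diseaseIds, refIds, seed) {
  grp <- sampleGroups(gse)
  ssns <- buildAllSSNs(gse, ppi, samples = diseaseIds,
                       referenceIds = refIds, alpha = param@alpha,
                       nullModel = param@nullModel)
  gsns <- buildGroupNetworks(ssns, grp, ppi = ppi)
  if (!param@includeReference)
    gsns <- gsns[setdiff(names(gsns), referenceGroup(gse))]
  candidates <- buildCandidateSet(gsns, k = param@topEdges,
                                  signed = param@signedRank)
  fm <- buildEdgeFeatures(candidates, ssns, grp,
                          referenceGroup = referenceGroup(gse),
                          includeReference = param@includeReference)
  ranking <- prescreenFeatures(fm, k = param@topFeatures,
                               nTrees = param@rfTrees,
                               seed = .deriveSeed(seed, 11L))
  fmTop <- new("EdgeFeatureMatrix",
               values = fm@values[, ranking@ranking, drop = FALSE],
               groups = fm@groups)
  sel <- selectFeatures(fmTop, param, seed = .deriveSeed(seed, 12L))
  list(ssns = ssns, gsns = gsns, candidates = candidates, ranking = ranking,
       featureMatrix = fmTop, selection = sel)
}

#' Single-shot biomarker selection (no outer cross-validation)
#'
#' Builds the reference network from all reference samples, the per-sample
#' networks for all disease samples, one group network per group (no fold
#' averaging), and runs both selection rounds once.
#'
#' @param gse A [GSNExperiment-class]; count data are CPM-filtered first.
#' @param ppi A [PPINetwork-class].
#' @param param A [GSNParam-class].
#' @return A list with elements `selection` ([SelectionResult-class]),
#'   `biomarkers` (data.frame `geneA`, `geneB`, `rank`), `gsns`,
#'   `candidates`, `ranking`, and `featureMatrix`.
#' @examples
#' sim <- simulateGSNData(simulationSpec(nGenes = 12,
#'   groupSizes = c(Normal = 12, A = 12, B = 12), plantedEdges = 2),
#'   seed = 1)
#' run <- selectBiomarkers(sim$experiment, sim$ppi,
#'   gsnParam(rfTrees = 50, maxThreshold = 5, seed = 1))
#' run$biomarkers
#' @export
selectBiomarkers <- function(gse, ppi, param = gsnParam()) {
  stopifnot(is(gse, "GSNExperiment"), is(ppi, "PPINetwork"))
  if (identical(S4Vectors::metadata(gse)$unit, "counts"))
    gse <- cpmFilter(gse, param@cpmThreshold, param@cpmFraction)
  pass <- .selectionPass(gse, ppi, param, diseaseSamples(gse),
                         referenceSamples(gse), seed = param@seed)
  pr <- .splitKey(optimalFeatures(pass$selection))
  pass$biomarkers <- data.frame(geneA = pr$geneA, geneB = pr$geneB,
                                rank = seq_len(nrow(pr)))
  pass[c("selection", "biomarkers", "gsns", "candidates", "ranking",
         "featureMatrix")]
}

#' Run the full cross-validated pipeline
#'
#' Stratified outer cross-validation over all samples.  Per fold, using
#' training samples only: the reference network is built from the
#' training-fold normals, per-sample networks for the training disease
#' samples, one group network per group, candidate edges, importance
#' pre-screening, and RFECV with CBR-guided stopping.  The held-out fold's
#' disease samples are then scored: their networks are computed against
#' the *training* reference, their features at the selected edges fed to a
#' random forest trained on the training features, and the held-out F1
#' recorded.  Finally the per-fold group networks are averaged per group
#' and one selection pass on all data derives the reported biomarkers.
#'
#' @param gse A [GSNExperiment-class]; count data are CPM-filtered first.
#' @param ppi A [PPINetwork-class].
#' @param param A [GSNParam-class]; all folds, seeds and forest sizes
#'   derive from it.
#' @return A [CrossValReport-class].
#' @export
runPipeline <- function(gse, ppi, param = gsnParam()) {
  stopifnot(is(gse, "GSNExperiment"), is(ppi, "PPINetwork"))
  if (identical(S4Vectors::metadata(gse)$unit, "counts"))
    gse <- cpmFilter(gse, param@cpmThreshold, param@cpmFraction)
  grp <- sampleGroups(gse)
  small <- names(which(table(grp) < param@outerFolds))
  if (length(small))
    stop("group(s) smaller than outerFolds (", param@outerFolds, "): ",
         paste(small, collapse = ", "), "; reduce outerFolds")
  folds <- .stratifiedFolds(grp, param@outerFolds,
                            seed = .deriveSeed(param@seed, 2L))
  refG <- referenceGroup(gse)
  ids <- names(grp)
  perFold <- vector("list", param@outerFolds)
  foldFeatures <- vector("list", param@outerFolds)
  predictions <- vector("list", param@outerFolds)
  foldGSNs <- vector("list", param@outerFolds)
  for (f in seq_len(param@outerFolds)) {
    trainIds <- ids[folds != f]
    testIds <- ids[folds == f]
    trainRef <- trainIds[grp[trainIds] == refG]
    trainDis <- trainIds[grp[trainIds] != refG]
    testDis <- testIds[grp[testIds] != refG]
    pass <- .selectionPass(gse, ppi, param, trainDis, trainRef,
                           seed = .deriveSeed(param@seed, 20L + f))
    sel <- pass$selection
    selFeats <- optimalFeatures(sel)
    # held-out samples: networks against the training reference only
    testSSNs <- buildAllSSNs(gse, ppi, samples = testDis,
                             referenceIds = trainRef, alpha = param@alpha,
                             nullModel = param@nullModel)
    fmTest <- buildEdgeFeatures(selFeats, testSSNs, grp,
                                referenceGroup = refG,
                                includeReference = param@includeReference)
    yTrain <- pass$featureMatrix@groups
    clf <- .fitForest(pass$featureMatrix@values[, selFeats, drop = FALSE],
                      yTrain, param@rfTrees,
                      .deriveSeed(param@seed, 50L + f))
    pred <- stats::predict(
      clf, data = .asForestData(fmTest@values))$predictions
    truth <- as.character(fmTest@groups)
    innerF1 <- selectionRecords(sel)$f1[
      match(optimalFeatureCount(sel), selectionRecords(sel)$k)]
    perFold[[f]] <- data.frame(
      fold = f, testF1 = macroF1(truth, pred, average = param@f1Average),
      innerF1 = innerF1, optimalK = optimalFeatureCount(sel))
    foldFeatures[[f]] <- selFeats
    predictions[[f]] <- data.frame(sample = rownames(fmTest@values),
                                   truth = truth,
                                   predicted = as.character(pred))
    foldGSNs[[f]] <- pass$gsns
  }
  perFold <- do.call(rbind, perFold)
  # fold-averaged group networks -> one reported network per group,
  # then a single selection pass on all data
  groupsSeen <- sort(unique(unlist(lapply(foldGSNs, names))))
  avgGSNs <- stats::setNames(lapply(groupsSeen, function(g)
    averageFoldGSNs(lapply(foldGSNs, `[[`, g))), groupsSeen)
  finalCand <- buildCandidateSet(avgGSNs, k = param@topEdges,
                                 signed = param@signedRank)
  allSSNs <- buildAllSSNs(gse, ppi, alpha = param@alpha,
                          nullModel = param@nullModel)
  fmAll <- buildEdgeFeatures(finalCand, allSSNs, grp,
                             referenceGroup = refG,
                             includeReference = param@includeReference)
  rankingAll <- prescreenFeatures(fmAll, k = param@topFeatures,
                                  nTrees = param@rfTrees,
                                  seed = .deriveSeed(param@seed, 13L))
  fmAllTop <- new("EdgeFeatureMatrix",
                  values = fmAll@values[, rankingAll@ranking, drop = FALSE],
                  groups = fmAll@groups)
  finalSel <- selectFeatures(fmAllTop, param,
                             seed = .deriveSeed(param@seed, 14L))
  pr <- .splitKey(optimalFeatures(finalSel))
  new("CrossValReport",
      perFold = perFold, foldFeatures = foldFeatures,
      predictions = predictions,
      meanF1 = mean(perFold$testF1), meanInnerF1 = mean(perFold$innerF1),
      finalSelection = finalSel,
      finalBiomarkers = data.frame(geneA = pr$geneA, geneB = pr$geneB,
                                   rank = seq_len(nrow(pr))))
}
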