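# Second selection round: recursive feature elimination over
# feature-count thresholds and Cost-Benefit-Ratio choice of the optimal
# count.

#' Stratified cross-validated F1 of a feature subset
#'
#' Trains a random forest on each training split of a stratified
#' inner cross-validation and returns the pooled-prediction F1 (percent).
#' Deterministic given `seed`: folds and forests derive from it, so
#' re-scoring the same feature set reproduces the value exactly.
#'
#' @param fm An [EdgeFeatureMatrix-class].
#' @param features Edge keys to use (default: all columns).
#' @param innerFolds Number of stratified folds (default 5).
#' @param nTrees Trees per forest (default 200).
#' @param average F1 averaging variant (default "macro").
#' @param seed RNG seed (default 1).
#' @return Cross-validated F1 in percent.
#' @export
crossValF1 <- function(fm, features = colnames(featureValues(fm)),
                       innerFolds = 5L, nTrees = 200L, average = "macro",
                       seed = 1L) {
  stopifnot(is(fm, "EdgeFeatureMatrix"))
  y <- droplevels(fm@groups)
  if (nlevels(y) < 2L) stop("cross-validation needs >= 2 classes")
  if (any(table(y) < innerFolds))
    stop("a class has fewer members than inner folds; reduce innerFolds")
  vals <- fm@values[, features, drop = FALSE]
  folds <- .stratifiedFolds(y, innerFolds, seed = .deriveSeed(seed, 1L))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(innerFolds)) {
    tr <- folds != f
    fit <- .fitForest(vals[tr, , drop = FALSE], y[tr], nTrees,
                      .deriveSeed(seed, 100L + f))
    pred[!tr] <- stats::predict(
      fit, data = .asForestData(vals[!tr, , drop = FALSE]))$predictions
  }
  macroF1(y, pred, average = average)
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from the full (pre-screened) feature set, repeatedly trains a
#' random forest, removes the least important feature (one per
#' iteration, ties broken lexicographically), and whenever the current
#' size equals one of the requested thresholds records the feature set
#' together with its stratified cross-validated F1.
#'
#' @param fm An [EdgeFeatureMatrix-class].
#' @param thresholds Feature counts at which to record (default `1:10`);
#'   values above the feature count are ignored.
#' @param innerFolds,nTrees,average,seed As in [crossValF1()].
#' @return data.frame with columns `k` and `f1` (percent), ascending in
#'   `k`, with the retained edge keys at each `k` in attribute
#'   `"features"` (a named list).
#' @export
rfecv <- function(fm, thresholds = 1:10, innerFolds = 5L, nTrees = 200L,
                  average = "macro", seed = 1L) {
  stopifnot(is(fm, "EdgeFeatureMatrix"))
  p <- ncol(fm@values)
  thresholds <- sort(unique(as.integer(thresholds[thresholds <= p])))
  if (!length(thresholds)) stop("no threshold is <= the feature count")
  y <- droplevels(fm@groups)
  current <- colnames(fm@values)
  recs <- list(); feats <- list()
  while (length(current) >= 1L) {
    if (length(current) %in% thresholds) {
      kk <- length(current)
      recs[[as.character(kk)]] <- crossValF1(
        fm, current, innerFolds = innerFolds, nTrees = nTrees,
        average = average, seed = seed)
      feats[[as.character(kk)]] <- current
    }
    if (length(current) <= min(thresholds)) break
    fit <- .fitForest(fm@values[, current, drop = FALSE], y, nTrees,
                      .deriveSeed(seed, 1000L + length(current)),
                      importance = TRUE)
    imp <- fit$variable.importance
    drop <- names(imp)[order(imp, names(imp))][1L]
    current <- setdiff(current, drop)
  }
  ks <- sort(as.integer(names(recs)))
  out <- data.frame(k = ks,
                    f1 = vapply(as.character(ks), function(n) recs[[n]],
                                numeric(1)))
  rownames(out) <- NULL
  attr(out, "features") <- feats[as.character(ks)]
  out
}

#' Cost-Benefit Ratio series from an F1-by-feature-count table
#'
#' For consecutive evaluated thresholds `k_prev < k`, the Cost-Benefit
#' Ratio is `CBR = 100 * PR / (INF * UFC)` with `PR` the fractional F1
#' gain `(F1_k - F1_prev) / 100`, `INF = k - k_prev` the number of added
#' features, and unit feature cost `UFC = 1` --- i.e., the F1 gain in
#' percentage points per added feature.  Undefined (`NA`) at the smallest
#' threshold.
#'
#' @param f1ByK Named numeric vector of F1 scores in percent; names are
#'   the evaluated feature counts.
#' @return Named numeric vector of CBR values aligned with `f1ByK`
#'   (`NA` for the smallest count).
#' @examples
#' computeCBRSeries(c(`1` = 48.7420, `2` = 86.2510))  # CBR(2) = 37.509
#' @export
computeCBRSeries <- function(f1ByK) {
  if (!length(f1ByK)) stop("empty F1 map")
  k <- as.integer(names(f1ByK))
  if (anyNA(k)) stop("names of f1ByK must be the feature counts")
  ord <- order(k)
  k <- k[ord]; f1 <- as.numeric(f1ByK)[ord]
  cbr <- c(NA_real_, diff(f1) / diff(k))
  stats::setNames(cbr, k)
}

#' Optimal feature count from a CBR series
#'
#' Scanning the evaluated counts in ascending order, the first count whose
#' CBR falls strictly below `threshold` marks the stopping point; the
#' evaluated count immediately before it is returned.  If no CBR falls
#' below the threshold, the largest evaluated count is returned.
#'
#' @param cbrByK Named numeric vector of CBR values (names = feature
#'   counts); an `NA` leading entry (the smallest count) is allowed.
#' @param threshold Balancing point (default 0.5); a CBR exactly equal to
#'   it does not stop the scan.
#' @return The optimal feature count (integer).
#' @examples
#' cbr <- c(`1` = NA, `2` = 37.5090, `3` = 5.0047, `4` = 1.2492,
#'          `5` = 0.8039, `6` = 2.8448, `7` = 0.6979, `8` = 0.0550,
#'          `9` = 0.5868, `10` = 0.3868)
#' selectOptimalCount(cbr)  # 7
#' @export
selectOptimalCount <- function(cbrByK, threshold = 0.5) {
  if (!length(cbrByK)) stop("empty CBR map")
  k <- as.integer(names(cbrByK))
  if (anyNA(k)) stop("names of cbrByK must be the feature counts")
  ord <- order(k)
  k <- k[ord]; cbr <- as.numeric(cbrByK)[ord]
  below <- which(!is.na(cbr) & cbr < threshold)
  if (!length(below)) return(k[length(k)])
  iStar <- below[1L]
  if (iStar == 1L) return(k[1L])  # nothing precedes the smallest count
  k[iStar - 1L]
}

#' Select the optimal edge-feature subset
#'
#' Runs [rfecv()] over the feature-count thresholds, converts the F1
#' series to Cost-Benefit Ratios, and picks the optimal count with
#' [selectOptimalCount()].
#'
#' @param fm An [EdgeFeatureMatrix-class] (typically restricted to the
#'   pre-screened top features).
#' @param param A [GSNParam-class]; `maxThreshold`, `innerFolds`,
#'   `rfTrees`, `cbrThreshold` and `f1Average` are used.
#' @param seed RNG seed; defaults to the one in `param`.
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(fm, param = gsnParam(), seed = param@seed) {
  recs <- rfecv(fm, thresholds = seq_len(param@maxThreshold),
                innerFolds = param@innerFolds, nTrees = param@rfTrees,
                average = param@f1Average, seed = seed)
  feats <- attr(recs, "features")
  cbr <- computeCBRSeries(stats::setNames(recs$f1, recs$k))
  optK <- selectOptimalCount(cbr, threshold = param@cbrThreshold)
  records <- data.frame(k = recs$k, f1 = recs$f1, cbr = as.numeric(cbr))
  new("SelectionResult", records = records, features = feats,
      optimalK = as.integer(optK),
      optimalFeatures = feats[[as.character(optK)]])
}
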