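# Edge ranking, feature-matrix assembly, Gini primitives, and
# random-forest importance pre-screening.

test_that("edge ranking sorts by |weight| with lexicographic ties", {
  g <- makeGSN("I", c("A", "B", "C"), c("B", "C", "D"),
               c(0.5, -0.7, 0.1))
  expect_identical(rankEdges(g, 2), c("B|C", "A|B"))
  expect_identical(rankEdges(g, 99), c("B|C", "A|B", "C|D"))
  # signed ranking restores the literal descending-weight reading
  expect_identical(rankEdges(g, 2, signed = TRUE), c("A|B", "C|D"))
  # ties break lexicographically
  gt <- makeGSN("I", c("B", "A"), c("C", "B"), c(0.5, 0.5))
  expect_identical(rankEdges(gt, 2), c("A|B", "B|C"))
})

test_that("edge ranking agrees with a full-sort-then-slice oracle", {
  withr::local_seed(17)
  genes <- sprintf("G%02d", 1:12)
  pool <- t(combn(genes, 2))
  for (rep in 1:5) {
    idx <- sample(nrow(pool), 30)
    w <- runif(30, -1, 1)
    g <- makeGSN("I", pool[idx, 1], pool[idx, 2], w)
    keys <- paste(pool[idx, 1], pool[idx, 2], sep = "|")
    oracle <- keys[order(-abs(w), keys)][1:10]
    expect_identical(rankEdges(g, 10), oracle)
  }
})

test_that("candidate set is the deduplicated union of per-group top edges", {
  gA <- makeGSN("I", c("A", "B"), c("B", "C"), c(0.9, 0.8))
  gB <- makeGSN("II", c("A", "B"), c("B", "C"), c(0.8, 0.9))
  expect_setequal(buildCandidateSet(list(gA, gB), 2), c("A|B", "B|C"))
  expect_length(buildCandidateSet(list(gA, gB), 2), 2L)

  gC <- makeGSN("III", c("X", "Y"), c("Y", "Z"), c(1, 1))
  expect_length(buildCandidateSet(list(gA, gC), 2), 4L)

  # random union oracle
  withr::local_seed(3)
  genes <- sprintf("G%d", 1:10)
  pool <- t(combn(genes, 2))
  gsns <- lapply(1:3, function(i) {
    idx <- sample(nrow(pool), 12)
    makeGSN(paste0("grp", i), pool[idx, 1], pool[idx, 2], runif(12, -1, 1))
  })
  got <- buildCandidateSet(gsns, 5)
  oracle <- unique(unlist(lapply(gsns, rankEdges, k = 5)))
  expect_setequal(got, oracle)
})

test_that("feature matrix is the per-sample significant delta with zero-fill", {
  ssns <- list(s1 = makeSSN("s1", "A", "B", 0.4),
               s2 = emptySSN("s2"),
               s3 = makeSSN("s3", c("A", "C"), c("B", "D"), c(-0.1, 0.9)),
               n1 = makeSSN("n1", "A", "B", 0.5))
  groups <- c(s1 = "I", s2 = "I", s3 = "II", n1 = "Normal")
  fm <- buildEdgeFeatures(c("A|B", "C|D"), ssns, groups,
                          referenceGroup = "Normal")
  v <- featureValues(fm)
  expect_identical(rownames(v), c("s1", "s2", "s3"))  # reference excluded
  expect_equal(v[, "A|B"], c(s1 = 0.4, s2 = 0, s3 = -0.1))
  expect_equal(v[, "C|D"], c(s1 = 0, s2 = 0, s3 = 0.9))
  expect_equal(unname(v["s2", ]), c(0, 0))  # all-zero row

  # per-cell lookup oracle on random instances
  withr::local_seed(23)
  genes <- sprintf("G%d", 1:8)
  pool <- t(combn(genes, 2))
  cand <- paste(pool[1:10, 1], pool[1:10, 2], sep = "|")
  rssns <- lapply(1:6, function(i) {
    idx <- sample(nrow(pool), 6)
    makeSSN(paste0("x", i), pool[idx, 1], pool[idx, 2], runif(6, -1, 1))
  })
  names(rssns) <- vapply(rssns, function(s) s@sampleId, "")
  rgroups <- setNames(rep(c("I", "II"), 3), names(rssns))
  rfm <- buildEdgeFeatures(cand, rssns, rgroups)
  rv <- featureValues(rfm)
  for (s in names(rssns)) for (k in cand) {
    e <- networkEdges(rssns[[s]])
    hit <- paste(e$geneA, e$geneB, sep = "|") == k
    expect_equal(unname(rv[s, k]), if (any(hit)) e$deltaPCC[hit] else 0)
  }
})

test_that("Gini impurity matches its closed form and bounds", {
  expect_equal(giniImpurity(c(1, 0)), 0)
  expect_equal(giniImpurity(c(0.5, 0.5)), 0.5)
  expect_equal(giniImpurity(rep(1 / 3, 3)), 2 / 3)
  expect_error(giniImpurity(c(0.6, 0.6)), "sum to 1")
  expect_error(giniImpurity(c(1.2, -0.2)), "non-negative")
  withr::local_seed(2)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    p <- runif(k); p <- p / sum(p)
    g <- giniImpurity(p)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / k + 1e-12)
  }
})

test_that("impurity gain evaluates the weighted split formula", {
  expect_equal(impurityGain(c(5, 5), c(5, 0), c(0, 5)), 0.5)
  expect_equal(impurityGain(c(6, 4), c(3, 2), c(3, 2)), 0)
  expect_equal(impurityGain(c(6, 4), c(4, 1), c(2, 3)), 0.08)
  expect_error(impurityGain(c(6, 4), c(4, 1), c(1, 3)), "sum to the parent")
})

test_that("impurity gain is non-negative on random splits", {
  withr::local_seed(41)
  for (rep in 1:2000) {
    k <- sample(2:4, 1)
    parent <- rpois(k, 5) + 1
    left <- vapply(parent, function(n) sample(0:n, 1), integer(1))
    right <- parent - left
    if (sum(left) == 0 || sum(right) == 0) next
    expect_gte(impurityGain(parent, left, right), -1e-12)
  }
})

test_that("a perfectly separating feature outranks pure-noise decoys", {
  hits <- 0
  for (seed in 1:20) {
    withr::local_seed(seed)
    n <- 40
    y <- rep(c("I", "II"), each = n / 2)
    vals <- matrix(rnorm(n * 10), n, 10,
                   dimnames = list(sprintf("s%02d", 1:n),
                                   sprintf("d|%02d", 1:10)))
    vals[, 1] <- ifelse(y == "I", rnorm(n, 3, 0.3), rnorm(n, -3, 0.3))
    fm <- makeFeatureMatrix(vals, y)
    rk <- prescreenFeatures(fm, k = 5, nTrees = 100, seed = seed)
    if (rk@ranking[1] == colnames(vals)[1]) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of runs
})

test_that("importances are non-negative and ranking is reproducible", {
  withr::local_seed(9)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("s%02d", 1:20),
                                 sprintf("e|%02d", 1:10)))
  fm <- makeFeatureMatrix(vals, rep(c("I", "II"), 10))
  r1 <- prescreenFeatures(fm, k = 10, nTrees = 50, seed = 4)
  r2 <- prescreenFeatures(fm, k = 10, nTrees = 50, seed = 4)
  expect_identical(r1@ranking, r2@ranking)
  expect_identical(importanceScores(r1), importanceScores(r2))
  expect_true(all(importanceScores(r1) >= 0))
  expect_error(prescreenFeatures(makeFeatureMatrix(vals, rep("I", 20)), 5),
               ">= 2 groups")
})

test_that("a single depth-1 tree's importance equals its split's impurity
           gain", {
  # one feature, forced full-sample single split: the reported importance
  # (per-sample Gini decrease) must equal impurityGain of that split
  withr::local_seed(5)
  y <- rep(c("I", "II"), c(6, 4))
  vals <- matrix(c(rnorm(6, -2, 0.1), rnorm(4, 2, 0.1)), ncol = 1,
                 dimnames = list(sprintf("s%02d", 1:10), "a|b"))
  fm <- makeFeatureMatrix(vals, y)
  rk <- prescreenFeatures(fm, k = 1, nTrees = 1, seed = 5, mtry = 1,
                          max.depth = 1, replace = FALSE,
                          sample.fraction = 1)
  expect_equal(unname(importanceScores(rk)),
               impurityGain(c(6, 4), c(6, 0), c(0, 4)), tolerance = 1e-12)
})
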