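# Reference network, perturbed correlations, and the per-sample
# differential-correlation test.

test_that("reference correlations reproduce textbook Pearson values", {
  m <- rbind(g1 = c(1, 2, 3, 4, 9),
             g2 = c(2, 4, 6, 8, 7),
             g3 = c(4, 3, 2, 1, 5))
  colnames(m) <- sprintf("s%d", 1:5)
  lab <- GroupLabels(setNames(c(rep("Normal", 4), "I"), colnames(m)),
                     "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  ref <- buildReferenceNetwork(gse, data.frame(a = c("g1", "g1"),
                                               b = c("g2", "g3")))
  e <- networkEdges(ref)
  expect_equal(e$pcc[match("g1|g2", edgeKeys(ref))], 1)
  expect_equal(e$pcc[match("g1|g3", edgeKeys(ref))], -1)
  expect_identical(ref@nRef, 4L)
})

test_that("reference correlations match the direct formula on random data", {
  withr::local_seed(5)
  n <- 8
  m <- matrix(rnorm(10 * (n + 2)), 10, n + 2,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("s%02d", 1:(n + 2))))
  lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(n, 2)), colnames(m)),
                     "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  pairs <- allGenePairs(gse)
  ref <- buildReferenceNetwork(gse, pairs)
  e <- networkEdges(ref)
  for (i in seq_len(nrow(e))) {
    x <- m[e$geneA[i], 1:n]; y <- m[e$geneB[i], 1:n]
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (sd(x) * sd(y) * (n - 1) / n)  # covariance over sigma-sigma
    expect_equal(e$pcc[i], oracle, tolerance = 1e-12)
  }
})

test_that("zero-variance pairs are flagged undefined with a warning", {
  m <- rbind(gFlat = c(5, 5, 5, 5, 1),
             gVar = c(1, 2, 3, 4, 2))
  colnames(m) <- sprintf("s%d", 1:5)
  lab <- GroupLabels(setNames(c(rep("Normal", 4), "I"), colnames(m)),
                     "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  expect_warning(
    ref <- buildReferenceNetwork(gse, data.frame(a = "gFlat", b = "gVar")),
    "zero variance")
  expect_true(is.na(networkEdges(ref)$pcc[1]))
})

test_that("perturbed correlation equals from-scratch Pearson on the
           concatenated vectors", {
  withr::local_seed(21)
  nRef <- 12
  reps <- 200  # instances: pairs x samples per repetition below
  m <- matrix(rnorm(20 * (nRef + 5), mean = 50, sd = 10), 20, nRef + 5,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%02d", 1:(nRef + 5))))
  lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(nRef, 5)),
                              colnames(m)), "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  pairs <- allGenePairs(gse)[1:40, ]
  ref <- buildReferenceNetwork(gse, pairs)
  e <- networkEdges(ref)
  refIds <- referenceSamples(gse)
  for (s in diseaseSamples(gse)) {
    got <- perturbedPCC(ref, gse, s)
    idx <- sample(nrow(e), min(reps, nrow(e)))
    for (i in idx) {
      oracle <- cor(c(m[e$geneA[i], refIds], m[e$geneA[i], s]),
                    c(m[e$geneB[i], refIds], m[e$geneB[i], s]))
      expect_equal(got[i], oracle, tolerance = 1e-10)
    }
  }
})

test_that("collinearity is preserved when the new sample lies on the line", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5),
             g2 = c(2, 4, 6, 8, 10))
  colnames(m) <- sprintf("s%d", 1:5)
  lab <- GroupLabels(setNames(c(rep("Normal", 4), "I"), colnames(m)),
                     "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  ref <- buildReferenceNetwork(gse, data.frame(a = "g1", b = "g2"))
  expect_equal(perturbedPCC(ref, gse, "s5"), 1)
  ssn <- buildSSN(ref, gse, "s5")
  expect_identical(nrow(networkEdges(ssn)), 0L)  # deltaPCC = 0, never significant
})

test_that("negating one gene flips the sign of every correlation quantity", {
  withr::local_seed(33)
  nRef <- 10
  m <- matrix(rnorm(4 * (nRef + 1)), 4, nRef + 1,
              dimnames = list(sprintf("g%d", 1:4),
                              sprintf("s%02d", 1:(nRef + 1))))
  lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(nRef, 1)),
                              colnames(m)), "Normal")
  gse <- GSNExperiment(m, lab, unit = "normalized")
  m2 <- m; m2["g1", ] <- -m2["g1", ]
  gse2 <- GSNExperiment(m2, lab, unit = "normalized")
  pairs <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  ref1 <- buildReferenceNetwork(gse, pairs)
  ref2 <- buildReferenceNetwork(gse2, pairs)
  i <- match("g1|g2", edgeKeys(ref1))
  j <- match("g2|g3", edgeKeys(ref1))
  expect_equal(networkEdges(ref2)$pcc[i], -networkEdges(ref1)$pcc[i])
  expect_equal(networkEdges(ref2)$pcc[j], networkEdges(ref1)$pcc[j])
  p1 <- perturbedPCC(ref1, gse, "s11")
  p2 <- perturbedPCC(ref2, gse2, "s11")
  expect_equal(p2[i], -p1[i])
  expect_equal(p2[j], p1[j])
})

test_that("SSN edge filter honours alpha and the delta bound", {
  gse <- makeTinyExperiment(nGenes = 8, nNormal = 8, nDisease = 2)
  pairs <- allGenePairs(gse)
  ref <- buildReferenceNetwork(gse, pairs)
  s <- diseaseSamples(gse)[1]
  # alpha = 0 admits nothing (no p-value is < 0)
  ssnNone <- buildSSN(ref, gse, s, alpha = .Machine$double.xmin)
  expect_identical(nrow(networkEdges(ssnNone)), 0L)
  # every stored delta lies in [-2, 2] and every stored p < alpha
  ssn <- buildSSN(ref, gse, s, alpha = 0.5)
  e <- networkEdges(ssn)
  expect_true(all(abs(e$deltaPCC) <= 2))
  expect_true(all(e$pValue < 0.5))
  # reference samples never receive SSNs
  expect_error(buildSSN(ref, gse, referenceSamples(gse)[1]),
               "non-reference")
})

test_that("batch SSN construction agrees with one-at-a-time construction", {
  gse <- makeTinyExperiment(nGenes = 7, nNormal = 9, nDisease = 3)
  pairs <- allGenePairs(gse)
  ref <- buildReferenceNetwork(gse, pairs)
  batch <- buildAllSSNs(gse, pairs)
  for (s in diseaseSamples(gse)) {
    single <- buildSSN(ref, gse, s)
    expect_identical(networkEdges(batch[[s]]), networkEdges(single))
  }
})

test_that("the edge test holds its size under the null", {
  # one null disease sample against 40 reference samples, disjoint pairs
  withr::local_seed(77)
  nRef <- 40; nPairs <- 60; reps <- 25
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    m <- matrix(rnorm(2 * nPairs * (nRef + 1)), 2 * nPairs, nRef + 1)
    rownames(m) <- sprintf("g%03d", seq_len(2 * nPairs))
    colnames(m) <- sprintf("s%03d", seq_len(nRef + 1))
    lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(nRef, 1)),
                                colnames(m)), "Normal")
    gse <- GSNExperiment(m, lab, unit = "normalized")
    pairs <- data.frame(a = rownames(m)[seq(1, 2 * nPairs, 2)],
                        b = rownames(m)[seq(2, 2 * nPairs, 2)])
    ref <- buildReferenceNetwork(gse, pairs)
    ssn <- buildSSN(ref, gse, sprintf("s%03d", nRef + 1), alpha = 0.05)
    hits <- hits + nrow(networkEdges(ssn))
    total <- total + nPairs
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_gt(rate, 0.05 - 3 * se)
  expect_lt(rate, 0.05 + 3 * se)
})
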