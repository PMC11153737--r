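# Input parsing, validation, and the CPM low-expression filter.

test_that("expression matrix round-trips through TSV unchanged", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t10\t0", "g2\t5\t7"), tf)
  se <- readExpressionMatrix(tf)
  expect_identical(dimnames(SummarizedExperiment::assay(se)),
                   list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(SummarizedExperiment::assay(se)),
               matrix(c(10, 5, 0, 7), 2, 2))
  expect_identical(S4Vectors::metadata(se)$unit, "counts")

  # write-then-read a random matrix: bitwise equality
  withr::local_seed(7)
  m <- matrix(round(runif(200, 0, 1e4), 3), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%02d", 1:10)))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, tf2)
  back <- SummarizedExperiment::assay(readExpressionMatrix(tf2))
  expect_identical(back, m)
})

test_that("malformed expression input is rejected with a located error", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t10\t0", "g1\t5\t7"), tf)
  expect_error(readExpressionMatrix(tf), "duplicated gene")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t10\tx!", "g2\t5\t7"), tf2)
  expect_error(readExpressionMatrix(tf2), "g1.*s2")
})

test_that("PPI reading canonicalizes, deduplicates and thresholds", {
  tf <- withr::local_tempfile()
  writeLines(c("A B 900", "B A 900", "C C 100"), tf)
  ppi <- readPPIEdges(tf)
  expect_equal(nrow(ppiEdges(ppi)), 1L)
  expect_identical(edgeKeys(ppi), "A|B")

  tf2 <- withr::local_tempfile()
  writeLines(c("A B 100", "A C 700"), tf2)
  expect_identical(edgeKeys(readPPIEdges(tf2, scoreMin = 400)), "A|C")

  # header auto-detection (STRING dialect)
  tf3 <- withr::local_tempfile()
  writeLines(c("protein1 protein2 combined_score", "P1 P2 800"), tf3)
  expect_identical(edgeKeys(readPPIEdges(tf3)), "P1|P2")

  tf4 <- withr::local_tempfile()
  writeLines(c("A B 900", "A"), tf4)
  expect_error(readPPIEdges(tf4), "fewer than 2")
})

test_that("random PPI files match a brute-force set-of-sets oracle", {
  withr::local_seed(42)
  for (rep in 1:5) {
    genes <- sprintf("G%d", 1:12)
    a <- sample(genes, 50, replace = TRUE)
    b <- sample(genes, 50, replace = TRUE)
    tf <- withr::local_tempfile()
    writeLines(paste(a, b), tf)
    ppi <- readPPIEdges(tf)
    # oracle: unordered-pair strings, self-loops dropped, unique
    oracle <- unique(vapply(seq_along(a), function(i)
      paste(sort(c(a[i], b[i])), collapse = "|"), ""))
    oracle <- oracle[vapply(strsplit(oracle, "|", fixed = TRUE),
                            function(p) p[1] != p[2], logical(1))]
    expect_setequal(edgeKeys(ppi), oracle)
    # round-trip reproduces the identical canonical edge set
    tf2 <- withr::local_tempfile()
    writePPIEdges(ppi, tf2)
    expect_identical(edgeKeys(readPPIEdges(tf2)), edgeKeys(ppi))
  }
})

test_that("identifier mapping is applied to the PPI before analysis", {
  tf <- withr::local_tempfile()
  writeLines(c("9606.ENSP1 9606.ENSP2 500"), tf)
  mapping <- data.frame(from = c("9606.ENSP1", "9606.ENSP2"),
                        to = c("TP53", "MDM2"))
  expect_identical(edgeKeys(readPPIEdges(tf, mapping = mapping)),
                   "MDM2|TP53")
})

test_that("group label reading validates reference and duplicates", {
  tf <- withr::local_tempfile()
  writeLines(c("s1\tNormal", "s2\tNormal", "s3\tNormal", "s4\tI"), tf)
  lab <- readGroupLabels(tf, "Normal")
  expect_length(sampleGroups(lab), 4L)
  expect_identical(referenceGroup(lab), "Normal")

  expect_error(readGroupLabels(tf, "Healthy"), "absent")

  tf2 <- withr::local_tempfile()
  writeLines(c("s1\tI", "s1\tII", "s2\tNormal"), tf2)
  expect_error(readGroupLabels(tf2, "Normal"), "conflicting")
})

test_that("unlabelled samples are dropped with a warning, missing ones error", {
  m <- matrix(rpois(12, 50), 2, 6,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  lab <- GroupLabels(setNames(rep(c("Normal", "I"), c(3, 2)),
                              sprintf("s%d", 1:5)), "Normal")
  expect_warning(gse <- GSNExperiment(m, lab), "unlabelled")
  expect_identical(colnames(gse), sprintf("s%d", 1:5))

  lab2 <- GroupLabels(setNames(rep(c("Normal", "I"), c(3, 4)),
                               sprintf("s%d", 1:7)), "Normal")
  expect_error(GSNExperiment(m, lab2), "absent from the expression matrix")
})

test_that("cpmFilter implements the strict-CPM / at-least-fraction rule", {
  # all-zero gene always removed; boundary: 1 of 2 samples >= 0.5 * 2
  m <- matrix(c(10, 0,
                0, 0,
                990, 1000), 3, 2, byrow = TRUE,
              dimnames = list(c("gKeep", "gZero", "gBig"),
                              c("s1", "s2")))
  kept <- cpmFilter(m, threshold = 2, fraction = 0.5)
  expect_identical(rownames(kept), c("gKeep", "gBig"))
  # retained values unchanged
  expect_identical(kept["gKeep", ], m["gKeep", ])

  expect_error(cpmFilter(matrix(0, 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2")))),
               "zero library size.*s1")
})

test_that("cpmFilter matches a two-loop oracle and is idempotent", {
  withr::local_seed(99)
  for (rep in 1:5) {
    m <- matrix(rpois(240, 30), 30, 8,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("s%d", 1:8)))
    thr <- sample(c(1, 2, 5), 1)
    keep <- cpmFilter(m, threshold = thr, fraction = 0.5)
    # independent two-loop recomputation of the rule
    oracle <- character()
    for (g in rownames(m)) {
      hits <- 0
      for (s in colnames(m))
        if (m[g, s] / sum(m[, s]) * 1e6 > thr) hits <- hits + 1
      if (hits >= 0.5 * ncol(m)) oracle <- c(oracle, g)
    }
    expect_identical(rownames(keep), oracle)
    expect_identical(cpmFilter(keep, threshold = thr, fraction = 0.5), keep)
  }
})

test_that("cpmFilter refuses non-count units", {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = matrix(1, 1, 1, dimnames = list("g", "s"))),
    metadata = list(unit = "normalized"))
  expect_error(cpmFilter(se), "count data only")
})
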