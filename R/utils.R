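# Internal helpers: canonical gene-pair handling, seeded RNG isolation,
# stratified fold assignment, and the product-normal tail probability used
# by the delta-PCC significance test.

#' @importFrom stats cor pnorm dnorm predict rnorm runif var setNames
#' @importFrom utils read.delim write.table head
NULL

# Canonicalize unordered gene pairs: geneA < geneB lexicographically.
# Accepts two character vectors; returns data.frame(geneA, geneB).
.canonicalPairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(geneA = a, geneB = b, stringsAsFactors = FALSE)
}

.pairKey <- function(a, b) paste(a, b, sep = "|")

.splitKey <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(geneA = vapply(parts, `[`, "", 1L),
             geneB = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Coerce a pair specification (PPINetwork, data.frame/matrix with two
# columns, or character vector of keys) to a canonical pair data.frame.
.asPairs <- function(pairs) {
  if (is(pairs, "PPINetwork")) return(ppiEdges(pairs)[, c("geneA", "geneB")])
  if (is.character(pairs) && is.null(dim(pairs))) return(.splitKey(pairs))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L)
    stop("pair specification needs two gene-identifier columns")
  .canonicalPairs(pairs[[1L]], pairs[[2L]])
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All randomized steps in the pipeline flow through this.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic derived seeds (kept below 2^31).
.deriveSeed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + salt * 104729) %% 2147483647)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds, so fold class counts differ by at most one.
.stratifiedFolds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k))
    stop("class '", names(which(table(y) < k))[1L], "' has fewer than ", k,
         " samples; reduce the number of folds")
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Two-sided tail probability of the product of two independent standard
# normals: P(|N1 * N2| >= z).  This is the asymptotic null of the scaled
# delta-PCC statistic (see the methods vignette).  Computed by 512-node
# Gauss-Legendre quadrature of 4 * integral_0^Inf phi(a) Phi(-z/a) da;
# nodes are cached per session.
.prodNormalCache <- new.env(parent = emptyenv())

.pProductNormal <- function(z) {
  if (is.null(.prodNormalCache$nodes)) {
    gl <- pracma::gaussLegendre(512L, 0, 12)
    .prodNormalCache$nodes <- gl$x
    .prodNormalCache$weights <- gl$w * stats::dnorm(gl$x)
  }
  z <- abs(z)
  a <- .prodNormalCache$nodes
  w <- .prodNormalCache$weights
  out <- vapply(z, function(zz) {
    if (!is.finite(zz)) return(NA_real_)
    4 * sum(w * stats::pnorm(-zz / a))
  }, numeric(1))
  pmin(pmax(out, 0), 1)
}
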