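# Synthetic expression / label / PPI generator with planted
# group-specific co-expression rewiring, so every stage of the pipeline
# is testable without external data.

#' Specification of a synthetic dataset
#'
#' Describes a multi-group count dataset generated from a Gaussian copula:
#' latent per-group multivariate-normal log-expression with background
#' pairwise correlation `baseCorr`.  Each planted gene pair is a strongly
#' co-expressed interaction partner: its latent correlation is
#' `baseCorr + deltaR` in the reference group and in every non-target
#' group, and drops to `baseCorr` in its target (disease) group --- the
#' planted signal is the group-specific *loss* of a normal co-expression
#' edge, the configuration a single-sample correlation perturbation can
#' actually detect (see the methods vignette).  The reference group
#' carries no group-specific rewiring by construction.  Latent values map
#' to counts by exponentiation and library-size scaling.  The PPI consists
#' of the planted pairs plus random decoy pairs.
#'
#' @slot nGenes Number of genes.
#' @slot groupSizes Named integer vector of samples per group; the first
#'   name is used as the reference unless `referenceGroup` says otherwise.
#' @slot referenceGroup Name of the reference (normal) group.
#' @slot plantedEdges data.frame `geneA`, `geneB`, `group`, `deltaR`:
#'   the pairs whose co-expression (`baseCorr + deltaR` elsewhere) is lost
#'   (dropping to `baseCorr`) in the named group.
#' @slot baseCorr Background pairwise latent correlation.
#' @slot noiseSd Lognormal sigma of the latent log-expression.
#' @slot ppiDensity Fraction of all gene pairs included as decoy PPI
#'   edges.
#' @slot libSizeMean Mean library size of the scaled counts.
#' @seealso [simulationSpec()], [simulateGSNData()]
#' @export
setClass("SimulationSpec",
  representation(nGenes = "integer", groupSizes = "integer",
                 referenceGroup = "character", plantedEdges = "data.frame",
                 baseCorr = "numeric", noiseSd = "numeric",
                 ppiDensity = "numeric", libSizeMean = "numeric"))

setValidity("SimulationSpec", function(object) {
  if (object@nGenes < 4L) return("nGenes must be >= 4")
  if (is.null(names(object@groupSizes)) || length(object@groupSizes) < 2L)
    return("groupSizes must be a named vector with >= 2 groups")
  if (any(object@groupSizes < 1L)) return("all group sizes must be positive")
  if (!object@referenceGroup %in% names(object@groupSizes))
    return("referenceGroup must be one of the groups")
  pe <- object@plantedEdges
  if (nrow(pe)) {
    if (!all(c("geneA", "geneB", "group", "deltaR") %in% names(pe)))
      return("plantedEdges needs columns geneA, geneB, group, deltaR")
    if (any(pe$group == object@referenceGroup))
      return("planted edges must target non-reference groups")
    if (any(abs(object@baseCorr + pe$deltaR) > 0.99))
      return("|baseCorr + deltaR| must be <= 0.99")
  }
  if (abs(object@baseCorr) > 0.99) return("|baseCorr| must be <= 0.99")
  if (object@ppiDensity < 0 || object@ppiDensity > 1)
    return("ppiDensity must lie in [0, 1]")
  if (object@noiseSd <= 0 || object@libSizeMean <= 0)
    return("noiseSd and libSizeMean must be positive")
  TRUE
})

#' Construct a simulation specification
#'
#' Defaults mirror a multi-stage tumour/normal design at desk scale: one
#' reference group and four disease groups with imbalanced sizes, a weak
#' background co-expression, and a PPI dominated by decoy edges.
#'
#' @param nGenes Number of genes (default 40).
#' @param groupSizes Named vector of samples per group; default
#'   `c(Normal = 23, I = 105, II = 47, III = 32, IV = 10)`.
#' @param referenceGroup Reference group name (default the first of
#'   `groupSizes`).
#' @param plantedEdges Either an integer number of planted pairs (they are
#'   then assigned to distinct genes and dealt round-robin across the
#'   non-reference groups with shift `deltaR`), or a data.frame `geneA`,
#'   `geneB`, `group`, `deltaR`.  Default 5.
#' @param deltaR Correlation shift of integer-specified planted pairs
#'   (default 0.8).
#' @param baseCorr Background latent correlation (default 0.1).
#' @param noiseSd Lognormal sigma of latent log-expression (default 0.5).
#' @param ppiDensity Fraction of gene pairs added as decoy PPI edges
#'   (default 0.25).
#' @param libSizeMean Mean library size (default 1e5).
#' @return A [SimulationSpec-class].
#' @examples
#' simulationSpec(nGenes = 12, groupSizes = c(Normal = 10, A = 8, B = 8))
#' @export
simulationSpec <- function(nGenes = 40L,
                           groupSizes = c(Normal = 23L, I = 105L, II = 47L,
                                          III = 32L, IV = 10L),
                           referenceGroup = names(groupSizes)[1L],
                           plantedEdges = 5L, deltaR = 0.8,
                           baseCorr = 0.1, noiseSd = 0.5,
                           ppiDensity = 0.25, libSizeMean = 1e5) {
  genes <- sprintf("g%03d", seq_len(nGenes))
  if (is.numeric(plantedEdges) && length(plantedEdges) == 1L) {
    nPlant <- as.integer(plantedEdges)
    if (2L * nPlant > nGenes)
      stop("not enough genes for ", nPlant, " disjoint planted pairs")
    targets <- setdiff(names(groupSizes), referenceGroup)
    plantedEdges <- if (nPlant == 0L) {
      data.frame(geneA = character(), geneB = character(),
                 group = character(), deltaR = numeric())
    } else {
      pairs <- .canonicalPairs(genes[seq(1L, 2L * nPlant, by = 2L)],
                               genes[seq(2L, 2L * nPlant, by = 2L)])
      data.frame(pairs,
                 group = rep_len(targets, nPlant),
                 deltaR = deltaR)
    }
  } else {
    plantedEdges <- data.frame(
      .canonicalPairs(plantedEdges$geneA, plantedEdges$geneB),
      group = as.character(plantedEdges$group),
      deltaR = as.numeric(plantedEdges$deltaR))
  }
  new("SimulationSpec", nGenes = as.integer(nGenes),
      groupSizes = stats::setNames(as.integer(groupSizes),
                                   names(groupSizes)),
      referenceGroup = as.character(referenceGroup),
      plantedEdges = plantedEdges, baseCorr = baseCorr, noiseSd = noiseSd,
      ppiDensity = ppiDensity, libSizeMean = libSizeMean)
}

# Per-group latent correlation matrix: background baseCorr; planted pairs
# coupled at baseCorr + deltaR except in their target group, where the
# coupling is lost (back to baseCorr).  Repaired to the nearest
# positive-definite matrix when planting leaves a tiny eigenvalue deficit,
# rejected otherwise.
.groupCorrelation <- function(spec, group, genes) {
  R <- matrix(spec@baseCorr, spec@nGenes, spec@nGenes,
              dimnames = list(genes, genes))
  diag(R) <- 1
  pe <- spec@plantedEdges
  pe <- pe[pe$group != group, , drop = FALSE]  # intact couplings here
  for (i in seq_len(nrow(pe))) {
    r <- spec@baseCorr + pe$deltaR[i]
    R[pe$geneA[i], pe$geneB[i]] <- r
    R[pe$geneB[i], pe$geneA[i]] <- r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    if (min(ev) > -1e-6) {
      warning("correlation matrix repaired to nearest positive definite ",
              "for group ", group)
      R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    } else {
      stop("planted correlation matrix for group ", group,
           " is not positive definite; use a smaller deltaR")
    }
  }
  R
}

#' Generate a synthetic dataset with planted co-expression rewiring
#'
#' Draws per-group latent multivariate-normal log-expression (see
#' [simulationSpec()]), maps it to non-negative integer counts via
#' exponentiation and library-size scaling, and assembles the three
#' pipeline inputs plus the ground truth of planted edges.
#'
#' @param spec A [SimulationSpec-class].
#' @param seed RNG seed; the output is fully reproducible from it.
#' @return A list: `experiment` ([GSNExperiment-class] of counts),
#'   `labels` ([GroupLabels-class]), `ppi` ([PPINetwork-class]:
#'   planted pairs plus decoys), and `groundTruth` (the planted-edge
#'   data.frame).
#' @examples
#' sim <- simulateGSNData(simulationSpec(nGenes = 10,
#'   groupSizes = c(Normal = 10, A = 6)), seed = 1)
#' sim$experiment
#' @export
simulateGSNData <- function(spec = simulationSpec(), seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"))
  genes <- sprintf("g%03d", seq_len(spec@nGenes))
  .withSeed(seed, {
    # per-gene baseline log-expression, shared by all groups
    mu <- stats::runif(spec@nGenes, log(20), log(500))
    counts <- NULL; groups <- character()
    for (g in names(spec@groupSizes)) {
      n <- spec@groupSizes[[g]]
      R <- .groupCorrelation(spec, g, genes)
      Z <- MASS::mvrnorm(n, mu = rep(0, spec@nGenes), Sigma = R)
      if (n == 1L) Z <- matrix(Z, nrow = 1L)
      expr <- exp(sweep(spec@noiseSd * t(Z), 1L, mu, `+`))  # genes x n
      libFactor <- exp(stats::rnorm(n, 0, 0.1))
      scale <- spec@libSizeMean / mean(colSums(expr))
      cnt <- round(sweep(expr * scale, 2L, libFactor, `*`))
      counts <- cbind(counts, cnt)
      groups <- c(groups, rep(g, n))
    }
    colnames(counts) <- sprintf("s%04d", seq_len(ncol(counts)))
    rownames(counts) <- genes
    labels <- GroupLabels(stats::setNames(groups, colnames(counts)),
                          spec@referenceGroup)
    # PPI: planted pairs plus decoys sampled from the remaining pairs
    allPairs <- t(utils::combn(genes, 2L))
    keys <- .pairKey(allPairs[, 1L], allPairs[, 2L])
    planted <- .pairKey(spec@plantedEdges$geneA, spec@plantedEdges$geneB)
    decoyPool <- which(!keys %in% planted)
    nDecoy <- round(spec@ppiDensity * length(keys))
    decoys <- sample(decoyPool, min(nDecoy, length(decoyPool)))
    sel <- unique(c(which(keys %in% planted), decoys))
    ppi <- PPINetwork(allPairs[sel, 1L], allPairs[sel, 2L])
    list(experiment = GSNExperiment(counts, labels),
         labels = labels, ppi = ppi,
         groundTruth = spec@plantedEdges)
  })
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", object@nGenes, "genes;",
      sum(object@groupSizes), "samples in", length(object@groupSizes),
      "groups (reference:", object@referenceGroup, ");",
      nrow(object@plantedEdges), "planted edges\n")
})
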