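# Reading and writing the three input tables, and CPM-based
# low-expression filtering.

#' Read a gene x sample expression matrix
#'
#' Reads a tab-separated table whose first column holds gene identifiers
#' and whose header row holds sample identifiers.
#'
#' @param path Path to the TSV file.
#' @param unit Unit tag for the values: `"counts"` (default), `"cpm"` or
#'   `"normalized"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   and `metadata()$unit` set; combine with labels via [GSNExperiment()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t10\t0", "g2\t5\t7"), tf)
#' se <- readExpressionMatrix(tf)
#' SummarizedExperiment::assay(se)
#' @export
readExpressionMatrix <- function(path, unit = "counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs gene ids plus >= 1 sample column")
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("duplicated gene identifier(s): ",
         paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(vals) && !anyNA(body)) {
    bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed numeric cell at gene '%s', sample '%s': '%s'",
                 genes[bad[1L]], colnames(body)[bad[2L]],
                 body[bad[1L], bad[2L]]))
  }
  dimnames(vals) <- list(genes, colnames(body))
  if (anyDuplicated(colnames(vals))) stop("duplicated sample identifiers")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = vals), metadata = list(unit = unit))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]: first column `gene`, header row the
#' sample identifiers.
#'
#' @param x A `SummarizedExperiment`/[GSNExperiment-class] or a numeric
#'   matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x) else x
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels
#'
#' Reads a two-column tab-separated table (`sample_id`, `group`), with or
#' without a header row (detected by the literal column names).
#'
#' @param path Path to the TSV file.
#' @param referenceGroup Name of the reference (normal) group; must occur
#'   in the table.
#' @return A [GroupLabels-class] object.
#' @export
readGroupLabels <- function(path, referenceGroup) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  hasHeader <- length(first) >= 2L &&
    tolower(first[1L]) %in% c("sample", "sample_id", "sampleid")
  tab <- utils::read.delim(path, header = hasHeader, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label table needs two columns: sample_id, group")
  ids <- tab[[1L]]; grp <- tab[[2L]]
  dup <- duplicated(ids)
  if (any(dup)) {
    conflict <- vapply(unique(ids[dup]), function(s)
      length(unique(grp[ids == s])) > 1L, logical(1))
    if (any(conflict))
      stop("sample(s) listed with conflicting groups: ",
           paste(names(conflict)[conflict][1:3], collapse = ", "))
    grp <- grp[!dup]; ids <- ids[!dup]
  }
  if (!referenceGroup %in% grp)
    stop("reference group '", referenceGroup, "' absent from the label table")
  GroupLabels(stats::setNames(grp, ids), referenceGroup)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a whitespace-separated edge list in the STRING physical-links
#' dialect: two identifier columns plus an optional score column, with an
#' optional single header row (auto-detected).  Edges are undirected:
#' duplicates (in either orientation) and self-loops are dropped, and pairs
#' are canonicalized.
#'
#' @param path Path to the edge-list file.
#' @param scoreMin Drop edges whose score is below this value (default 0;
#'   edges without a score column are always kept).
#' @param mapping Optional identifier mapping applied to the PPI before
#'   canonicalization, as a two-column data.frame (`from`, `to`) or path to
#'   such a TSV; unmapped identifiers are kept as-is.
#' @return A [PPINetwork-class] object.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A B 900", "B A 900", "C C 100"), tf)
#' readPPIEdges(tf)
#' @export
readPPIEdges <- function(path, scoreMin = 0, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PPI file: ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("PPI row ", which(nf < 2L)[1L], " has fewer than 2 columns")
  # header heuristic: a first row whose third field is non-numeric, or
  # whose identifier fields look like column names
  f1 <- fields[[1L]]
  isHeader <- (length(f1) >= 3L &&
                 is.na(suppressWarnings(as.numeric(f1[3L])))) ||
    any(grepl("^(protein|gene|node|item)", tolower(f1[1:2])))
  if (isHeader) fields <- fields[-1L]
  if (!length(fields)) stop("PPI file contains only a header: ", path)
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  score <- vapply(fields, function(f)
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_,
    numeric(1))
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L)
      mapping <- utils::read.delim(mapping, header = FALSE,
                                   colClasses = "character")
    map <- stats::setNames(as.character(mapping[[2L]]),
                           as.character(mapping[[1L]]))
    a <- ifelse(a %in% names(map), map[a], a)
    b <- ifelse(b %in% names(map), map[b], b)
  }
  keep <- is.na(score) | score >= scoreMin
  PPINetwork(a[keep], b[keep], score[keep])
}

#' Write a PPI edge list
#'
#' @param ppi A [PPINetwork-class] object.
#' @param path Output path; written space-separated as `geneA geneB
#'   [score]`.
#' @return `path`, invisibly.
#' @export
writePPIEdges <- function(ppi, path) {
  e <- ppiEdges(ppi)
  if (all(is.na(e$score))) {
    writeLines(paste(e$geneA, e$geneB), path)
  } else {
    writeLines(paste(e$geneA, e$geneB, e$score), path)
  }
  invisible(path)
}

#' Filter low-expression genes by counts per million
#'
#' Retains genes whose CPM exceeds `threshold` (strictly) in at least
#' `fraction` of the samples; CPM(g, s) = counts(g, s) / librarySize(s) x
#' 1e6.  The sample set and all retained values are unchanged.  Applies
#' only to count data.
#'
#' @param x A [GSNExperiment-class] (or `SummarizedExperiment` with
#'   `metadata()$unit == "counts"`), or a numeric count matrix.
#' @param threshold CPM cutoff (default 2).
#' @param fraction Minimum fraction of samples above the cutoff
#'   (default 0.5); the count comparison is `>= fraction * nSamples`.
#' @return The input object with low-expression gene rows removed.
#' @examples
#' m <- matrix(c(10, 0, 990, 1000), 2, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rownames(cpmFilter(m))
#' @export
cpmFilter <- function(x, threshold = 2, fraction = 0.5) {
  m <- if (is(x, "SummarizedExperiment")) {
    unit <- S4Vectors::metadata(x)$unit
    if (!is.null(unit) && unit != "counts")
      stop("cpmFilter applies to count data only (unit is '", unit, "')")
    SummarizedExperiment::assay(x)
  } else as.matrix(x)
  libSize <- colSums(m)
  if (any(libSize <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m)[libSize <= 0][1:3], collapse = ", "))
  cpm <- edgeR::cpm(m)
  keep <- rowSums(cpm > threshold) >= fraction * ncol(m)
  x[keep, ]
}
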