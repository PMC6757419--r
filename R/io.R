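## Readers and writers for the on-disk dialects: association edge lists,
## labeled similarity matrices, DAG edge lists, score tables and ranked
## prediction lists. All files are TSV; lines starting with '#' are
## comments.

.readLinesNoComment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep), all = lines)
}

.splitFields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a miRNA-disease association edge list
#'
#' The file is a two-column TSV (`miRNA_id`, `disease_id`), one known
#' association per row; an optional header row and `#` comment lines are
#' allowed. Duplicate rows collapse to a single association. Identifier
#' order is first-appearance order unless the file carries the
#' `## mirnas:` / `## diseases:` directives written by
#' [writeAssociationTable()], which pin the exact orders (needed to
#' round-trip matrices with label orders that no edge ordering can
#' encode).
#'
#' @param path path to the TSV edge list.
#' @return An [AssociationMatrix-class].
#' @export
readAssociationTable <- function(path) {
  parsed <- .readLinesNoComment(path)
  if (!length(parsed$lines)) stop("empty association file: ", path)
  fields <- .splitFields(parsed$lines)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("malformed association row at line %d of %s: expected 2 fields, got %d",
                 parsed$lineno[bad[1L]], path, lengths(fields)[bad[1L]]))
  m <- vapply(fields, `[`, character(1), 1L)
  d <- vapply(fields, `[`, character(1), 2L)
  ## optional header: drop a first row naming the columns
  if (length(m) && grepl("mirna", m[1L], ignore.case = TRUE) &&
      grepl("disease", d[1L], ignore.case = TRUE)) {
    m <- m[-1L]; d <- d[-1L]
  }
  if (!length(m)) stop("association file contains no data rows: ", path)
  mids <- unique(m); dids <- unique(d)
  dir1 <- grep("^##\\s*mirnas:", parsed$all, value = TRUE)
  dir2 <- grep("^##\\s*diseases:", parsed$all, value = TRUE)
  if (length(dir1) == 1L && length(dir2) == 1L) {
    pull <- function(x, tag) strsplit(sub(tag, "", x), "\t", fixed = TRUE)[[1L]]
    fullM <- pull(dir1, "^##\\s*mirnas:\\s*")
    fullD <- pull(dir2, "^##\\s*diseases:\\s*")
    if (!all(mids %in% fullM) || !all(dids %in% fullD))
      stop("label directives in ", path, " do not cover all listed pairs")
    mids <- fullM; dids <- fullD
  }
  a <- matrix(0, length(mids), length(dids), dimnames = list(mids, dids))
  a[cbind(m, d)] <- 1
  AssociationMatrix(a)
}

#' Write a miRNA-disease association edge list
#'
#' Writes one row per known association plus `## mirnas:` and
#' `## diseases:` comment directives recording the full ordered label
#' lists, so [readAssociationTable()] reproduces the matrix exactly
#' (values and label orders).
#'
#' @param assoc an [AssociationMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssociationTable <- function(assoc, path) {
  a <- as.matrix(assoc)
  idx <- which(t(a) == 1, arr.ind = TRUE)  # row-major pair order
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("## mirnas:\t", paste(rownames(a), collapse = "\t")),
               paste0("## diseases:\t", paste(colnames(a), collapse = "\t")),
               "#miRNA_id\tdisease_id"), con)
  if (nrow(idx))
    writeLines(paste(rownames(a)[idx[, 2L]], colnames(a)[idx[, 1L]],
                     sep = "\t"), con)
  invisible(path)
}

#' Read a labeled similarity matrix
#'
#' The file is a TSV with row and column labels (first header cell
#' ignored); row and column label sets must match. Columns are re-ordered
#' to the row-label order. Small asymmetries (at most 1e-8) are averaged
#' away as \eqn{(M + M^T)/2}; larger ones are an error.
#'
#' @param path path to the TSV matrix.
#' @param kind kind tag for the result (see [SimilarityMatrix-class]).
#' @return A [SimilarityMatrix-class], exactly symmetric.
#' @export
readSimilarityMatrix <- function(path, kind = "functional") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE,
                   comment.char = "#")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("similarity matrix in %s is not square (%d x %d)",
                 path, nrow(m), ncol(m)))
  if (!setequal(rownames(m), colnames(m)))
    stop("row and column labels of ", path, " do not match as sets")
  m <- m[, rownames(m), drop = FALSE]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    stop(sprintf("similarity matrix in %s is asymmetric (max |M - t(M)| = %.3g > 1e-8)",
                 path, asym))
  SimilarityMatrix((m + t(m)) / 2, kind = kind)
}

#' Write a labeled similarity matrix
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- as.matrix(sim)
  df <- data.frame(id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-disease ancestor DAGs from an edge list
#'
#' Three-column TSV (`disease_id`, `child_term`, `parent_term`): each row
#' adds the edge child -> parent to the named disease's DAG. A root term
#' (no parent) uses `-` in the parent column; a disease whose DAG is a
#' single term appears as `(disease_id, term, -)`. Each disease's own
#' term is the unique node from which every other node of its graph is
#' reachable along parent edges (taken to be `disease_id` itself when
#' that is a term of the graph and satisfies the condition).
#'
#' @param path path to the TSV edge list.
#' @return A [DiseaseDAGSet-class]. Cycles or a graph with no valid own
#'   term raise an error naming the disease.
#' @export
readDiseaseDAGs <- function(path) {
  parsed <- .readLinesNoComment(path)
  if (!length(parsed$lines)) stop("empty DAG file: ", path)
  fields <- .splitFields(parsed$lines)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop(sprintf("malformed DAG row at line %d of %s: expected 3 fields",
                 parsed$lineno[bad[1L]], path))
  rows <- do.call(rbind, fields)
  if (grepl("disease", rows[1L, 1L], ignore.case = TRUE) &&
      grepl("child|term", rows[1L, 2L], ignore.case = TRUE))
    rows <- rows[-1L, , drop = FALSE]
  graphs <- lapply(split.data.frame(rows, rows[, 1L]), function(r) {
    id <- r[1L, 1L]
    edges <- r[r[, 3L] != "-", c(2L, 3L), drop = FALSE]
    terms <- unique(c(r[, 2L], edges[, 2L]))
    if (nrow(edges)) {
      ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
      if (!igraph::is_dag(ig))
        stop("cycle detected in the DAG of disease '", id, "'")
      reachesAll <- function(s)
        setequal(union(igraph::subcomponent(ig, s, mode = "out")$name, s), terms)
      cand <- if (id %in% terms && id %in% igraph::V(ig)$name && reachesAll(id)) {
        id
      } else {
        src <- setdiff(terms, edges[, 2L])  # never a parent
        src[vapply(src, function(s) s %in% igraph::V(ig)$name && reachesAll(s),
                   logical(1))]
      }
      if (length(cand) != 1L)
        stop("disease '", id,
             "': cannot identify its own term (no unique source covering the graph)")
      term <- cand
    } else {
      if (length(terms) != 1L)
        stop("disease '", id, "': multiple root rows but no edges")
      term <- terms
    }
    list(term = term, terms = terms, edges = edges)
  })
  DiseaseDAGSet(graphs[unique(rows[, 1L])])
}

#' Write per-disease DAGs as a 3-column edge list
#' @param dagSet a [DiseaseDAGSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiseaseDAGs <- function(dagSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#disease_id\tchild_term\tparent_term", con)
  for (id in diseaseIds(dagSet)) {
    g <- diseaseDAG(dagSet, id)
    if (nrow(g$edges)) {
      writeLines(paste(id, g$edges[, 1L], g$edges[, 2L], sep = "\t"), con)
      roots <- setdiff(g$terms, g$edges[, 1L])
      if (length(roots))
        writeLines(paste(id, roots, "-", sep = "\t"), con)
    } else {
      writeLines(paste(id, g$term, "-", sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Rank unobserved pairs per disease
#'
#' For every disease, the miRNAs not yet known to be associated with it
#' (entries with \eqn{A = 0}) are ranked by descending prediction score;
#' ties are broken lexicographically on the miRNA identifier so output
#' is deterministic.
#'
#' @param scores a [ScoreMatrix-class].
#' @param assoc the [AssociationMatrix-class] with the same labels.
#' @return A data.frame with columns `disease`, `rank`, `mirna`, `score`,
#'   diseases in column order.
#' @export
rankedPredictions <- function(scores, assoc) {
  s <- as.matrix(scores); a <- as.matrix(assoc)
  if (!identical(dimnames(s), dimnames(a)))
    stop("scores and associations must share identical labels and order")
  out <- lapply(colnames(a), function(d) {
    cand <- which(a[, d] == 0)
    if (!length(cand)) return(NULL)
    ids <- rownames(a)[cand]
    sc <- s[cand, d]
    o <- order(-sc, ids, method = "radix")
    data.frame(disease = d, rank = seq_along(o), mirna = ids[o],
               score = sc[o], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(disease = character(), rank = integer(),
                      mirna = character(), score = numeric())
  rownames(out) <- NULL
  out
}

#' Write ranked per-disease predictions
#'
#' @param scores a [ScoreMatrix-class].
#' @param assoc the matching [AssociationMatrix-class].
#' @param path output path; a 4-column TSV
#'   (`disease_id`, `rank`, `miRNA_id`, `score`).
#' @return `path`, invisibly.
#' @export
writeRankedPredictions <- function(scores, assoc, path) {
  rp <- rankedPredictions(scores, assoc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("disease_id\trank\tmiRNA_id\tscore", con)
  if (nrow(rp))
    writeLines(sprintf("%s\t%d\t%s\t%.17g", rp$disease, rp$rank, rp$mirna,
                       rp$score), con)
  invisible(path)
}

#' Write a score matrix as labeled TSV
#' @param scores a [ScoreMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreMatrix <- function(scores, path) {
  v <- as.matrix(scores)
  df <- data.frame(mirna = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
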