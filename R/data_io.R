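#' @keywords internal
"_PACKAGE"

# Identifier normalization shared by every ingestion path: trim surrounding
# whitespace, collapse internal runs to one space, case-fold. The three public
# association databases spell the same entity inconsistently; this is the
# dedup key.
normalize_id <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tolower(x)
}

new_adjacency <- function(values, row_kind, col_kind) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  structure(values,
            kinds = c(rows = row_kind, cols = col_kind),
            class = c("bipartite_adjacency", "matrix", "array"))
}

adjacency_kinds <- function(a) attr(a, "kinds")

#' Read a two-column association edge list
#'
#' Parses a delimited text file of entity-pair associations into a binary
#' bipartite adjacency matrix. Identifiers are normalized (whitespace trimmed
#' and collapsed, case-folded) and duplicate edges are removed, so the
#' nonzero count of the result equals the number of unique normalized pairs.
#' Vocabularies are ordered by first appearance in the file.
#'
#' A header line is auto-detected: the first line is dropped as a header when
#' neither of its tokens recurs as an identifier in its own column later in
#' the file (column labels such as `lncRNA`/`disease` never do; real entities
#' in a multi-edge list almost always do). Force the decision with `header`
#' for pathological single-mention entities.
#'
#' @param path Path to a two-column TSV (or CSV via `delim`).
#' @param kind_a,kind_b Entity kinds of the first and second column, each one
#'   of `"lncRNA"`, `"miRNA"`, `"disease"`.
#' @param delim Field delimiter, default tab.
#' @param header `NA` (default) auto-detects; `TRUE`/`FALSE` force.
#' @return A binary matrix of class `bipartite_adjacency` with row/column
#'   names set to the normalized identifiers and a `kinds` attribute.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("l1\td1", "l2\td1", "L1 \td1"), f)
#' a <- read_edge_list(f, "lncRNA", "disease")
#' sum(a)  # 2: "L1 " deduplicates onto "l1"
#' @export
read_edge_list <- function(path, kind_a, kind_b, delim = "\t", header = NA) {
  kinds <- c("lncRNA", "miRNA", "disease")
  kind_a <- match.arg(kind_a, kinds)
  kind_b <- match.arg(kind_b, kinds)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty edge list: ", path)
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("edge list %s: line %d has %d field(s), expected 2",
                 path, bad[1L], nf[bad[1L]]))
  }
  a <- normalize_id(vapply(parts, `[[`, "", 1L))
  b <- normalize_id(vapply(parts, `[[`, "", 2L))
  # auto-detect: a header's tokens never recur as entity ids in their columns
  if (isTRUE(is.na(header))) {
    header <- length(lines) > 1L &&
      !(a[1L] %in% a[-1L]) && !(b[1L] %in% b[-1L])
  }
  if (isTRUE(header)) {
    if (length(a) == 1L) stop("edge list ", path, " holds only a header line")
    a <- a[-1L]
    b <- b[-1L]
  }
  keep <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[keep]
  b <- b[keep]
  rows <- unique(a)
  cols <- unique(b)
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(a, rows), match(b, cols))] <- 1
  new_adjacency(m, kind_a, kind_b)
}

# Re-index a matrix onto target row/col vocabularies, zero-filling entities
# the source never mentions.
reindex <- function(m, rows, cols) {
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  ri <- intersect(rows, rownames(m))
  ci <- intersect(cols, colnames(m))
  out[ri, ci] <- m[ri, ci]
  out
}

orient <- function(a, row_kind, col_kind) {
  k <- adjacency_kinds(a)
  if (identical(unname(k), c(row_kind, col_kind))) return(a)
  if (identical(unname(k), c(col_kind, row_kind))) {
    return(new_adjacency(t(unclass(a)), row_kind, col_kind))
  }
  stop(sprintf("adjacency has kinds %s x %s; expected %s x %s",
               k[1L], k[2L], row_kind, col_kind))
}

#' Align three association matrices onto shared vocabularies
#'
#' Re-indexes the lncRNA-disease, lncRNA-miRNA and miRNA-disease adjacencies
#' onto the union vocabulary of each entity kind, so downstream profile
#' construction can concatenate blocks bit-for-bit. Entities present in only
#' one source keep all-zero rows/columns elsewhere. Orientation is normalized
#' to lncRNA x disease, lncRNA x miRNA and miRNA x disease regardless of the
#' column order of the input files (disambiguated by each adjacency's `kinds`
#' attribute).
#'
#' @param ld,ml,md Adjacencies from [read_edge_list()] carrying, in any
#'   orientation, the lncRNA-disease, lncRNA-miRNA and miRNA-disease edges.
#' @return A list with elements `ld` (lncRNA x disease), `ml`
#'   (lncRNA x miRNA) and `md` (miRNA x disease), all re-indexed.
#' @export
align_vocabularies <- function(ld, ml, md) {
  ld <- orient(ld, "lncRNA", "disease")
  ml <- orient(ml, "lncRNA", "miRNA")
  md <- orient(md, "miRNA", "disease")
  lnc <- unique(c(rownames(ld), rownames(ml)))
  mir <- unique(c(colnames(ml), rownames(md)))
  dis <- unique(c(colnames(ld), colnames(md)))
  list(ld = new_adjacency(reindex(ld, lnc, dis), "lncRNA", "disease"),
       ml = new_adjacency(reindex(ml, lnc, mir), "lncRNA", "miRNA"),
       md = new_adjacency(reindex(md, mir, dis), "miRNA", "disease"))
}

#' Build concatenated interaction profile matrices
#'
#' Each lncRNA's feature vector (one row of `lmd`) is its miRNA interaction
#' profile followed by its disease association profile; each disease's
#' feature vector (one row of `dml`) is its miRNA association profile
#' (transpose of miRNA x disease) followed by its lncRNA association profile
#' (transpose of lncRNA x disease). These binary rows are what the fused
#' similarity compares; the profile length `n` is the dimension of the
#' all-ones reference vector in its denominator.
#'
#' @param ld,ml,md Aligned adjacencies, as returned by [align_vocabularies()].
#' @return A list with `lmd` (lncRNA x (miRNA + disease)) and `dml`
#'   (disease x (miRNA + lncRNA)) binary matrices. Each carries a `blocks`
#'   attribute naming its column blocks and their widths.
#' @export
build_profiles <- function(ld, ml, md) {
  if (!identical(rownames(ld), rownames(ml))) {
    stop("lncRNA vocabularies differ between LD and ML; run align_vocabularies() first")
  }
  if (!identical(colnames(ld), colnames(md))) {
    stop("disease vocabularies differ between LD and MD; run align_vocabularies() first")
  }
  if (!identical(colnames(ml), rownames(md))) {
    stop("miRNA vocabularies differ between ML and MD; run align_vocabularies() first")
  }
  lmd <- cbind(unclass(ml), unclass(ld))
  dml <- cbind(t(unclass(md)), t(unclass(ld)))
  attr(lmd, "blocks") <- c(miRNA = ncol(ml), disease = ncol(ld))
  attr(dml, "blocks") <- c(miRNA = nrow(md), lncRNA = nrow(ld))
  list(lmd = lmd, dml = dml)
}

#' Write a completed score matrix as a ranked edge list
#'
#' Flattens a prediction into a four-column TSV (`lncRNA`, `disease`,
#' `score`, `known`) sorted by descending score, ties broken by lncRNA then
#' disease identifier. The `known` column flags pairs that were positive in
#' the input matrix (their score is pinned at 1).
#'
#' @param pred A `dmwnn_prediction` from [predict_associations()].
#' @param path Output file path.
#' @return The output `data.frame`, invisibly.
#' @export
write_scores <- function(pred, path) {
  stopifnot(inherits(pred, "dmwnn_prediction"))
  s <- pred$scores
  df <- data.frame(
    lncRNA  = rep(rownames(s), times = ncol(s)),
    disease = rep(colnames(s), each = nrow(s)),
    score   = as.vector(s),
    known   = as.integer(as.vector(pred$known) != 0),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$score, df$lncRNA, df$disease), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export / import a labelled matrix as dense TSV
#'
#' Debug-friendly round trip for adjacency, similarity and score matrices:
#' a dense tab-separated table with row and column identifiers.
#'
#' @param m A matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` its
#'   input, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(m)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an adjacency back out as a two-column edge list
#'
#' Inverse of [read_edge_list()] up to line order: one `row<TAB>col` line per
#' nonzero entry.
#'
#' @param a A `bipartite_adjacency`.
#' @param path Output path.
#' @export
write_edge_list <- function(a, path) {
  nz <- which(unclass(a) != 0, arr.ind = TRUE)
  lines <- paste(rownames(a)[nz[, 1L]], colnames(a)[nz[, 2L]], sep = "\t")
  writeLines(lines, path)
  invisible(a)
}
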