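# TSV I/O. All formats are tab-delimited UTF-8; lines starting with '#' are
# comments. Edge list: two columns (miRNA, disease), no header. Dense
# matrices: header row of column labels, first column of row labels.

#' @keywords internal
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a miRNA-disease association matrix from TSV
#'
#' @param path Path to a TSV file.
#' @param format `"edge_list"` (two columns `miRNA<TAB>disease`, no header;
#'   duplicate edges collapse to a single 1; label order is first appearance)
#'   or `"dense"` (header row of disease labels, first column of miRNA
#'   labels, 0/1 cells; label order is file order).
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, format = c("edge_list", "dense")) {
  format <- match.arg(format)
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    stop("no associations in ", path, call. = FALSE)
  }
  if (format == "edge_list") {
    parts <- strsplit(tl$lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad)) {
      stop(sprintf("malformed edge list row at line %d of %s (expected 2 columns)",
                   tl$lineno[bad[1]], path), call. = FALSE)
    }
    mir <- trimws(vapply(parts, `[[`, "", 1L))
    dis <- trimws(vapply(parts, `[[`, "", 2L))
    mirna_ids <- unique(mir)
    disease_ids <- unique(dis)
    values <- matrix(0, length(mirna_ids), length(disease_ids),
                     dimnames = list(mirna_ids, disease_ids))
    values[cbind(mir, dis)] <- 1
    association_matrix(values, mirna_ids, disease_ids)
  } else {
    mat <- parse_dense(tl, path)
    if (anyNA(mat$values) || !all(mat$values == 0 | mat$values == 1)) {
      stop("dense association matrix in ", path,
           " contains cells other than 0/1", call. = FALSE)
    }
    association_matrix(mat$values, mat$row_ids, mat$col_ids)
  }
}

#' @keywords internal
parse_dense <- function(tl, path) {
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- trimws(parts[[1]])
  # tolerate an optional corner label in the header
  body <- parts[-1]
  ncols <- unique(vapply(body, length, 1L))
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (length(ncols) != 1L) {
    stop("ragged rows in ", path, " (line ",
         tl$lineno[-1][which(vapply(body, length, 1L) != ncols[1])[1]], ")",
         call. = FALSE)
  }
  col_ids <- if (length(header) == ncols) header[-1] else header
  if (length(col_ids) != ncols - 1L) {
    stop("header of ", path, " does not match the number of data columns",
         call. = FALSE)
  }
  row_ids <- trimws(vapply(body, `[[`, "", 1L))
  values <- matrix(NA_real_, length(body), length(col_ids))
  for (i in seq_along(body)) {
    cells <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(cells)) {
      stop(sprintf("non-numeric cell at line %d of %s",
                   tl$lineno[-1][i], path), call. = FALSE)
    }
    values[i, ] <- cells
  }
  list(values = values, row_ids = row_ids, col_ids = col_ids)
}

#' Read a square similarity matrix from dense TSV
#'
#' Row and column labels must match as sets. Tiny asymmetries (at most 1e-8)
#' from file round-off are symmetrized by averaging with the transpose;
#' larger asymmetry is an error. The self-similarity diagonal is forced to 1
#' (MISIM and semantic-similarity inputs define self-similarity as 1, and the
#' cosine of a vector with itself is 1).
#'
#' @param path Path to a dense TSV file (header row + label column).
#' @param kind Similarity kind, see [similarity_matrix()].
#' @param expected_ids Optional label vector; rows/columns are reordered to
#'   match it and missing labels are an error.
#' @return A [similarity_matrix()].
#' @export
read_similarity <- function(path, kind = "mirna_functional",
                            expected_ids = NULL) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop("empty similarity file: ", path, call. = FALSE)
  mat <- parse_dense(tl, path)
  if (length(mat$row_ids) != length(mat$col_ids)) {
    stop("similarity matrix must be square (", length(mat$row_ids), " rows, ",
         length(mat$col_ids), " columns) in ", path, call. = FALSE)
  }
  v <- mat$values
  dimnames(v) <- list(mat$row_ids, mat$col_ids)
  if (!setequal(mat$row_ids, mat$col_ids)) {
    stop("row and column labels differ in ", path, call. = FALSE)
  }
  v <- v[, mat$row_ids, drop = FALSE]  # align columns to row order
  asym <- max(abs(v - t(v)))
  if (asym > 1e-8) {
    stop("similarity matrix in ", path, " is asymmetric (max |v - t(v)| = ",
         format(asym), " > 1e-8)", call. = FALSE)
  }
  v <- (v + t(v)) / 2
  diag(v) <- 1
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, mat$row_ids)
    if (length(missing)) {
      stop("similarity matrix in ", path, " is missing labels: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    v <- v[expected_ids, expected_ids, drop = FALSE]
  }
  similarity_matrix(v, rownames(v), kind = kind)
}

#' Read a miRNA-to-family table from TSV
#'
#' Two columns (`miRNA<TAB>family`), no header. miRNAs absent from the table
#' are treated as family `"none"` downstream.
#'
#' @param path Path to the TSV file.
#' @return A [family_assignment()].
#' @export
read_family <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    return(family_assignment(character(), character()))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed family row at line %d of %s (expected 2 columns)",
                 tl$lineno[bad[1]], path), call. = FALSE)
  }
  family_assignment(trimws(vapply(parts, `[[`, "", 1L)),
                    trimws(vapply(parts, `[[`, "", 2L)))
}

#' Write a matrix as dense TSV (header row + label column)
#'
#' @param values Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(values, path) {
  df <- data.frame(id = rownames(values), as.data.frame(unclass(values)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association matrix as a two-column edge list
#'
#' @param assoc An [association_matrix()].
#' @param path Output path.
#' @export
write_edge_list <- function(assoc, path) {
  idx <- which(assoc == 1, arr.ind = TRUE)
  # preserve first-appearance order: sort by row, then column of occurrence
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(rownames(assoc)[idx[, 1]], colnames(assoc)[idx[, 2]],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write ranked per-disease predictions
#'
#' For each disease, ranks the unknown pairs (entries with `assoc == 0`) by
#' descending recovered score and writes the top `top_k`. Ties are broken by
#' lexicographic miRNA label so output is deterministic.
#'
#' @param result An `ilrmr_recovery` object (see [ilrmr_recover()]).
#' @param assoc The [association_matrix()] whose 0-entries are the candidates.
#' @param path Output TSV path (columns: disease, rank, miRNA, score), or
#'   `NULL` to return the table without writing.
#' @param top_k Number of candidates to keep per disease (diseases with fewer
#'   unknown pairs emit all they have).
#' @return Invisibly (or visibly when `path` is `NULL`), a tibble of the
#'   written rows.
#' @export
write_predictions <- function(result, assoc, path, top_k = 50L) {
  if (top_k < 1L) stop("top_k must be at least 1", call. = FALSE)
  tab <- rank_predictions(result$scores, assoc, top_k)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @keywords internal
rank_predictions <- function(scores, assoc, top_k) {
  stopifnot(all(dim(scores) == dim(assoc)))
  out <- lapply(colnames(assoc), function(d) {
    unknown <- which(assoc[, d] == 0)
    if (!length(unknown)) return(NULL)
    s <- scores[unknown, d]
    m <- rownames(assoc)[unknown]
    ord <- order(-s, m)
    k <- min(top_k, length(ord))
    tibble::tibble(disease = d, rank = seq_len(k),
                   miRNA = m[ord[seq_len(k)]], score = s[ord[seq_len(k)]])
  })
  dplyr::bind_rows(out)
}
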