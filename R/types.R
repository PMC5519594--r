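#' Construct a binary miRNA-disease association matrix
#'
#' The association matrix is the central object of the package: rows are
#' miRNAs, columns are diseases, a 1 marks an experimentally verified
#' association and a 0 an unknown pair (the entries the method scores).
#'
#' @param values Numeric matrix of 0/1 entries, miRNAs in rows, diseases in
#'   columns.
#' @param mirna_ids Character vector of unique miRNA labels (row names). If
#'   `NULL`, taken from `rownames(values)`.
#' @param disease_ids Character vector of unique disease labels (column
#'   names). If `NULL`, taken from `colnames(values)`.
#' @return A numeric matrix with dimnames and class `ilrmr_assoc`.
#' @examples
#' association_matrix(matrix(c(1, 0, 0, 1), 2), c("m1", "m2"), c("d1", "d2"))
#' @export
association_matrix <- function(values, mirna_ids = NULL, disease_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(mirna_ids)) mirna_ids <- rownames(values)
  if (is.null(disease_ids)) disease_ids <- colnames(values)
  if (is.null(mirna_ids)) mirna_ids <- paste0("m", seq_len(nrow(values)))
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  dimnames(values) <- list(mirna_ids, disease_ids)
  class(values) <- c("ilrmr_assoc", class(matrix()))
  validate_association(values)
}

#' @keywords internal
validate_association <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("association matrix must have at least one miRNA and one disease",
         call. = FALSE)
  }
  if (anyNA(x) || !all(x == 0 | x == 1)) {
    stop("association matrix entries must be exactly 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate miRNA labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate disease labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Upper bound on entries by similarity kind. Cosine and input similarities are
# bounded by 1; the integrated matrices inherit the bounds of their product
# forms: fun * (1 + cos) * (1 + FAM) <= 4 and phe * (1 + cos) <= 2.
.sim_kinds <- c(
  mirna_functional = 1, mirna_cosine = 1, mirna_integrated = 4,
  disease_semantic = 1, disease_cosine = 1, disease_integrated = 2,
  family = 1
)

#' Construct a square similarity matrix
#'
#' @param values Square numeric matrix of nonnegative similarities.
#' @param ids Character vector of labels (both axes). If `NULL`, taken from
#'   `rownames(values)`.
#' @param kind One of `"mirna_functional"`, `"mirna_cosine"`,
#'   `"mirna_integrated"`, `"disease_semantic"`, `"disease_cosine"`,
#'   `"disease_integrated"`, `"family"`. Determines the admissible upper
#'   bound on entries.
#' @return A numeric matrix with class `ilrmr_sim` and a `kind` attribute.
#' @export
similarity_matrix <- function(values, ids = NULL,
                              kind = c("mirna_functional", "mirna_cosine",
                                       "mirna_integrated", "disease_semantic",
                                       "disease_cosine", "disease_integrated",
                                       "family")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  class(values) <- c("ilrmr_sim", class(matrix()))
  validate_similarity(values)
}

#' @keywords internal
validate_similarity <- function(x, tol = 1e-12) {
  kind <- attr(x, "kind")
  if (nrow(x) != ncol(x)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate similarity labels", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    stop("similarity values must be nonnegative and finite", call. = FALSE)
  }
  if (max(abs(x - t(x))) > tol) {
    stop("similarity matrix must be symmetric (max asymmetry ",
         format(max(abs(x - t(x)))), ")", call. = FALSE)
  }
  bound <- .sim_kinds[[kind]]
  if (any(x > bound + 1e-9)) {
    stop(sprintf("similarity of kind '%s' must be bounded by %g", kind, bound),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a miRNA family assignment
#'
#' miRBase groups evolutionarily related miRNAs into families; same-family
#' membership contributes the FAM(i, j) term of the integrated miRNA
#' similarity. miRNAs without a known family carry the distinguished family
#' `"none"`, which never matches itself.
#'
#' @param mirna_ids Character vector of miRNA labels (each at most once).
#' @param families Character vector of family labels, same length; `NA` or
#'   `""` are mapped to `"none"`.
#' @return A named character vector of class `ilrmr_family` (names = miRNAs).
#' @export
family_assignment <- function(mirna_ids, families) {
  mirna_ids <- as.character(mirna_ids)
  families <- as.character(families)
  if (length(mirna_ids) != length(families)) {
    stop("mirna_ids and families must have the same length", call. = FALSE)
  }
  if (anyDuplicated(mirna_ids)) {
    stop("each miRNA may appear at most once in the family table",
         call. = FALSE)
  }
  families[is.na(families) | families == ""] <- "none"
  structure(stats::setNames(families, mirna_ids), class = "ilrmr_family")
}

#' Look up families for a set of miRNAs, defaulting to "none"
#' @keywords internal
family_of <- function(fams, mirna_ids) {
  if (is.null(fams)) {
    return(stats::setNames(rep("none", length(mirna_ids)), mirna_ids))
  }
  out <- unclass(fams)[mirna_ids]
  out[is.na(out)] <- "none"
  stats::setNames(out, mirna_ids)
}

#' Construct a confidence weight matrix
#'
#' @param values Nonnegative finite numeric matrix, same orientation as the
#'   association matrix (miRNAs x diseases).
#' @param mirna_ids,disease_ids Optional labels; taken from dimnames if `NULL`.
#' @return A numeric matrix with class `ilrmr_weights`.
#' @export
weight_matrix <- function(values, mirna_ids = NULL, disease_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(mirna_ids)) rownames(values) <- mirna_ids
  if (!is.null(disease_ids)) colnames(values) <- disease_ids
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("weights must be nonnegative and finite", call. = FALSE)
  }
  class(values) <- c("ilrmr_weights", class(matrix()))
  values
}

#' @keywords internal
check_same_ids <- function(a, b, what) {
  if (length(a) != length(b) || !all(a == b)) {
    stop(what, ": label order mismatch (missing: ",
         paste(setdiff(a, b), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}
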