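# Cosine-based similarities from the association matrix and their
# integration with functional/semantic/family information.
#
# The integrated scores are deliberately NOT rescaled to [0,1]: the weight
# construction downstream is scale-sensitive and the multiplicative forms
# fun * (1 + cos) * (1 + FAM) and phe * (1 + cos) are used as-is, so the
# miRNA-integrated matrix lives in [0,4] and the disease-integrated one in
# [0,2].

#' @keywords internal
cosine_rows <- function(mat) {
  # cosine between all row pairs; rows with zero norm get similarity 0
  nrm <- sqrt(rowSums(mat^2))
  g <- tcrossprod(mat)
  denom <- outer(nrm, nrm)
  out <- ifelse(denom > 0, g / denom, 0)
  # guard round-off outside [0,1] (entries are nonnegative here)
  out[out > 1] <- 1
  out[out < 0] <- 0
  d <- diag(out)
  d[nrm > 0] <- 1
  diag(out) <- d
  (out + t(out)) / 2
}

#' Cosine similarity between miRNAs from their disease interaction profiles
#'
#' Each miRNA is the row vector of its 0/1 disease interactions; the
#' similarity of two miRNAs is the cosine of the angle between their vectors.
#' An all-zero profile (a miRNA with no known association, as arises during
#' cross-validation) has similarity 0 to everything, including itself — the
#' uninformative value rather than NaN.
#'
#' @param assoc An [association_matrix()] (or plain 0/1 matrix, miRNAs in
#'   rows).
#' @return A [similarity_matrix()] of kind `mirna_cosine`.
#' @export
mirna_cosine_similarity <- function(assoc) {
  similarity_matrix(cosine_rows(unclass(assoc)), rownames(assoc),
                    kind = "mirna_cosine")
}

#' Cosine similarity between diseases from their miRNA interaction profiles
#'
#' Identical formula applied to the columns of the association matrix.
#'
#' @inheritParams mirna_cosine_similarity
#' @return A [similarity_matrix()] of kind `disease_cosine`.
#' @export
disease_cosine_similarity <- function(assoc) {
  similarity_matrix(cosine_rows(t(unclass(assoc))), colnames(assoc),
                    kind = "disease_cosine")
}

#' Binary same-family indicator matrix
#'
#' `FAM(i, j) = 1` exactly when miRNAs i and j are assigned the same family
#' and that family is not `"none"`; the diagonal is 1. Unassigned miRNAs
#' (family `"none"`) never match each other.
#'
#' @param fams A [family_assignment()], or `NULL` for all-`"none"`.
#' @param mirna_ids miRNA labels defining the matrix order.
#' @return A [similarity_matrix()] of kind `family`.
#' @export
family_matrix <- function(fams, mirna_ids) {
  f <- family_of(fams, mirna_ids)
  same <- outer(f, f, `==`) & outer(f != "none", f != "none", `&`)
  out <- matrix(as.numeric(same), length(mirna_ids), length(mirna_ids))
  diag(out) <- 1
  similarity_matrix(out, mirna_ids, kind = "family")
}

#' Integrate functional, cosine and family similarity between miRNAs
#'
#' `Sim_mir(i,j) = Sim_fun(i,j) * (1 + Sim_cos(i,j)) * (1 + FAM(i,j))`:
#' the functional similarity is amplified when the interaction profiles agree
#' and doubled again for same-family pairs.
#'
#' @param fun Functional similarity (`mirna_functional`).
#' @param cos Cosine similarity (`mirna_cosine`).
#' @param fam Family indicator (`family`).
#' @return A [similarity_matrix()] of kind `mirna_integrated`, in \[0, 4\].
#' @export
integrate_mirna_similarity <- function(fun, cos, fam) {
  check_same_ids(rownames(fun), rownames(cos), "mirna similarity integration")
  check_same_ids(rownames(fun), rownames(fam), "mirna similarity integration")
  out <- unclass(fun) * (1 + unclass(cos)) * (1 + unclass(fam))
  similarity_matrix(out, rownames(fun), kind = "mirna_integrated")
}

#' Integrate semantic and cosine similarity between diseases
#'
#' `Sim_dd(i,j) = Sim_phe(i,j) * (1 + Sim_cos(i,j))`.
#'
#' @param phe Semantic similarity (`disease_semantic`).
#' @param cos Cosine similarity (`disease_cosine`).
#' @return A [similarity_matrix()] of kind `disease_integrated`, in \[0, 2\].
#' @export
integrate_disease_similarity <- function(phe, cos) {
  check_same_ids(rownames(phe), rownames(cos), "disease similarity integration")
  out <- unclass(phe) * (1 + unclass(cos))
  similarity_matrix(out, rownames(phe), kind = "disease_integrated")
}
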