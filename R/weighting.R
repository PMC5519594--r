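# Confidence weight matrix W for the l1 penalty of the weighted recovery
# model. W(i,j) averages a miRNA-based and a disease-based weight:
#
#   W_mir(i,j) = (Sim_mir[i, ] . X[, j]) / ||X[, j]||
#   W_dd(i,j)  = (X[i, ] . Sim_dd[, j]) / ||X[i, ]||
#
# i.e. how similar miRNA i is to the known interactors of disease j, and how
# similar disease j is to the diseases miRNA i is known to interact with,
# each normalized by the Euclidean norm of the profile vector. Zero-norm
# profiles give weight 0 (no evidence, no confidence), never NaN. No global
# rescaling is applied: the solver's lambda absorbs scale.

#' miRNA-based confidence weight
#'
#' @param sim_mir Integrated miRNA similarity ([integrate_mirna_similarity()]).
#' @param assoc Training [association_matrix()].
#' @return A [weight_matrix()] (miRNAs x diseases).
#' @export
mirna_weight <- function(sim_mir, assoc) {
  check_same_ids(rownames(assoc), rownames(sim_mir), "mirna weight")
  colnorm <- sqrt(colSums(unclass(assoc)^2))
  num <- unclass(sim_mir) %*% unclass(assoc)
  w <- sweep(num, 2, ifelse(colnorm > 0, colnorm, 1), "/")
  w[, colnorm == 0] <- 0
  weight_matrix(w, rownames(assoc), colnames(assoc))
}

#' Disease-based confidence weight
#'
#' @param sim_dd Integrated disease similarity
#'   ([integrate_disease_similarity()]).
#' @param assoc Training [association_matrix()].
#' @return A [weight_matrix()] (miRNAs x diseases).
#' @export
disease_weight <- function(sim_dd, assoc) {
  check_same_ids(colnames(assoc), rownames(sim_dd), "disease weight")
  rownorm <- sqrt(rowSums(unclass(assoc)^2))
  num <- unclass(assoc) %*% unclass(sim_dd)
  w <- sweep(num, 1, ifelse(rownorm > 0, rownorm, 1), "/")
  w[rownorm == 0, ] <- 0
  weight_matrix(w, rownames(assoc), colnames(assoc))
}

#' Combine the miRNA- and disease-based weights
#'
#' Entrywise average `W = (W_mir + W_dd) / 2`.
#'
#' @param w_mir,w_dd [weight_matrix()] objects of identical shape and labels.
#' @return A [weight_matrix()].
#' @export
combine_weights <- function(w_mir, w_dd) {
  if (!all(dim(w_mir) == dim(w_dd))) {
    stop("weight matrices must have the same shape", call. = FALSE)
  }
  check_same_ids(rownames(w_mir), rownames(w_dd), "weight combination")
  check_same_ids(colnames(w_mir), colnames(w_dd), "weight combination")
  weight_matrix((unclass(w_mir) + unclass(w_dd)) / 2,
                rownames(w_mir), colnames(w_mir))
}

#' Build the full confidence weight matrix from raw inputs
#'
#' Convenience wrapper: cosine similarities from the (training) association
#' matrix, integration with functional/semantic/family information, then the
#' two weight components and their average.
#'
#' @param assoc Training [association_matrix()].
#' @param sim_mir_fun miRNA functional similarity (kind `mirna_functional`).
#' @param sim_dd_phe Disease semantic similarity (kind `disease_semantic`).
#' @param fams Optional [family_assignment()].
#' @param use_family_and_cosine If `FALSE`, only the functional/semantic
#'   similarities enter the weights (the ablation used when comparing against
#'   methods that cannot use family or interaction-profile information).
#' @return A [weight_matrix()].
#' @export
build_weight_matrix <- function(assoc, sim_mir_fun, sim_dd_phe, fams = NULL,
                                use_family_and_cosine = TRUE) {
  sims <- build_integrated_similarities(assoc, sim_mir_fun, sim_dd_phe, fams,
                                        use_family_and_cosine)
  combine_weights(mirna_weight(sims$mirna, assoc),
                  disease_weight(sims$disease, assoc))
}

#' Map similarity confidence to l1 penalty weights
#'
#' The raw confidence matrix `W` is high exactly where a pair is plausible:
#' at verified 1-entries and at unknown pairs whose miRNA resembles the
#' disease's interactors. For recovery, confidence at an unknown pair must
#' LOWER the barrier against moving that entry into the sparse residual, so
#' that a plausible pair can take its low-rank completion value instead of
#' being pinned to its observed 0. The default `"prior"` transform therefore
#' keeps unit penalty weight at known entries (the same trust as unweighted
#' robust PCA) and redistributes the residual budget among the unknown
#' entries by the mean-normalized decreasing map `1 / (1 + W)` — the overall
#' penalty scale stays with `lambda`, the confidence only shifts it between
#' candidates. `"direct"` passes the raw confidence through unchanged
#' (penalty proportional to `W`), which suppresses scores at plausible pairs
#' and is kept for ablation study only.
#'
#' @param w_raw Raw confidence [weight_matrix()] (from
#'   [build_weight_matrix()]).
#' @param assoc The training [association_matrix()] marking known entries.
#' @param transform `"prior"` (default) or `"direct"`.
#' @return A [weight_matrix()] of l1 penalty weights for [ilrmr_recover()].
#' @export
penalty_weights <- function(w_raw, assoc, transform = c("prior", "direct")) {
  transform <- match.arg(transform)
  w <- unclass(w_raw)
  if (!all(dim(w) == dim(assoc))) {
    stop("weight and association matrices must have the same shape",
         call. = FALSE)
  }
  if (transform == "direct") return(w_raw)
  p <- matrix(1, nrow(w), ncol(w))
  unknown <- unclass(assoc) == 0
  if (any(unknown)) {
    g <- 1 / (1 + w[unknown])
    p[unknown] <- g / mean(g)
  }
  weight_matrix(p, rownames(assoc), colnames(assoc))
}

#' @keywords internal
build_integrated_similarities <- function(assoc, sim_mir_fun, sim_dd_phe,
                                          fams = NULL,
                                          use_family_and_cosine = TRUE) {
  check_same_ids(rownames(assoc), rownames(sim_mir_fun), "miRNA similarity")
  check_same_ids(colnames(assoc), rownames(sim_dd_phe), "disease similarity")
  if (use_family_and_cosine) {
    mir <- integrate_mirna_similarity(sim_mir_fun,
                                      mirna_cosine_similarity(assoc),
                                      family_matrix(fams, rownames(assoc)))
    dd <- integrate_disease_similarity(sim_dd_phe,
                                       disease_cosine_similarity(assoc))
  } else {
    mir <- similarity_matrix(unclass(sim_mir_fun), rownames(sim_mir_fun),
                             kind = "mirna_integrated")
    dd <- similarity_matrix(unclass(sim_dd_phe), rownames(sim_dd_phe),
                            kind = "disease_integrated")
  }
  list(mirna = mir, disease = dd)
}
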