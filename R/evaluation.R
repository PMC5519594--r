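# Evaluation protocols: leave-one-out cross-validation over known
# associations, mask-ratio robustness experiments, and isolated-disease
# prediction, summarized by ROC/AUC and precision-recall/AUPR.
#
# Leakage rule: whenever an experiment alters the association matrix
# (holding out an edge, masking a fraction of edges, isolating a disease),
# the cosine similarities and the weight matrix are recomputed from the
# altered TRAINING matrix — the held-out information never enters its own
# score.

#' Area under the ROC curve from scores and binary labels
#'
#' Rank (Mann-Whitney) formulation; tied scores contribute 1/2.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length, with at least one of each
#'   class.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve from scores and binary labels
#'
#' Step-wise (non-linear) interpolation over descending score thresholds;
#' tied scores are processed as a single block, so all-equal scores give
#' exactly the positive prevalence.
#'
#' @inheritParams auc_from_scores
#' @return AUPR in \[0, 1\].
#' @export
aupr_from_scores <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR undefined: no positive labels", call. = FALSE)
  pts <- pr_points(scores, labels)
  # right-continuous step area: sum over recall increments of the precision
  # attained at that threshold
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' @keywords internal
threshold_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # block boundaries at distinct score values (ties as one block)
  last_of_block <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last_of_block]
  fp <- cumsum(1 - l)[last_of_block]
  list(tp = tp, fp = fp, n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' @keywords internal
roc_points <- function(scores, labels) {
  tc <- threshold_counts(scores, labels)
  tibble::tibble(fpr = c(0, tc$fp / tc$n_neg), tpr = c(0, tc$tp / tc$n_pos))
}

#' @keywords internal
pr_points <- function(scores, labels) {
  tc <- threshold_counts(scores, labels)
  tibble::tibble(recall = tc$tp / tc$n_pos,
                 precision = tc$tp / (tc$tp + tc$fp))
}

#' @keywords internal
new_eval_report <- function(records, scores, labels, n_repeats = 1L,
                            seed = NA_integer_, settings = list(),
                            per_repeat = NULL) {
  structure(list(
    per_item_records = records,
    pooled_scores = scores,
    pooled_labels = as.numeric(labels),
    roc_points = roc_points(scores, labels),
    pr_points = pr_points(scores, labels),
    auc = auc_from_scores(scores, labels),
    aupr = aupr_from_scores(scores, labels),
    per_repeat = per_repeat,
    n_repeats = as.integer(n_repeats),
    seed = seed,
    settings = settings
  ), class = "ilrmr_eval")
}

#' @export
print.ilrmr_eval <- function(x, ...) {
  cat(sprintf("ilrmr evaluation (%s): AUC = %.4f, AUPR = %.4f over %d items\n",
              x$settings$protocol %||% "custom", x$auc, x$aupr,
              nrow(x$per_item_records)))
  invisible(x)
}

#' Leave-one-out cross-validation over known associations
#'
#' Each known association (1-entry) is removed in turn; similarities and
#' weights are rebuilt from the training matrix, recovery is rerun, and the
#' held-out pair's score is ranked among the candidate pairs (the held-out
#' pair plus the 0-entries of the training matrix). A single pooled ROC/PR is
#' computed from all folds, held-out pairs labeled 1 and training 0-entries
#' labeled 0.
#'
#' @inheritParams predict_scores
#' @param pooling `"global"` (candidates are all unknown pairs of the
#'   network, the default — the method scores all diseases simultaneously)
#'   or `"per_disease"` (candidates restricted to the held-out pair's
#'   disease column).
#' @return An `ilrmr_eval` report. `per_item_records` has one row per fold:
#'   miRNA, disease, score, rank among candidates, candidate count.
#' @export
loocv <- function(assoc, sim_mir_fun, sim_dd_phe, fams = NULL,
                  config = solver_config(), use_weights = TRUE,
                  use_family_and_cosine = TRUE,
                  pooling = c("global", "per_disease"),
                  penalty_transform = c("prior", "direct")) {
  pooling <- match.arg(pooling)
  penalty_transform <- match.arg(penalty_transform)
  known <- which(unclass(assoc) == 1, arr.ind = TRUE)
  if (nrow(known) < 2) {
    stop("LOOCV requires at least 2 known associations", call. = FALSE)
  }
  folds <- lapply(seq_len(nrow(known)), function(k) {
    i <- known[k, 1]; j <- known[k, 2]
    train <- assoc
    train[i, j] <- 0
    fit <- predict_scores(train, sim_mir_fun, sim_dd_phe, fams, config,
                          use_weights, use_family_and_cosine,
                          penalty_transform)
    zero_idx <- which(unclass(train) == 0, arr.ind = TRUE)
    if (pooling == "per_disease") {
      zero_idx <- zero_idx[zero_idx[, 2] == j, , drop = FALSE]
    }
    cand_scores <- fit$scores[zero_idx]
    is_test <- zero_idx[, 1] == i & zero_idx[, 2] == j
    list(
      record = tibble::tibble(
        miRNA = rownames(assoc)[i], disease = colnames(assoc)[j],
        score = fit$scores[i, j],
        rank = sum(cand_scores > fit$scores[i, j]) +
          (sum(cand_scores == fit$scores[i, j]) + 1) / 2,
        n_candidates = length(cand_scores)),
      scores = cand_scores,
      labels = as.numeric(is_test)
    )
  })
  new_eval_report(
    dplyr::bind_rows(lapply(folds, `[[`, "record")),
    unlist(lapply(folds, `[[`, "scores")),
    unlist(lapply(folds, `[[`, "labels")),
    settings = list(protocol = "loocv", use_weights = use_weights,
                    use_family_and_cosine = use_family_and_cosine,
                    pooling = pooling, penalty_transform = penalty_transform)
  )
}

#' Mask-ratio robustness experiment
#'
#' Per repeat, hides a uniform random fraction of the known associations,
#' recovers from the masked matrix, and scores the masked entries (positives)
#' against the 0-entries of the original matrix (negatives). Reports the
#' per-repeat AUCs and the pooled ROC/PR over all repeats.
#'
#' @inheritParams loocv
#' @param mask_ratio Fraction of known associations to hide, in (0, 1); the
#'   number masked is `floor(mask_ratio * #known)` and must be at least 1,
#'   leaving at least one known association.
#' @param n_repeats Number of independent maskings.
#' @param seed Integer seed controlling the maskings.
#' @return An `ilrmr_eval` report with a `per_repeat` tibble (repeat, auc,
#'   aupr, n_masked).
#' @export
mask_experiment <- function(assoc, sim_mir_fun, sim_dd_phe, fams = NULL,
                            config = solver_config(), mask_ratio = 0.1,
                            n_repeats = 20L, seed = 1L,
                            use_weights = TRUE, use_family_and_cosine = TRUE,
                            penalty_transform = c("prior", "direct")) {
  penalty_transform <- match.arg(penalty_transform)
  if (mask_ratio <= 0 || mask_ratio >= 1) {
    stop("mask_ratio must be in (0, 1)", call. = FALSE)
  }
  known <- which(unclass(assoc) == 1, arr.ind = TRUE)
  n_mask <- floor(mask_ratio * nrow(known))
  if (n_mask < 1) stop("mask_ratio too small: would mask 0 entries", call. = FALSE)
  if (n_mask >= nrow(known)) {
    stop("mask_ratio too large: no known association would remain", call. = FALSE)
  }
  neg_idx <- which(unclass(assoc) == 0, arr.ind = TRUE)
  rng <- local({
    set.seed(seed)
    lapply(seq_len(n_repeats), function(r) sample(nrow(known), n_mask))
  })
  reps <- lapply(seq_len(n_repeats), function(r) {
    hide <- known[rng[[r]], , drop = FALSE]
    train <- assoc
    train[hide] <- 0
    fit <- predict_scores(train, sim_mir_fun, sim_dd_phe, fams, config,
                          use_weights, use_family_and_cosine,
                          penalty_transform)
    scores <- c(fit$scores[hide], fit$scores[neg_idx])
    labels <- c(rep(1, nrow(hide)), rep(0, nrow(neg_idx)))
    list(scores = scores, labels = labels,
         summary = tibble::tibble(repeat_id = r,
                                  auc = auc_from_scores(scores, labels),
                                  aupr = aupr_from_scores(scores, labels),
                                  n_masked = n_mask))
  })
  per_repeat <- dplyr::bind_rows(lapply(reps, `[[`, "summary"))
  all_scores <- unlist(lapply(reps, `[[`, "scores"))
  all_labels <- unlist(lapply(reps, `[[`, "labels"))
  report <- new_eval_report(
    per_repeat, all_scores, all_labels, n_repeats = n_repeats, seed = seed,
    settings = list(protocol = "mask", mask_ratio = mask_ratio,
                    use_weights = use_weights,
                    use_family_and_cosine = use_family_and_cosine,
                    penalty_transform = penalty_transform),
    per_repeat = per_repeat
  )
  report$mean_auc <- mean(per_repeat$auc)
  report$mean_aupr <- mean(per_repeat$aupr)
  report
}

#' Isolated-disease prediction
#'
#' Removes every known association of one disease (its entire column),
#' recovers from the remaining network, and ranks the disease's true
#' interactors among all miRNAs — the setting of predicting a disease with
#' no known associated miRNA purely from similarity structure.
#'
#' A column with no observations is an invariant set of the recovery
#' iteration: its recovered scores are identically zero, so the low-rank
#' part alone cannot rank an isolated disease. The only channel through
#' which similarity information reaches such a column is the confidence
#' weight, so the isolated column is ranked by `W(., j)` computed from the
#' training (column-zeroed) matrix — for a zero column this reduces to the
#' disease-side weight, i.e. each miRNA's known interactions propagated
#' through the integrated disease similarity. The recovery itself is still
#' run and its convergence reported.
#'
#' @inheritParams loocv
#' @param disease_id Label of the disease to isolate; it must have at least
#'   one known association.
#' @return An `ilrmr_eval` report; `per_item_records` ranks every miRNA for
#'   the isolated disease with its true label.
#' @export
isolated_disease_eval <- function(assoc, sim_mir_fun, sim_dd_phe, fams = NULL,
                                  config = solver_config(), disease_id,
                                  use_weights = TRUE,
                                  use_family_and_cosine = TRUE,
                                  penalty_transform = c("prior", "direct")) {
  penalty_transform <- match.arg(penalty_transform)
  if (!disease_id %in% colnames(assoc)) {
    stop("unknown disease label: ", disease_id, call. = FALSE)
  }
  truth <- unclass(assoc)[, disease_id]
  if (sum(truth) < 1) {
    stop("disease ", disease_id, " has no known association to evaluate",
         call. = FALSE)
  }
  train <- assoc
  train[, disease_id] <- 0
  fit <- predict_scores(train, sim_mir_fun, sim_dd_phe, fams, config,
                        use_weights, use_family_and_cosine,
                        penalty_transform)
  w_raw <- build_weight_matrix(train, sim_mir_fun, sim_dd_phe, fams,
                               use_family_and_cosine)
  scores <- unclass(w_raw)[, disease_id]
  records <- tibble::tibble(
    miRNA = rownames(assoc), disease = disease_id, score = scores,
    rank = rank(-scores, ties.method = "average"),
    n_candidates = nrow(assoc), label = as.numeric(truth)
  )
  new_eval_report(records, scores, truth,
                  settings = list(protocol = "isolated_disease",
                                  disease = disease_id,
                                  use_weights = use_weights,
                                  use_family_and_cosine = use_family_and_cosine,
                                  penalty_transform = penalty_transform))
}
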