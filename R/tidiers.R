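# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a recovery fit into one row per miRNA-disease pair
#'
#' @param x An `ilrmr_recovery` object.
#' @param assoc Optional [association_matrix()]; when given, a `known`
#'   column marks the training 1-entries.
#' @param ... Unused.
#' @return A tibble with columns `miRNA`, `disease`, `score`, `residual`
#'   (and `known`).
#' @export
tidy.ilrmr_recovery <- function(x, assoc = NULL, ...) {
  dn <- dimnames(x$scores)
  out <- tibble::tibble(
    miRNA = rep(dn[[1]] %||% as.character(seq_len(nrow(x$scores))),
                times = ncol(x$scores)),
    disease = rep(dn[[2]] %||% as.character(seq_len(ncol(x$scores))),
                  each = nrow(x$scores)),
    score = as.vector(x$scores),
    residual = as.vector(x$residual)
  )
  if (!is.null(assoc)) out$known <- as.vector(unclass(assoc)) == 1
  out
}

#' One-row summary of a recovery fit
#'
#' @param x An `ilrmr_recovery` object.
#' @param ... Unused.
#' @return A tibble: convergence flag, iterations, lambda, final
#'   feasibility residual, numerical rank of the scores, objective value.
#' @exportS3Method generics::glance
glance.ilrmr_recovery <- function(x, ...) {
  d <- svd(x$scores, nu = 0, nv = 0)$d
  tibble::tibble(
    converged = x$converged,
    iterations = x$iterations,
    lambda = x$lambda_used,
    feasibility = if (length(x$feasibility_trace))
      x$feasibility_trace[length(x$feasibility_trace)] else 0,
    rank = sum(d > max(d[1], 1e-12) * 1e-8),
    objective = if (length(x$objective_trace))
      x$objective_trace[length(x$objective_trace)] else 0
  )
}

#' Tidy an evaluation report into its per-item records
#'
#' @param x An `ilrmr_eval` object.
#' @param ... Unused.
#' @return The per-item/per-fold tibble.
#' @exportS3Method generics::tidy
tidy.ilrmr_eval <- function(x, ...) x$per_item_records

#' One-row summary of an evaluation report
#'
#' @param x An `ilrmr_eval` object.
#' @param ... Unused.
#' @return A tibble with `auc`, `aupr`, `n_items`, `n_repeats`, `protocol`.
#' @exportS3Method generics::glance
glance.ilrmr_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, aupr = x$aupr,
    n_items = nrow(x$per_item_records),
    n_repeats = x$n_repeats,
    protocol = x$settings$protocol %||% NA_character_
  )
}

#' Plot ROC or precision-recall curve of an evaluation report
#'
#' @param object An `ilrmr_eval` object.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ilrmr_eval <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.4f)", object$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr_points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh", linewidth = 0.7, colour = "#de2d26") +
      ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUPR = %.4f)",
                                    object$aupr)) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.ilrmr_eval
#' @export
plot_roc <- function(object) autoplot(object, type = "roc")

#' @rdname autoplot.ilrmr_eval
#' @export
plot_pr <- function(object) autoplot(object, type = "pr")
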