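# Weighted robust PCA via the exact augmented Lagrange multiplier method.
#
# The model:  min  ||R||_* + lambda * ||W o (X - R)||_1   s.t.  X = R + E
# where ||.||_* is the nuclear norm (convex surrogate for rank), o the
# Hadamard product, and W a nonnegative confidence matrix. The recovered
# low-rank R holds the association scores; E absorbs sparse discrepancies.
#
# The augmented Lagrangian
#   L(R, E, Y, mu) = ||R||_* + lambda ||W o E||_1
#                    + <Y, X - R - E> + mu/2 ||X - R - E||_F^2
# is minimized over (R, E) to an inner tolerance before each multiplier
# update (the "exact" ALM variant); the inexact variant takes a single
# R/E pass per multiplier update. Both proximal steps are closed-form:
# singular value thresholding for R, entrywise soft-thresholding at
# lambda * W[i,j] / mu for E.

#' Solver configuration for the weighted recovery problem
#'
#' @param lambda Weight of the sparse-error term, in (0, 1]. The default
#'   `NULL` resolves to `1 / sqrt(max(m, n))` at solve time, the standard
#'   robust-PCA choice (always in (0, 1]).
#' @param mu0 Initial augmented-Lagrangian penalty; default `NULL` resolves
#'   to `1.25 / sigma1(X)`.
#' @param rho Penalty growth factor per multiplier update (> 1).
#' @param tol Feasibility tolerance on `||X - R - E||_F / ||X||_F`.
#' @param inner_tol Relative-change tolerance for the inner (R, E)
#'   minimization of the exact variant.
#' @param max_iter Maximum number of multiplier updates.
#' @param variant `"exact"` (inner loop to `inner_tol`) or `"inexact"`
#'   (single pass per multiplier update).
#' @return A list of class `ilrmr_config`.
#' @export
solver_config <- function(lambda = NULL, mu0 = NULL, rho = 1.5, tol = 1e-7,
                          inner_tol = 1e-6, max_iter = 500L,
                          variant = c("exact", "inexact")) {
  variant <- match.arg(variant)
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (rho <= 1) stop("rho must exceed 1", call. = FALSE)
  if (tol <= 0 || inner_tol <= 0) stop("tolerances must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be at least 1", call. = FALSE)
  structure(list(lambda = lambda, mu0 = mu0, rho = rho, tol = tol,
                 inner_tol = inner_tol, max_iter = as.integer(max_iter),
                 variant = variant),
            class = "ilrmr_config")
}

#' Soft-thresholding (l1 proximal operator)
#'
#' `shrink(v, t) = sign(v) * max(|v| - t, 0)`, applied elementwise.
#'
#' @param value Numeric vector or matrix.
#' @param threshold Nonnegative threshold (scalar or conformable).
#' @return Same shape as `value`.
#' @export
shrink <- function(value, threshold) {
  if (any(threshold < 0)) stop("threshold must be nonnegative", call. = FALSE)
  sign(value) * pmax(abs(value) - threshold, 0)
}

#' Singular value thresholding (nuclear-norm proximal operator)
#'
#' Soft-thresholds the singular values: `U shrink(Sigma, tau) V'`. The
#' result's rank is the number of singular values exceeding `tau`.
#'
#' @param mat Numeric matrix.
#' @param tau Nonnegative threshold.
#' @return Matrix of the same shape.
#' @export
svt <- function(mat, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  s <- svd(mat)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(mat), ncol(mat)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Recover a low-rank score matrix from a weighted sparse decomposition
#'
#' Solves `min ||R||_* + lambda ||W o (X - R)||_1 s.t. X = R + E` by the
#' exact ALM method. Entries with large `W` are expensive to move into the
#' sparse residual, so the recovered `R` stays close to `X` there; entries
#' with `W = 0` are unconstrained and `R` takes its low-rank completion
#' value.
#'
#' @param X Numeric matrix (typically an [association_matrix()], possibly
#'   masked).
#' @param W Nonnegative weight matrix of the same shape, or `NULL` for the
#'   unweighted model (`W` identically 1). An all-zero `W` is replaced by
#'   the unweighted model with a warning, since it would leave the residual
#'   unpenalized.
#' @param config A [solver_config()].
#' @return An object of class `ilrmr_recovery`: list with `scores` (R),
#'   `residual` (E), `converged`, `iterations`, `objective_trace`,
#'   `feasibility_trace`, `lambda_used`.
#' @examples
#' X <- outer(c(1, 1, 1), c(1, 0, 1))
#' fit <- ilrmr_recover(X)
#' max(abs(fit$scores - X)) < 1e-5
#' @export
ilrmr_recover <- function(X, W = NULL, config = solver_config()) {
  Xm <- unclass(as.matrix(X))
  storage.mode(Xm) <- "double"
  m <- nrow(Xm); n <- ncol(Xm)
  if (is.null(W)) {
    Wm <- matrix(1, m, n)
  } else {
    Wm <- unclass(as.matrix(W))
    if (!all(dim(Wm) == dim(Xm))) {
      stop("X and W must have identical shape", call. = FALSE)
    }
    if (any(Wm < 0)) stop("W must be nonnegative", call. = FALSE)
    if (all(Wm == 0)) {
      warning("weight matrix is identically zero; falling back to the ",
              "unweighted model (W = 1)")
      Wm <- matrix(1, m, n)
    }
  }
  lambda <- if (is.null(config$lambda)) 1 / sqrt(max(m, n)) else config$lambda

  normX <- norm(Xm, "F")
  if (normX == 0) {
    return(new_recovery(matrix(0, m, n), matrix(0, m, n), TRUE, 0L,
                        numeric(0), numeric(0), lambda, dimnames(X)))
  }
  sigma1 <- svd(Xm, nu = 0, nv = 0)$d[1]
  mu <- if (is.null(config$mu0)) 1.25 / sigma1 else config$mu0
  # dual-feasible multiplier start, as in the reference exact-ALM scheme
  Y <- Xm / max(sigma1, max(abs(Xm)) / lambda)
  R <- matrix(0, m, n)
  E <- matrix(0, m, n)
  obj_trace <- numeric(0)
  feas_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  inner_cap <- 100L

  while (iter < config$max_iter) {
    iter <- iter + 1L
    E_outer <- E
    for (inner in seq_len(if (config$variant == "exact") inner_cap else 1L)) {
      R_new <- svt(Xm - E + Y / mu, 1 / mu)
      E_new <- shrink(Xm - R_new + Y / mu, lambda * Wm / mu)
      delta <- max(norm(R_new - R, "F"), norm(E_new - E, "F")) / normX
      R <- R_new; E <- E_new
      if (delta < config$inner_tol) break
    }
    resid <- Xm - R - E
    feas <- norm(resid, "F") / normX
    feas_trace <- c(feas_trace, feas)
    obj_trace <- c(obj_trace, sum(svd(R, nu = 0, nv = 0)$d) +
                     lambda * sum(Wm * abs(E)))
    if (feas <= config$tol) {
      converged <- TRUE
      break
    }
    Y <- Y + mu * resid
    # grow the penalty only once the sparse iterate has stabilized at this
    # mu; growing it while E is still moving drives the iterates to a
    # feasible but sub-optimal split
    if (mu * norm(E - E_outer, "F") / normX < config$inner_tol) {
      mu <- mu * config$rho
    }
  }
  new_recovery(R, E, converged, iter, obj_trace, feas_trace, lambda,
               dimnames(X))
}

#' @keywords internal
new_recovery <- function(R, E, converged, iterations, obj, feas, lambda, dn) {
  if (!is.null(dn)) {
    dimnames(R) <- dn
    dimnames(E) <- dn
  }
  structure(list(scores = R, residual = E, converged = converged,
                 iterations = iterations, objective_trace = obj,
                 feasibility_trace = feas, lambda_used = lambda),
            class = "ilrmr_recovery")
}

#' @export
print.ilrmr_recovery <- function(x, ...) {
  cat(sprintf(
    "ilrmr recovery: %d x %d, %s in %d iterations (lambda = %.4g)\n",
    nrow(x$scores), ncol(x$scores),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$lambda_used))
  if (length(x$feasibility_trace)) {
    cat(sprintf("  final feasibility ||X-R-E||_F/||X||_F = %.3g\n",
                x$feasibility_trace[length(x$feasibility_trace)]))
  }
  invisible(x)
}

#' End-to-end association scoring
#'
#' Runs the full pipeline on an association matrix: cosine similarities,
#' integration with functional/semantic/family information, confidence
#' weights, and weighted low-rank recovery. `scores[i, j]` of the result is
#' the predicted association strength of miRNA i with disease j.
#'
#' @inheritParams build_weight_matrix
#' @param config A [solver_config()].
#' @param use_weights If `FALSE`, solve the unweighted model (no `W`) — the
#'   ablation quantifying what the confidence weights add.
#' @param penalty_transform Confidence-to-penalty mapping, see
#'   [penalty_weights()].
#' @inheritParams build_weight_matrix
#' @return An `ilrmr_recovery` object.
#' @export
predict_scores <- function(assoc, sim_mir_fun, sim_dd_phe, fams = NULL,
                           config = solver_config(), use_weights = TRUE,
                           use_family_and_cosine = TRUE,
                           penalty_transform = c("prior", "direct")) {
  W <- if (use_weights) {
    penalty_weights(
      build_weight_matrix(assoc, sim_mir_fun, sim_dd_phe, fams,
                          use_family_and_cosine),
      assoc, transform = penalty_transform)
  }
  ilrmr_recover(assoc, W, config)
}
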