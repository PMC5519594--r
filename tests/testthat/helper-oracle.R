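# Independent oracles, deliberately coded apart from the package internals.

# Basic inexact-ALM robust PCA (single SVT + single shrink per multiplier
# update, unweighted l1 penalty). Written directly from the classical
# algorithm statement; shares no code with ilrmr_recover.
oracle_rpca <- function(X, lambda = 1 / sqrt(max(dim(X))), tol = 1e-8,
                        max_iter = 1000) {
  m <- nrow(X); n <- ncol(X)
  norm_two <- svd(X, nu = 0, nv = 0)$d[1]
  norm_inf <- max(abs(X)) / lambda
  Y <- X / max(norm_two, norm_inf)
  E <- matrix(0, m, n)
  mu <- 1.25 / norm_two
  rho <- 1.5
  normX <- norm(X, "F")
  A_hat <- matrix(0, m, n)
  for (iter in seq_len(max_iter)) {
    E_prev <- E
    # E update
    temp <- X - A_hat + Y / mu
    E <- pmax(temp - lambda / mu, 0) + pmin(temp + lambda / mu, 0)
    # A update via partial soft-threshold of singular values
    s <- svd(X - E + Y / mu)
    dshr <- s$d - 1 / mu
    keep <- dshr > 0
    A_hat <- if (any(keep)) {
      s$u[, keep, drop = FALSE] %*% diag(dshr[keep], sum(keep)) %*%
        t(s$v[, keep, drop = FALSE])
    } else matrix(0, m, n)
    Z <- X - A_hat - E
    Y <- Y + mu * Z
    # grow the penalty only once the E iterates have stabilized at this mu
    if (mu * norm(E - E_prev, "F") / normX < 1e-6) mu <- mu * rho
    if (norm(Z, "F") / normX < tol) break
  }
  list(L = A_hat, S = E, iterations = iter)
}

# Brute-force AUC: average over all positive-negative pairs, ties count 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Brute-force AUPR by explicit threshold sweep over distinct score values,
# processing tied scores as one block; rectangle rule on recall increments.
brute_aupr <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
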