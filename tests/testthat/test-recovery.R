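test_that("soft-thresholding matches its closed form", {
  expect_equal(shrink(3, 1), 2)
  expect_equal(shrink(-0.5, 1), 0)
  expect_equal(shrink(-2, 0.5), -1.5)
  expect_equal(shrink(c(3, -0.5, -2), c(1, 1, 0.5)), c(2, 0, -1.5))
  expect_error(shrink(1, -0.1), "nonnegative")
})

test_that("singular value thresholding shrinks the spectrum", {
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)), tolerance = 1e-12)
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(svt(m, 0), m, tolerance = 1e-12)
  expect_equal(svt(m, svd(m)$d[1] + 1), matrix(0, 3, 4))
  expect_error(svt(m, -1), "nonnegative")
})

test_that("svt is non-expansive", {
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(rnorm(35), 5, 7)
    b <- matrix(rnorm(35), 5, 7)
    tau <- runif(1, 0, 2)
    expect_lte(norm(svt(a, tau) - svt(b, tau), "F"),
               norm(a - b, "F") + 1e-12)
  }
})

test_that("all-zero input returns the trivial decomposition", {
  fit <- ilrmr_recover(matrix(0, 4, 3))
  expect_true(fit$converged)
  expect_equal(fit$scores, matrix(0, 4, 3))
  expect_equal(fit$residual, matrix(0, 4, 3))
})

test_that("noiseless low-rank inputs are recovered exactly", {
  X1 <- outer(c(1, 1, 1), c(1, 0, 1))
  fit1 <- ilrmr_recover(X1)
  expect_true(fit1$converged)
  expect_lte(norm(fit1$scores - X1, "F") / norm(X1, "F"), 1e-6)
  expect_lte(max(abs(fit1$residual)), 1e-6)
  set.seed(11)
  X2 <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(30), 2, 15)
  fit2 <- ilrmr_recover(X2)
  expect_lte(norm(fit2$scores - X2, "F") / norm(X2, "F"), 1e-6)
})

test_that("a planted low-rank plus sparse decomposition is separated", {
  inst <- generate_lowrank_sparse(20, 15, rank = 2, spike_fraction = 0.05,
                                  spike_magnitude = 1, seed = 3)
  fit <- ilrmr_recover(inst$X, config = solver_config(lambda = 1 / sqrt(20)))
  expect_lte(norm(fit$scores - inst$R0, "F") / norm(inst$R0, "F"), 1e-4)
})

test_that("with unit weights the solver matches an independent inexact-ALM oracle", {
  # run both solvers well past their default tolerances so the comparison
  # reflects the shared optimum, not finite stopping
  for (seed in c(1, 5, 14)) {
    inst <- generate_lowrank_sparse(20, 15, rank = 2, spike_fraction = 0.05,
                                    seed = seed)
    fit <- ilrmr_recover(inst$X, W = matrix(1, 20, 15),
                         config = solver_config(lambda = 1 / sqrt(20),
                                                tol = 1e-9, max_iter = 3000))
    ref <- oracle_rpca(inst$X, tol = 1e-10, max_iter = 8000)
    expect_lte(norm(fit$scores - ref$L, "F") / norm(ref$L, "F"), 1e-4)
  }
})

test_that("a zero-weight entry is free: R takes the completion value, not X's", {
  # lambda large enough that unit-weight entries are pinned to X; the
  # zero-weight entry must then land on the minimal-nuclear-norm completion
  u <- c(1, 2, 3, 4); v <- c(2, 1, 3)
  X <- outer(u, v)
  X[2, 3] <- X[2, 3] + 0.8   # corrupt one entry
  W <- matrix(1, 4, 3)
  W[2, 3] <- 0               # declare it untrusted
  fit <- ilrmr_recover(X, W, config = solver_config(lambda = 10))
  expect_equal(fit$scores[2, 3], outer(u, v)[2, 3], tolerance = 1e-4)
  expect_equal(fit$residual[2, 3], 0.8, tolerance = 1e-4)
  pinned <- ilrmr_recover(X, config = solver_config(lambda = 10))
  expect_equal(pinned$scores[2, 3], X[2, 3], tolerance = 1e-4)
})

test_that("feasibility holds at convergence and the residual trace improves", {
  net <- small_network(seed = 9)
  fit <- predict_scores(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams)
  expect_true(fit$converged)
  tr <- fit$feasibility_trace
  X <- unclass(net$assoc)
  expect_lte(norm(X - fit$scores - fit$residual, "F") / norm(X, "F"), 1e-7)
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(fit$objective_trace >= 0))
  expect_lte(fit$iterations, solver_config()$max_iter)
})

test_that("invalid inputs are rejected and degenerate weights fall back", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(ilrmr_recover(X, W = matrix(1, 3, 3)), "shape")
  expect_error(ilrmr_recover(X, W = matrix(-1, 4, 3)), "nonnegative")
  expect_warning(fit <- ilrmr_recover(X, W = matrix(0, 4, 3)),
                 "identically zero")
  ref <- ilrmr_recover(X)
  expect_equal(fit$scores, ref$scores)
})

test_that("the inexact variant reaches the same decomposition within tolerance", {
  inst <- generate_lowrank_sparse(15, 10, rank = 2, spike_fraction = 0.05,
                                  seed = 5)
  f_exact <- ilrmr_recover(inst$X, config = solver_config(variant = "exact"))
  f_inex <- ilrmr_recover(inst$X, config = solver_config(variant = "inexact"))
  expect_lte(norm(f_exact$scores - f_inex$scores, "F") /
               norm(f_exact$scores, "F"), 1e-3)
})

test_that("family and profile sharing drives a candidate to the top of its disease", {
  # d1 interacts with m1, m2, m3; candidate m5 shares their family and
  # functional profile; m6 is unrelated. m5 must outrank every other
  # unknown miRNA for d1.
  mir <- paste0("m", 1:6)
  dis <- paste0("d", 1:4)
  A <- matrix(0, 6, 4, dimnames = list(mir, dis))
  A[c(1, 2, 3), 1] <- 1
  A[c(1, 2, 3), 2] <- 1   # m1-m3 share a second disease
  A[5, 2] <- 1            # m5 seen on the similar disease d2
  A[4, 3] <- 1
  A[6, 4] <- 1
  a <- association_matrix(A, mir, dis)
  fun <- matrix(0.1, 6, 6); diag(fun) <- 1
  fun[1:3, 5] <- fun[5, 1:3] <- 0.9
  fun[1:3, 1:3] <- 0.9; diag(fun) <- 1
  sim_mir <- similarity_matrix(fun, mir, kind = "mirna_functional")
  sim_dd <- flat_similarity(dis, 0.2, "disease_semantic")
  fams <- family_assignment(mir, c("famA", "famA", "famA", "none", "famA",
                                   "none"))
  fit <- predict_scores(a, sim_mir, sim_dd, fams)
  unknown <- which(A[, "d1"] == 0)
  best <- names(which.max(fit$scores[unknown, "d1"]))
  expect_identical(best, "m5")
})

test_that("a single known association still yields a finite, convergent fit", {
  A <- matrix(0, 5, 4)
  A[2, 3] <- 1
  a <- association_matrix(A)
  fit <- predict_scores(a, flat_similarity(rownames(a)),
                        flat_similarity(colnames(a), 0.2, "disease_semantic"))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$scores)))
})

test_that("scores are equivariant under miRNA permutation of all inputs", {
  net <- small_network(seed = 13, m = 10, n = 7)
  fit <- predict_scores(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams)
  perm <- c(4, 1, 10, 3, 7, 2, 9, 5, 6, 8)
  ap <- association_matrix(unclass(net$assoc)[perm, , drop = FALSE])
  sp <- similarity_matrix(unclass(net$sim_mir_fun)[perm, perm],
                          rownames(net$sim_mir_fun)[perm],
                          kind = "mirna_functional")
  fp <- family_assignment(names(net$fams)[perm], unclass(net$fams)[perm])
  fit_p <- predict_scores(ap, sp, net$sim_dd_phe, fp)
  expect_equal(unclass(fit_p$scores), unclass(fit$scores)[perm, ],
               ignore_attr = TRUE, tolerance = 1e-6)
})
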