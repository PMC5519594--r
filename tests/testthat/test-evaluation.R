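test_that("AUC matches hand cases and the pair-counting oracle", {
  expect_equal(auc_from_scores(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  expect_equal(auc_from_scores(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_equal(auc_from_scores(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(brute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc_from_scores(c(1, 2), c(1, 1)), "AUC undefined")
  set.seed(20)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    s <- round(runif(n), 2)  # coarse grid to exercise ties
    l <- rbinom(n, 1, 0.4)
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(auc_from_scores(s, l), brute_auc(s, l), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(30)
  s <- runif(60)
  l <- rbinom(60, 1, 0.5)
  expect_equal(auc_from_scores(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUPR matches hand cases and the block-tie oracle", {
  expect_equal(aupr_from_scores(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(aupr_from_scores(c(0.9, 0.5, 0.1), c(0, 0, 1)), 1 / 3)
  expect_equal(aupr_from_scores(rep(0.7, 10), c(rep(1, 3), rep(0, 7))),
               3 / 10)
  expect_error(aupr_from_scores(c(1, 2), c(0, 0)), "no positive")
  set.seed(21)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 1)
    l <- rbinom(n, 1, 0.4)
    if (sum(l) == 0) next
    expect_equal(aupr_from_scores(s, l), brute_aupr(s, l), tolerance = 1e-12)
  }
})

test_that("ROC points start at (0,0), end at (1,1) and are nondecreasing", {
  net <- small_network(seed = 2, m = 10, n = 6)
  d <- colnames(net$assoc)[which(colSums(net$assoc) >= 2)[1]]
  rep <- isolated_disease_eval(net$assoc, net$sim_mir_fun, net$sim_dd_phe,
                               net$fams, disease_id = d)
  roc <- rep$roc_points
  expect_equal(unname(unlist(roc[1, ])), c(0, 0))
  expect_equal(unname(unlist(roc[nrow(roc), ])), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$aupr >= 0 && rep$aupr <= 1)
})

test_that("random label shuffles center the AUC at one half", {
  set.seed(99)
  s <- runif(200)
  l <- c(rep(1, 40), rep(0, 160))
  aucs <- vapply(1:100, function(i) auc_from_scores(s, sample(l)), numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("a perfect scorer run through the LOOCV pooling yields AUC 1", {
  # harness self-test: emulate folds whose score matrix is the truth itself
  a <- unclass(small_network(seed = 4, m = 8, n = 6)$assoc)
  known <- which(a == 1, arr.ind = TRUE)
  scores <- c(); labels <- c()
  for (k in seq_len(nrow(known))) {
    train <- a; train[known[k, 1], known[k, 2]] <- 0
    zi <- which(train == 0, arr.ind = TRUE)
    scores <- c(scores, a[zi])  # oracle: the full truth
    labels <- c(labels, as.numeric(zi[, 1] == known[k, 1] &
                                     zi[, 2] == known[k, 2]))
  }
  expect_equal(auc_from_scores(scores, labels), 1)
})

test_that("LOOCV records one fold per known pair with valid ranks", {
  net <- small_network(seed = 6)
  ev <- loocv(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams)
  recs <- tidy(ev)
  expect_equal(nrow(recs), sum(net$assoc))
  expect_true(all(recs$rank >= 1 & recs$rank <= recs$n_candidates))
  expect_gt(ev$auc, 0.5)
  expect_error(loocv(association_matrix(matrix(c(1, 0), 2, 1)),
                     flat_similarity(c("m1", "m2")),
                     flat_similarity("d1", 0, "disease_semantic")),
               "at least 2")
})

test_that("per-disease pooling restricts candidates to the held-out column", {
  net <- small_network(seed = 6)
  ev <- loocv(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams,
              pooling = "per_disease")
  expect_true(all(tidy(ev)$n_candidates <= nrow(net$assoc)))
})

test_that("a held-out edge backed by family and shared profile ranks near the top", {
  # m1-m3 form a family block interacting with d1-d3; m4-m7 carry one edge
  # each elsewhere. Holding out m1-d1, the family plus the shared profile
  # must place it in the top decile of candidates.
  mir <- paste0("m", 1:7)
  dis <- paste0("d", 1:5)
  A <- matrix(0, 7, 5, dimnames = list(mir, dis))
  A[1:3, 1:3] <- 1
  A[4, 4] <- 1; A[5, 5] <- 1; A[6, 4] <- 1; A[7, 5] <- 1
  a <- association_matrix(A, mir, dis)
  fun <- matrix(0.1, 7, 7); fun[1:3, 1:3] <- 0.9; diag(fun) <- 1
  fams <- family_assignment(mir, c("f1", "f1", "f1", rep("none", 4)))
  ev <- loocv(a, similarity_matrix(fun, mir, kind = "mirna_functional"),
              flat_similarity(dis, 0.2, "disease_semantic"), fams)
  rec <- tidy(ev)
  r <- rec[rec$miRNA == "m1" & rec$disease == "d1", ]
  expect_lte(r$rank / r$n_candidates, 0.1)
})

test_that("masking is deterministic under a seed and guards its bounds", {
  net <- small_network(seed = 6)
  m1 <- mask_experiment(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams,
                        mask_ratio = 0.3, n_repeats = 3, seed = 7)
  m2 <- mask_experiment(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams,
                        mask_ratio = 0.3, n_repeats = 3, seed = 7)
  expect_identical(m1$per_repeat$auc, m2$per_repeat$auc)
  m3 <- mask_experiment(net$assoc, net$sim_mir_fun, net$sim_dd_phe, net$fams,
                        mask_ratio = 0.3, n_repeats = 3, seed = 8)
  expect_false(identical(m1$per_repeat$auc, m3$per_repeat$auc))
  expect_error(mask_experiment(net$assoc, net$sim_mir_fun, net$sim_dd_phe,
                               net$fams, mask_ratio = 0.001), "mask 0 entries")
  expect_error(mask_experiment(net$assoc, net$sim_mir_fun, net$sim_dd_phe,
                               net$fams, mask_ratio = 1.2), "in \\(0, 1\\)")
})

test_that("an isolated disease with a twin pattern ranks its miRNAs above the median", {
  # d2 duplicates d1's interaction pattern and is semantically close to it
  mir <- paste0("m", 1:8)
  dis <- paste0("d", 1:3)
  A <- matrix(0, 8, 3, dimnames = list(mir, dis))
  A[c(1, 3, 5), 1] <- 1
  A[c(1, 3, 5), 2] <- 1
  A[7, 3] <- 1
  a <- association_matrix(A, mir, dis)
  phe <- matrix(0.05, 3, 3); phe[1, 2] <- phe[2, 1] <- 0.95; diag(phe) <- 1
  ev <- isolated_disease_eval(a, flat_similarity(mir, 0.1),
                              similarity_matrix(phe, dis,
                                                kind = "disease_semantic"),
                              NULL, disease_id = "d2")
  recs <- tidy(ev)
  expect_true(all(recs$rank[recs$label == 1] <= nrow(recs) / 2))
  expect_gt(ev$auc, 0.9)
})

test_that("an isolated disease dissimilar to every other is near chance", {
  set.seed(70)
  aucs <- vapply(1:10, function(s) {
    net <- small_network(seed = s, m = 15, n = 8, density = 0.2)
    phe <- unclass(net$sim_dd_phe)
    phe[1, ] <- phe[, 1] <- 0; phe[1, 1] <- 1  # sever disease 1
    d <- colnames(net$assoc)[1]
    if (sum(net$assoc[, d]) == 0) return(NA_real_)
    isolated_disease_eval(net$assoc,
                          net$sim_mir_fun,
                          similarity_matrix(phe, colnames(net$assoc),
                                            kind = "disease_semantic"),
                          net$fams, disease_id = d)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.15)
})

test_that("unknown disease labels are rejected", {
  net <- small_network(seed = 2, m = 8, n = 5)
  expect_error(isolated_disease_eval(net$assoc, net$sim_mir_fun,
                                     net$sim_dd_phe, net$fams,
                                     disease_id = "no-such-disease"),
               "unknown disease")
})
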