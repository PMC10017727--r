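small_grid1 <- c(1e-3, 1e-2, 1e-1)
small_grid2 <- c(1e-3, 1e-1)

test_that("RMSE and correlation metrics match hand computation", {
  m <- compute_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(m$rmse, 0); expect_equal(m$cc, 1)
  m2 <- compute_metrics(c(0, 1, 2), c(1, 2, 3))
  expect_equal(m2$rmse, 1); expect_equal(m2$cc, 1)
  m3 <- compute_metrics(c(0, 1, 2), c(2, 1, 0))
  expect_equal(m3$cc, -1); expect_equal(m3$rmse, sqrt(8 / 3))
  m4 <- compute_metrics(c(0, 1, 2), c(1, 1, 1))
  expect_equal(m4$cc, 0); expect_true(m4$degenerate)
  expect_error(compute_metrics(1:3, 1:4), "equal length")
})

test_that("the default penalty ladder is the 12-value half-decade grid", {
  g <- lambda_ladder()
  expect_length(g, 12)
  expect_equal(g[1:4], c(1e-5, 3e-5, 1e-4, 3e-4))
  expect_equal(g[11:12], c(1, 3))
})

test_that("folds partition subjects, stratify by stage, and are seed-stable", {
  sim <- simulate_cohort(n = 100, d = 10, support_size = 3, seed = 5)
  cv <- nested_cv(sim$X, sim$y, sim$stages, variant = "MM",
                  lambda1_grid = small_grid1, repeats = 1, k = 5, seed = 9)
  folds <- cv$folds[[1]]
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100)
  # near-equal fold sizes (stratification balances within each stage)
  expect_true(all(abs(as.numeric(table(folds)) - 20) <= 2))
  # each fold carries every stage (counts allow it at these proportions)
  for (f in 1:5)
    expect_setequal(unique(sim$stages[folds == f]), c("HC", "MD", "SD"))
  # determinism: identical metrics on rerun with the same seed
  cv2 <- nested_cv(sim$X, sim$y, sim$stages, variant = "MM",
                   lambda1_grid = small_grid1, repeats = 1, k = 5, seed = 9)
  expect_identical(cv$metrics, cv2$metrics)
  expect_identical(cv$selected, cv2$selected)
  # different repeats use different fold assignments
  cv3 <- nested_cv(sim$X, sim$y, sim$stages, variant = "MM",
                   lambda1_grid = small_grid1, repeats = 2, k = 5, seed = 9)
  expect_false(identical(cv3$folds[[1]], cv3$folds[[2]]))
})

test_that("planted signal is detected far above the permutation null", {
  sim <- simulate_cohort(n = 120, d = 12, support_size = 4, seed = 21)
  cv <- nested_cv(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                  lambda1_grid = small_grid1, lambda2_grid = small_grid2,
                  repeats = 2, k = 5, seed = 3)
  mean_cc <- mean(cv$metrics$cc_test)
  null_cc <- permutation_null_cc(sim$X, sim$y, sim$stages,
                                 lambda1 = 0.05, lambda2 = 0.01,
                                 n_perm = 30, k = 5, seed = 4)
  expect_gt(mean_cc, mean(null_cc) + 3 * sd(null_cc))
})

test_that("ROI ranking agrees with a sort-based oracle and finds planted rows", {
  sim <- simulate_cohort(n = 120, d = 15, support_size = 3, seed = 31)
  cv <- nested_cv(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                  lambda1_grid = small_grid1, lambda2_grid = small_grid2,
                  repeats = 1, k = 5, seed = 7)
  rk <- rank_rois(cv, modality = "node", top_k = 15)
  expect_setequal(rk$roi, rownames(cv$weights_mean_abs))
  # exhaustive-sort oracle on the averaged weights
  wa <- cv$weights_mean_abs[, "node"]
  expect_equal(rk$mean_abs_weight, unname(sort(wa, decreasing = TRUE)),
               tolerance = 1e-15)
  top <- rank_rois(cv, modality = "node", top_k = 3)$roi
  planted <- rownames(cv$weights_mean_abs)[sim$support]
  expect_gte(length(intersect(top, planted)), 2)
  expect_error(rank_rois(cv, modality = "nope"), "unknown modality")
})

test_that("hyperparameter selection never sees the held-out fold", {
  sim <- simulate_cohort(n = 60, d = 8, support_size = 3, seed = 41)
  cv <- nested_cv(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                  lambda1_grid = small_grid1, lambda2_grid = small_grid2,
                  repeats = 1, k = 5, seed = 13)
  folds <- cv$folds[[1]]
  for (f in 1:5) {
    y_bad <- sim$y
    y_bad[folds == f] <- rev(y_bad[folds == f]) + 5  # corrupt test labels
    cv_bad <- nested_cv(sim$X, y_bad, sim$stages, variant = "MSD-MM",
                        lambda1_grid = small_grid1,
                        lambda2_grid = small_grid2,
                        repeats = 1, k = 5, seed = 13)
    sel <- cv$selected[cv$selected$fold == f, c("lambda1", "lambda2")]
    sel_bad <- cv_bad$selected[cv_bad$selected$fold == f,
                               c("lambda1", "lambda2")]
    expect_identical(sel, sel_bad)
    tr <- cv$metrics[cv$metrics$fold == f, c("rmse_train", "cc_train")]
    tr_bad <- cv_bad$metrics[cv_bad$metrics$fold == f,
                             c("rmse_train", "cc_train")]
    expect_identical(tr, tr_bad)
  }
})

test_that("SNP screening ranks the causal SNP first and is consistent at S = 1", {
  sim <- simulate_cohort(n = 100, d = 10, support_size = 3, seed = 51)
  set.seed(52)
  G <- cbind(causal = sim$y,
             sapply(1:4, function(i) simulate_genotype(100, 0.3, seed = 60 + i)))
  colnames(G) <- c("causal", paste0("null", 1:4))
  res <- screen_snps(sim$X, sim$stages, G, variant = "MM",
                     lambda1_grid = small_grid1, repeats = 1, k = 5, seed = 1)
  expect_equal(res$snp[1], "causal")
  expect_equal(nrow(res), 5)
  # single-SNP screening equals a direct nested_cv call
  res1 <- screen_snps(sim$X, sim$stages, G[, "causal", drop = FALSE],
                      variant = "MM", lambda1_grid = small_grid1,
                      repeats = 1, k = 5, seed = 1)
  cv1 <- nested_cv(sim$X, sim$y, sim$stages, variant = "MM",
                   lambda1_grid = small_grid1, repeats = 1, k = 5, seed = 1)
  agg <- aggregate(cc_test ~ modality, data = cv1$metrics, FUN = mean)
  expect_equal(res1$cc_node, agg$cc_test[agg$modality == "node"])
  expect_equal(res1$cc_edge, agg$cc_test[agg$modality == "edge"])
  # constant column is skipped with a message
  Gc <- cbind(G, mono = rep(0, 100))
  expect_message(res2 <- screen_snps(sim$X, sim$stages, Gc, variant = "MM",
                                     lambda1_grid = small_grid1,
                                     repeats = 1, k = 5, seed = 1),
                 "constant SNP")
  expect_false("mono" %in% res2$snp)
})

test_that("sensitivity grids reduce to single runs and saturate at lambda1_max", {
  sim <- simulate_cohort(n = 80, d = 8, support_size = 3, seed = 61)
  g1 <- sensitivity_grid(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                         lambda1_grid = 0.05, lambda2_grid = 0.01,
                         k = 5, seed = 2)
  expect_equal(dim(g1$node), c(1, 1))
  # a 1x1 grid cell matches the same cell inside a larger grid (same folds)
  g2 <- sensitivity_grid(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                         lambda1_grid = c(0.05, 0.2),
                         lambda2_grid = c(0.01, 0.1), k = 5, seed = 2)
  expect_equal(g2$node[1, 1], g1$node[1, 1])
  expect_equal(g2$edge[1, 1], g1$edge[1, 1])
  # a saturating lambda1 forces zero weights, so predictions degenerate
  lmax <- lambda1_max(sim$X, sim$y)
  g3 <- sensitivity_grid(sim$X, sim$y, sim$stages, variant = "MSD-MM",
                         lambda1_grid = lmax * 1.5, lambda2_grid = 0.01,
                         k = 5, seed = 2)
  expect_true(attr(g3, "degenerate")[1, 1])
  expect_equal(g3$node[1, 1], 0)
})
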