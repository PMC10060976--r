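# PAM/cosine clustering, diagnostics and k-NN projection.

test_that("cosine distance covers collinear, orthogonal, antipodal cases", {
  expect_equal(cosine_distance(c(1, 1), c(2, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("pam_fit solves the worked instance and matches exhaustive search", {
  x <- rbind(c(1, 0.9, 0, 0.1), c(0, 0.1, 1, 0.9))
  colnames(x) <- paste0("s", 1:4)
  fit <- pam_fit(x, k = 2)
  expect_true(same_partition(fit$assignments, c(1, 1, 2, 2)))

  # k = n: every point its own medoid, zero cost
  full <- pam_fit(x, k = 4)
  expect_equal(full$cost, 0)
  expect_equal(sort(full$medoid_ids), colnames(x))

  # oracle equivalence on random small instances
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    xi <- matrix(rnorm(3 * n), 3, n, dimnames = list(NULL, paste0("s", 1:n)))
    fit_i <- pam_fit(xi, k = k)
    oracle <- oracle_kmedoids(xi, k)
    expect_equal(fit_i$cost, oracle$cost, tolerance = 1e-9)
    expect_true(same_partition(fit_i$assignments, oracle$assignments))
  }

  # duplicating every point keeps the partition structure
  xd <- cbind(x, x)
  colnames(xd) <- paste0("s", 1:8)
  fitd <- pam_fit(xd, k = 2)
  expect_true(same_partition(fitd$assignments,
                             rep(fit$assignments, 2)))

  xdup <- x[, c(1, 1, 1, 1)]
  colnames(xdup) <- paste0("s", 1:4)
  expect_error(pam_fit(xdup, k = 2), "distinct")
})

test_that("cluster naming follows mean panel expression, not input order", {
  sim <- simulate_cohort(simulation_design(seed = 77, n_samples = 80), 1)
  tum <- tumor_only(sim$cohort)
  cm <- chemokine_clusters(tum, default_chemokine_panel())
  expect_s3_class(cm, "cluster_model")
  high <- names(cm$assignments)[cm$assignments == "high"]
  low <- names(cm$assignments)[cm$assignments == "low"]
  pm <- colMeans(zscore_genes(tum, default_chemokine_panel())$scaled)
  expect_gt(mean(pm[high]), mean(pm[low]))

  # reversing sample order must not flip high/low semantics
  rev_ids <- rev(tum$sample_meta$sample_id)
  cm_rev <- chemokine_clusters(subset_cohort(tum, rev_ids),
                               default_chemokine_panel())
  expect_equal(as.character(cm_rev$assignments[names(cm$assignments)]),
               as.character(cm$assignments))
})

test_that("k diagnostics pick the planted two-cluster structure", {
  sim <- simulate_cohort(simulation_design(seed = 41), 1)
  x <- zscore_genes(tumor_only(sim$cohort), default_chemokine_panel())$scaled
  ck <- choose_k(x, 2:6)
  expect_equal(ck$recommended_k, 2L)
  expect_equal(ck$metrics$k, 2:6)
  expect_true(all(ck$metrics$avg_silhouette >= -1 &
                    ck$metrics$avg_silhouette <= 1))

  # pure noise: silhouettes stay low for every k
  sim0 <- simulate_cohort(simulation_design(seed = 42, panel_shift = 0,
                                            module_shifts = c(IFN = 0, EXH = 0,
                                                              OXPHOS = 0,
                                                              TCA = 0, FAO = 0,
                                                              TRP = 0)), 1)
  x0 <- zscore_genes(tumor_only(sim0$cohort), default_chemokine_panel())$scaled
  ck0 <- choose_k(x0, 2:6)
  expect_true(all(ck0$metrics$avg_silhouette < 0.2))

  # k = n - 1 exercises the singleton convention without error
  small <- x[, 1:6]
  expect_no_error(choose_k(small, ks = 5))
})

test_that("explained variance matches its boundary cases", {
  set.seed(8)
  x <- matrix(rnorm(20), 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  expect_equal(explained_variance(x, seq_len(10)), 1)
  expect_equal(explained_variance(x, rep(1, 10)), 0)
  ident <- matrix(1, 2, 5, dimnames = list(NULL, paste0("s", 1:5)))
  expect_error(explained_variance(ident, rep(1:2, c(2, 3))), "identical")
})

test_that("cross-validation reports stability of the planted structure", {
  sim <- simulate_cohort(simulation_design(seed = 19), 1)
  x <- zscore_genes(tumor_only(sim$cohort), default_chemokine_panel())$scaled
  cv <- crossvalidate(x, k = 2, folds = 10, seed = 1)
  expect_gt(cv$mean_ari, 0.9)
  expect_length(cv$ari, 10L)
  expect_error(crossvalidate(x, k = 2, folds = 1), ">= 2")
})

test_that("k-NN projection obeys zero-distance and ordering rules", {
  sim <- simulate_cohort(simulation_design(seed = 23), 1)
  tum <- tumor_only(sim$cohort)
  cm <- chemokine_clusters(tum, default_chemokine_panel())

  # projecting the training cohort back onto itself (training scaling) must
  # copy labels through the zero-distance rule
  self <- knn_project(cm, tum, scaling = "train")
  expect_equal(as.character(self), as.character(cm$assignments))

  expect_error(knn_project(cm, tum, k_neighbors = 10000), "exceeds")
  broken <- tum$values[-match("CXCL9", rownames(tum$values)), ]
  expect_error(knn_project(cm, broken), "CXCL9")

  # invariance to training-sample order: permute stored training data
  cm_perm <- cm
  perm <- sample(ncol(cm$train_scaled))
  cm_perm$train_scaled <- cm$train_scaled[, perm]
  cm_perm$assignments <- cm$assignments[perm]
  sib <- tumor_only(simulate_cohort(simulation_design(seed = 23), 2)$cohort)
  expect_equal(knn_project(cm, sib), knn_project(cm_perm, sib))
})
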