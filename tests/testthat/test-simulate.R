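# Synthetic multi-cohort generator: determinism, planted structure, truth.

test_that("design validation rejects out-of-range parameters", {
  expect_error(simulation_design(n_samples = 5), ">= 10")
  expect_error(simulation_design(cluster_prevalence = 1), "\\(0, 1\\)")
  expect_error(simulation_design(panel_shift = -1), ">= 0")
  expect_error(simulation_design(noise_sd = 0), "> 0")
  expect_error(simulation_design(paired_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_design(baseline_hazard = 0), "> 0")
  expect_error(simulation_design(censoring_rate = 1), "\\[0, 1\\)")
  expect_error(simulation_design(n_genes = 50), "at least")
})

test_that("identical design and seed give bit-identical cohorts", {
  d <- small_design(seed = 9)
  a <- simulate_cohort(d, 1)
  b <- simulate_cohort(d, 1)
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$infiltration$scores, b$infiltration$scores)
  expect_identical(a$truth$cluster_labels, b$truth$cluster_labels)
  # different cohort index -> different draws, same gene baselines
  c2 <- simulate_cohort(d, 2)
  expect_false(identical(a$cohort$values[, 1], c2$cohort$values[, 1]))
  expect_identical(rownames(a$cohort$values), rownames(c2$cohort$values))
})

test_that("paired normals carry the planted enrichment and respect fractions", {
  # isolate the enrichment by switching all cluster effects off
  d <- simulation_design(seed = 3, n_samples = 334, panel_shift = 0,
                         module_shifts = c(IFN = 0, EXH = 0, OXPHOS = 0,
                                           TCA = 0, FAO = 0, TRP = 0))
  sim <- simulate_cohort(d, 1)
  meta <- sim$cohort$sample_meta
  n_ids <- meta$sample_id[meta$tissue == "normal"]
  expect_equal(length(n_ids), 100L)           # floor(0.3 * 334)
  donors <- meta$donor_id[match(n_ids, meta$sample_id)]
  t_ids <- meta$sample_id[meta$tissue == "tumor"][
    match(donors, meta$donor_id[meta$tissue == "tumor"])]
  pt <- paired_t_test(colMeans(sim$cohort$values[default_chemokine_panel(), t_ids]),
                      colMeans(sim$cohort$values[default_chemokine_panel(), n_ids]))
  expect_lt(abs(pt$mean_diff - 2), 0.35)      # recovers tumor_enrichment

  none <- simulate_cohort(small_design(seed = 4, paired_fraction = 0), 1)
  expect_false(any(none$cohort$sample_meta$tissue == "normal"))
})

test_that("null genes keep their marginal moments and stay unselected", {
  d <- simulation_design(seed = 12, n_samples = 1000, paired_fraction = 0)
  sim <- simulate_cohort(d, 1)
  gt <- chemoclust:::design_gene_table(d)
  bg <- gt$gene[gt$module == "background"][1:20]
  mu <- setNames(gt$mu, gt$gene)[bg]
  # per-gene mean within 3 standard errors of mu + cohort offset is not
  # directly checkable (offset unknown to the test) but SD must track sigma
  sds <- apply(sim$cohort$values[bg, ], 1, sd)
  se_sd <- d$noise_sd / sqrt(2 * (d$n_samples - 1))
  expect_true(all(abs(sds - d$noise_sd) < 4 * se_sd))
  # and the gene means stay within offset (sd 0.3) + 3 SE of the baseline
  means <- rowMeans(sim$cohort$values[bg, ])
  expect_true(all(abs(means - mu) < 3 * sqrt(0.3^2 + 1 / d$n_samples)))
})

test_that("no-signal designs yield no recoverable clustering", {
  d0 <- small_design(seed = 6, panel_shift = 0,
                     module_shifts = c(IFN = 0, EXH = 0, OXPHOS = 0,
                                       TCA = 0, FAO = 0, TRP = 0))
  sim <- simulate_cohort(d0, 1)
  tum <- tumor_only(sim$cohort)
  cm <- chemokine_clusters(tum, default_chemokine_panel())
  ari <- mclust::adjustedRandIndex(
    as.character(cm$assignments),
    sim$truth$cluster_labels[names(cm$assignments)])
  expect_lt(abs(ari), 0.2)
})

test_that("infiltration couples the CD8 score to panel expression", {
  sim <- simulate_cohort(simulation_design(seed = 8), 1)
  sc <- sim$infiltration$scores
  expect_true(all(sc > 0 & sc < 1))
  tum_ids <- colnames(sc)
  rho <- spearman_cor(sim$cohort$values["CXCL9", tum_ids],
                      sc["T cell CD8+", ])$rho
  expect_gt(rho, 0.6)
  # the unlinked cell type stays near zero
  rho0 <- spearman_cor(sim$cohort$values["CXCL9", tum_ids],
                       sc["Neutrophil", ])$rho
  expect_lt(abs(rho0), 0.25)
})

test_that("survival generator hits the planted hazard and censoring rate", {
  d <- simulation_design(seed = 14, n_samples = 400,
                         cluster_log_hr = log(2), stage_log_hr = 0,
                         grade_log_hr = 0)
  set.seed(100)
  z <- rbinom(400, 1, 0.5)
  surv <- simulate_survival(d, z)
  expect_true(all(surv$os_time > 0))
  expect_lt(abs(mean(1 - surv$os_event) - d$censoring_rate), 0.08)
  fit <- survival::coxph(survival::Surv(surv$os_time, surv$os_event) ~ z)
  ci <- confint(fit)
  expect_true(ci[1] < log(2) && log(2) < ci[2])
})

test_that("toy metabolic model truth equals exact GPR evaluation", {
  d <- small_design(seed = 5)
  tm <- toy_metabolic_model(d)
  expect_gte(nrow(tm$model$reactions), 12L)
  expect_gte(length(setdiff(unique(tm$model$reactions$subsystem),
                            "Transport")), 4L)
  # truth recomputed through the independent R-parser oracle
  act <- 2^tm$gene_effects
  for (i in which(tm$model$reactions$has_gpr)) {
    rule <- tm$model$reactions$gpr[i]
    expected <- log2(oracle_gpr_eval(rule, act)) -
      log2(oracle_gpr_eval(rule, setNames(rep(1, length(act)),
                                          names(act))))
    j <- match(tm$model$reactions$reaction_id[i], tm$reaction_truth$reaction_id)
    expect_equal(tm$reaction_truth$log2_reg_true[j], expected,
                 tolerance = 1e-12)
  }
  # all effects zero -> all true regulations zero
  d0 <- small_design(seed = 5, panel_shift = 0,
                     module_shifts = c(IFN = 0, EXH = 0, OXPHOS = 0,
                                       TCA = 0, FAO = 0, TRP = 0))
  tm0 <- toy_metabolic_model(d0)
  expect_true(all(tm0$reaction_truth$log2_reg_true == 0))
})

test_that("whole-study wrapper wires cohorts and the toy model together", {
  st <- simulate_study(small_design(seed = 10))
  expect_length(st$cohorts, 1L)
  expect_s3_class(st$cohorts[[1]]$cohort, "expression_cohort")
  expect_s3_class(st$metabolic$model, "metabolic_model")
})
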