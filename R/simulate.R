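# Multi-cohort synthetic data generator with full ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: two latent chemokine clusters separated on an 8-gene panel,
# donor-paired tumor/normal samples with planted tumor enrichment of the
# panel, CD8 infiltration scores coupled to mean panel expression,
# co-regulated IFN/exhaustion/metabolic gene modules, survival times with a
# configurable (default null) cluster effect, and a toy metabolic model
# whose true reaction regulation is analytically computable.

#' Default chemokine gene panel
#'
#' The three ligand/receptor axes CXCL9/10/11-CXCR3, CXCL13-CXCR5 and
#' XCL1-XCR1.
#'
#' @return Character vector of 8 gene symbols.
#' @export
default_chemokine_panel <- function() {
  c("CXCL9", "CXCL10", "CXCL11", "CXCR3", "CXCL13", "CXCR5", "XCL1", "XCR1")
}

#' Simulation design for synthetic multi-cohort data
#'
#' All knobs of the generator with defaults matching the intended study
#' conditions. Expression follows `x_gi = mu_g + cohort_offset_g +
#' tumor_enrichment * panel_g + effect_g * z_i + eps` with `z_i` the latent
#' cluster indicator; paired normal samples carry the baseline only, so the
#' expected paired tumor-vs-normal contrast of a panel gene is
#' `tumor_enrichment + cluster_prevalence * panel_shift`.
#'
#' @param n_samples Tumor samples per cohort (>= 10; default 200).
#' @param n_cohorts Number of cohorts sharing one design (default 2).
#' @param n_genes Total genes, including panel, modules and background
#'   (default 200).
#' @param chemokine_panel The 8 panel genes.
#' @param cluster_prevalence Probability of the chemokine-high cluster
#'   (default 0.5).
#' @param panel_shift Cluster-high vs cluster-low shift of panel genes in
#'   log2 units (default 2).
#' @param module_shifts Named log2 shifts per gene module (IFN and
#'   exhaustion up, OXPHOS/TCA/FAO down, TRP up in the high cluster).
#' @param module_sizes Genes per module.
#' @param tumor_enrichment Log2 shift of panel genes, tumor vs paired
#'   normal (default 2, i.e. four-fold).
#' @param paired_fraction Fraction of tumor donors with a matched normal
#'   sample (default 0.3).
#' @param infiltration_link Slope of the CD8 score linear predictor on mean
#'   panel expression (default 1).
#' @param infiltration_noise SD of the noise on that linear predictor
#'   (default 0.35; yields a planted CD8-panel Spearman rho around 0.7).
#' @param noise_sd Residual SD of log2 expression (default 1).
#' @param baseline_hazard Exponential event hazard per day (default 1/1500,
#'   median overall survival around 1000 days).
#' @param cluster_log_hr Log hazard ratio of the high vs low cluster
#'   (default 0: the null survival scenario).
#' @param stage_log_hr,grade_log_hr Log-HR per stage/grade level (defaults
#'   0.35 and 0.25) — the clinical effects ridge models should pick up.
#' @param censoring_rate Target fraction of censored observations
#'   (default 0.3; must be < 1).
#' @param seed Integer seed; identical design + seed gives bit-identical
#'   output.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_samples = 200L,
                              n_cohorts = 2L,
                              n_genes = 200L,
                              chemokine_panel = default_chemokine_panel(),
                              cluster_prevalence = 0.5,
                              panel_shift = 2,
                              module_shifts = c(IFN = 1, EXH = 1,
                                                OXPHOS = -1, TCA = -1,
                                                FAO = -1, TRP = 1),
                              module_sizes = c(IFN = 20, EXH = 20,
                                               OXPHOS = 14, TCA = 13,
                                               FAO = 13, TRP = 10),
                              tumor_enrichment = 2,
                              paired_fraction = 0.3,
                              infiltration_link = 1,
                              infiltration_noise = 0.35,
                              noise_sd = 1,
                              baseline_hazard = 1 / 1500,
                              cluster_log_hr = 0,
                              stage_log_hr = 0.35,
                              grade_log_hr = 0.25,
                              censoring_rate = 0.3,
                              seed = 1L) {
  if (n_samples < 10L) stop("`n_samples` must be >= 10", call. = FALSE)
  if (panel_shift < 0) stop("`panel_shift` must be >= 0", call. = FALSE)
  if (cluster_prevalence <= 0 || cluster_prevalence >= 1) {
    stop("`cluster_prevalence` must lie in (0, 1)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (paired_fraction < 0 || paired_fraction > 1) {
    stop("`paired_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be > 0",
                                 call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("`censoring_rate` must lie in [0, 1)", call. = FALSE)
  }
  need <- length(chemokine_panel) + sum(module_sizes)
  if (n_genes < need) {
    stop("`n_genes` must be at least ", need,
         " to hold the panel and all modules", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_cohorts = as.integer(n_cohorts),
         n_genes = as.integer(n_genes), chemokine_panel = chemokine_panel,
         cluster_prevalence = cluster_prevalence, panel_shift = panel_shift,
         module_shifts = module_shifts, module_sizes = module_sizes,
         tumor_enrichment = tumor_enrichment,
         paired_fraction = paired_fraction,
         infiltration_link = infiltration_link,
         infiltration_noise = infiltration_noise,
         noise_sd = noise_sd, baseline_hazard = baseline_hazard,
         cluster_log_hr = cluster_log_hr, stage_log_hr = stage_log_hr,
         grade_log_hr = grade_log_hr, censoring_rate = censoring_rate,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# Deterministic sub-seed, kept below 2^31.
derive_seed <- function(seed, index, salt) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * index + 7919 * salt) %%
               2147483646) + 1L
}

# Gene table shared by all cohorts of a design: names, module membership,
# baseline means and per-gene true cluster effects. Effects within a module
# spread uniformly over [0.6, 1.4] x the module shift, so complex subunits
# in the toy metabolic model carry distinct (realistic) effect sizes.
design_gene_table <- function(design) {
  panel <- design$chemokine_panel
  sizes <- design$module_sizes
  mod_genes <- unlist(lapply(names(sizes), function(m) {
    sprintf("%s%02d", m, seq_len(sizes[[m]]))
  }))
  n_bg <- design$n_genes - length(panel) - length(mod_genes)
  bg <- if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character(0L)
  gene <- c(panel, mod_genes, bg)
  module <- c(rep("panel", length(panel)),
              rep(names(sizes), sizes),
              rep("background", n_bg))
  set.seed(derive_seed(design$seed, 0L, 1L))
  mu <- rnorm(length(gene), mean = 6, sd = 1.5)
  spread <- runif(length(gene), 0.6, 1.4)
  effect <- numeric(length(gene))
  effect[module == "panel"] <- design$panel_shift
  for (m in names(sizes)) {
    effect[module == m] <- design$module_shifts[[m]] * spread[module == m]
  }
  tibble(gene = gene, module = module, mu = mu, effect = effect)
}

#' Simulate survival outcomes
#'
#' Exponential event times with hazard `h0 * exp(log_hr * z + extra_lp)`
#' and independent uniform censoring calibrated (numerically) to the target
#' censoring rate.
#'
#' @param design A `simulation_design`.
#' @param cluster_labels 0/1 vector (1 = chemokine-high).
#' @param extra_lp Optional additional linear predictor (e.g. clinical
#'   effects), same length.
#' @return Tibble with `os_time` (days) and `os_event`.
#' @export
simulate_survival <- function(design, cluster_labels, extra_lp = NULL) {
  z <- as.numeric(cluster_labels)
  n <- length(z)
  if (is.null(extra_lp)) extra_lp <- rep(0, n)
  h <- design$baseline_hazard * exp(design$cluster_log_hr * z + extra_lp)
  t_event <- rexp(n, rate = h)
  r <- design$censoring_rate
  if (r == 0) {
    return(tibble(os_time = t_event, os_event = rep(1, n)))
  }
  p_cens <- function(u) mean((1 - exp(-h * u)) / (h * u)) - r
  u <- uniroot(p_cens, lower = 1e-6 / design$baseline_hazard,
               upper = 1e6 / design$baseline_hazard)$root
  c_time <- runif(n, 0, u)
  tibble(os_time = pmin(t_event, c_time),
         os_event = as.integer(t_event <= c_time))
}

#' Simulate donor-matched normal kidney samples
#'
#' For `paired_fraction` of the cohort's tumor donors (the first ones, by
#' construction deterministic), emits a normal sample whose panel genes sit
#' `tumor_enrichment` log2 units below the matched tumor baseline and whose
#' remaining genes are null with respect to the tumor.
#'
#' @param design A `simulation_design`.
#' @param cohort_index Cohort number (matches [simulate_cohort()]).
#' @return List with `values` (genes x normal samples), `donor_ids` and
#'   `sample_ids`; empty matrices when `paired_fraction = 0`.
#' @export
simulate_paired_normals <- function(design, cohort_index = 1L) {
  gt <- design_gene_table(design)
  n_pairs <- floor(design$paired_fraction * design$n_samples)
  genes <- gt$gene
  if (n_pairs == 0L) {
    return(list(values = matrix(numeric(0L), nrow = length(genes), ncol = 0L,
                                dimnames = list(genes, NULL)),
                donor_ids = character(0L), sample_ids = character(0L)))
  }
  set.seed(derive_seed(design$seed, cohort_index, 2L))
  offset <- rnorm(length(genes), 0, 0.3)
  set.seed(derive_seed(design$seed, cohort_index, 4L))
  eps <- matrix(rnorm(length(genes) * n_pairs, 0, design$noise_sd),
                nrow = length(genes))
  values <- gt$mu + offset + eps
  sample_ids <- sprintf("C%d_N%03d", cohort_index, seq_len(n_pairs))
  donor_ids <- sprintf("C%d_D%03d", cohort_index, seq_len(n_pairs))
  dimnames(values) <- list(genes, sample_ids)
  list(values = values, donor_ids = donor_ids, sample_ids = sample_ids)
}

#' Simulate one synthetic cohort
#'
#' Draws cluster labels `Bernoulli(prevalence)`, builds the tumor expression
#' matrix `x_gi = mu_g + cohort_offset_g + enrichment * panel_g +
#' effect_g * z_i + eps`, appends donor-paired normal samples,
#' couples the CD8 infiltration score to mean panel expression through a
#' noisy logistic link, and attaches survival and clinical metadata.
#'
#' @param design A `simulation_design`.
#' @param cohort_index Cohort number (1-based); cohorts of one design share
#'   gene baselines but carry their own per-gene offsets.
#' @return List with `cohort` (`expression_cohort`, tumor + normal samples),
#'   `infiltration` (`infiltration_table` over tumor samples) and `truth`
#'   (`ground_truth`: cluster labels, per-gene effects, planted log-HRs).
#' @export
simulate_cohort <- function(design, cohort_index = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  gt <- design_gene_table(design)
  genes <- gt$gene
  n <- design$n_samples
  pan <- gt$module == "panel"

  set.seed(derive_seed(design$seed, cohort_index, 2L))
  offset <- rnorm(length(genes), 0, 0.3)

  set.seed(derive_seed(design$seed, cohort_index, 3L))
  z <- rbinom(n, 1L, design$cluster_prevalence)
  eps <- matrix(rnorm(length(genes) * n, 0, design$noise_sd),
                nrow = length(genes))
  values <- gt$mu + offset + design$tumor_enrichment * pan +
    outer(gt$effect, z) + eps
  sample_ids <- sprintf("C%d_S%03d", cohort_index, seq_len(n))
  donor_ids <- sprintf("C%d_D%03d", cohort_index, seq_len(n))
  dimnames(values) <- list(genes, sample_ids)

  # infiltration scores: logistic link on mean panel expression, noise on
  # the linear predictor (keeps scores in (0, 1) and ranks intact)
  m <- colMeans(values[pan, , drop = FALSE])
  lin <- design$infiltration_link * (m - mean(m))
  cell_types <- c("T cell CD8+", "T cell CD4+", "Macrophage M1", "B cell",
                  "NK cell", "Neutrophil")
  slope <- c(1, 0.4, 0.6, 0.3, 0.2, 0)
  noise <- c(design$infiltration_noise, 0.8, 0.6, 0.9, 1, 1)
  scores <- t(vapply(seq_along(cell_types), function(k) {
    plogis(slope[k] * lin + rnorm(n, 0, noise[k]))
  }, numeric(n)))
  dimnames(scores) <- list(cell_types, sample_ids)

  stage <- sample(1:4, n, replace = TRUE, prob = c(0.5, 0.14, 0.3, 0.06))
  grade <- sample(1:4, n, replace = TRUE, prob = c(0.05, 0.45, 0.35, 0.15))
  extra_lp <- design$stage_log_hr * (stage - mean(stage)) +
    design$grade_log_hr * (grade - mean(grade))
  surv <- simulate_survival(design, z, extra_lp = extra_lp)

  normals <- simulate_paired_normals(design, cohort_index)
  all_values <- cbind(values, normals$values)
  meta <- tibble(
    sample_id = c(sample_ids, normals$sample_ids),
    tissue = c(rep("tumor", n), rep("normal", length(normals$sample_ids))),
    donor_id = c(donor_ids, normals$donor_ids),
    os_time = c(surv$os_time, rep(NA_real_, length(normals$sample_ids))),
    os_event = c(surv$os_event, rep(NA_integer_, length(normals$sample_ids))),
    stage = c(stage, rep(NA_integer_, length(normals$sample_ids))),
    grade = c(grade, rep(NA_integer_, length(normals$sample_ids))),
    response = NA_character_
  )
  cohort <- expression_cohort(sprintf("synthetic_C%d", cohort_index),
                              all_values, meta)

  truth <- structure(
    list(
      cluster_labels = setNames(ifelse(z == 1L, "high", "low"), sample_ids),
      gene_effects = setNames(gt$effect, genes),
      gene_modules = setNames(gt$module, genes),
      tumor_effects = setNames(design$tumor_enrichment * pan, genes),
      log_hr = c(cluster = design$cluster_log_hr,
                 stage = design$stage_log_hr,
                 grade = design$grade_log_hr)
    ),
    class = "ground_truth"
  )
  list(cohort = cohort, infiltration = infiltration_table(scores),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$cluster_labels), " samples; ",
      sum(x$gene_effects != 0), " genes with planted cluster effects\n",
      sep = "")
  invisible(x)
}

#' Toy metabolic model with analytically known regulation
#'
#' A 22-reaction model over the simulated metabolic module genes, spanning
#' the oxidative phosphorylation, citric acid cycle, fatty acid oxidation
#' and tryptophan metabolism subsystems (plus one GPR-free transport
#' reaction exercising the skip path). GPR rules mix `and`/`or` to depth 3.
#' The true regulation of each reaction is the exact GPR evaluation of the
#' planted per-gene log2 cluster effects against the all-ones baseline.
#'
#' @param design A `simulation_design`.
#' @return List with `model` (a `metabolic_model`), `reaction_truth`
#'   (tibble: `reaction_id`, `subsystem`, `log2_reg_true`) and
#'   `gene_effects` (named true per-gene log2 effects of the model genes).
#' @export
toy_metabolic_model <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  gt <- design_gene_table(design)
  rules <- c(
    R_OXPHOS_CI   = "(OXPHOS01 and OXPHOS02 and OXPHOS03) or (OXPHOS04 and OXPHOS05)",
    R_OXPHOS_CII  = "OXPHOS06 and OXPHOS07",
    R_OXPHOS_CIII = "OXPHOS08 and (OXPHOS09 or OXPHOS10)",
    R_OXPHOS_CIV  = "OXPHOS11 and OXPHOS12",
    R_OXPHOS_ATP  = "OXPHOS13 or OXPHOS14",
    R_TCA_CS      = "TCA01",
    R_TCA_ACO     = "TCA02 or TCA03",
    R_TCA_IDH     = "TCA04 and TCA05",
    R_TCA_OGDH    = "(TCA06 and TCA07) or TCA08",
    R_TCA_SDH     = "TCA09 and TCA10 and TCA11",
    R_TCA_MDH     = "TCA12 or TCA13",
    R_FAO_CPT     = "FAO01 and FAO02",
    R_FAO_ACAD    = "FAO03 or FAO04 or FAO05",
    R_FAO_ECH     = "FAO06",
    R_FAO_HADH    = "FAO07 and (FAO08 or FAO09)",
    R_FAO_KT      = "FAO10 or (FAO11 and FAO12)",
    R_TRP_IDO     = "TRP01 or TRP02",
    R_TRP_KYNU    = "TRP03",
    R_TRP_KMO     = "TRP04",
    R_TRP_KAT     = "TRP05 or TRP06",
    R_TRP_HAAO    = "TRP07",
    R_TRP_QPRT    = "TRP08 and TRP09"
  )
  subsystems <- c(
    rep("Oxidative phosphorylation", 5L),
    rep("Citric acid cycle", 6L),
    rep("Fatty acid oxidation", 5L),
    rep("Tryptophan metabolism", 6L)
  )
  reactions <- tibble(
    reaction_id = c(names(rules), "R_TRANSPORT_TRP"),
    gpr = c(unname(rules), ""),
    subsystem = c(subsystems, "Transport")
  )
  mod_genes <- gt$gene[gt$module %in% c("OXPHOS", "TCA", "FAO", "TRP")]
  model <- metabolic_model(reactions, mod_genes)
  eff <- setNames(gt$effect, gt$gene)[mod_genes]
  act <- setNames(2^eff, mod_genes)
  ones <- setNames(rep(1, length(mod_genes)), mod_genes)
  keep <- model$reactions[model$reactions$has_gpr, ]
  truth <- tibble(
    reaction_id = keep$reaction_id,
    subsystem = keep$subsystem,
    log2_reg_true = vapply(keep$tree, function(tr) {
      log2(evaluate_gpr(tr, act)) - log2(evaluate_gpr(tr, ones))
    }, numeric(1L))
  )
  list(model = model, reaction_truth = truth, gene_effects = eff)
}

#' Simulate a full multi-cohort study
#'
#' Convenience wrapper: all cohorts of the design plus the toy metabolic
#' model and its analytic truth.
#'
#' @param design A `simulation_design`.
#' @return List with `cohorts` (list of [simulate_cohort()] results, one
#'   per cohort) and `metabolic` (the [toy_metabolic_model()] output).
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  cohorts <- lapply(seq_len(design$n_cohorts), function(i) {
    simulate_cohort(design, cohort_index = i)
  })
  list(cohorts = cohorts, metabolic = toy_metabolic_model(design))
}
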