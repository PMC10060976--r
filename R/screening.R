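# Statistical primitives and the chemokine screening stage.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} p_(j) * m / j`, clipped
#' at 1 and returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Paired two-sided t-test with Cohen's d
#'
#' Operates on the pair differences `d = x - y`: `t = mean(d) / (sd(d) /
#' sqrt(n))` with `n - 1` degrees of freedom, and `cohens_d = mean(d) /
#' sd(d)`. Used for tumor vs donor-matched normal contrasts on the log2
#' scale, where `mean_diff` is a log2 fold change.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 3` without
#'   missing values.
#' @return One-row tibble: `mean_diff`, `se`, `t_stat`, `p`, `cohens_d`, `n`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("pairs must be complete", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("degenerate differences (zero variance)", call. = FALSE)
  se <- s / sqrt(n)
  t_stat <- mean(d) / se
  tibble(
    mean_diff = mean(d), se = se, t_stat = t_stat,
    p = 2 * pt(-abs(t_stat), df = n - 1L),
    cohens_d = mean(d) / s, n = n
  )
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks. The two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom; below `n = 10` (and without ties) the exact
#' permutation distribution is used instead.
#'
#' @param x,y Numeric vectors, `n >= 3`, no missing values.
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n < 10L && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2L)
  }
  tibble(rho = rho, p = p, n = n)
}

# Vectorized Welch t-test across matrix rows (used by the profiling stage).
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(t_stat), df = df)
  pooled <- sqrt(((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L))
  tibble(
    mean_diff = unname(m1 - m2), se = unname(sqrt(se2)),
    t_stat = unname(t_stat), df = unname(df), p = unname(p),
    cohens_d = unname((m1 - m2) / pooled), n = n1 + n2
  )
}

#' Screen candidate chemokine genes
#'
#' Applies the two screening rules to each candidate gene: (a) tumor
#' enrichment — paired t-test against donor-matched normal tissue with
#' BH-FDR < `fdr_threshold` and a mean log2 difference of at least
#' `log2(fold_threshold)` (default four-fold); and (b) infiltration link —
#' Spearman correlation with the CD8+ T cell score above `rho_threshold`
#' at BH-FDR < `fdr_threshold` among tumor samples. FDR is adjusted across
#' all evaluated candidates, separately per test family. Both statistics are
#' always reported so the gate is transparent.
#'
#' @param cohort An `expression_cohort` containing tumor and paired normal
#'   samples (`tissue` and `donor_id` metadata).
#' @param infiltration An `infiltration_table` covering the tumor samples.
#' @param candidates Character vector of candidate gene symbols.
#' @param fold_threshold Minimum linear fold change tumor vs normal
#'   (default 4).
#' @param rho_threshold Minimum Spearman rho with the CD8 score
#'   (default 0.6).
#' @param fdr_threshold FDR gate for both tests (default 0.05).
#' @param cd8_label Row of the infiltration table holding CD8+ T cell
#'   scores.
#' @return List with `selected` (gene symbols passing both rules), `stats`
#'   (per-gene tibble of both test batteries) and `not_evaluated`
#'   (candidates absent from the cohort).
#' @export
screen_chemokines <- function(cohort, infiltration, candidates,
                              fold_threshold = 4, rho_threshold = 0.6,
                              fdr_threshold = 0.05,
                              cd8_label = "T cell CD8+") {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(infiltration, "infiltration_table"))
  meta <- cohort$sample_meta
  if (!all(c("tissue", "donor_id") %in% names(meta))) {
    stop("cohort metadata needs `tissue` and `donor_id`", call. = FALSE)
  }
  tumor <- meta$sample_id[meta$tissue == "tumor"]
  normal <- meta$sample_id[meta$tissue == "normal"]
  donors_t <- meta$donor_id[match(tumor, meta$sample_id)]
  donors_n <- meta$donor_id[match(normal, meta$sample_id)]
  shared <- intersect(donors_t, donors_n)
  if (length(shared) < 3L) stop("no (or too few) paired samples", call. = FALSE)
  t_ids <- tumor[match(shared, donors_t)]
  n_ids <- normal[match(shared, donors_n)]

  if (!cd8_label %in% rownames(infiltration$scores)) {
    stop("infiltration table lacks cell type '", cd8_label, "'", call. = FALSE)
  }
  cd8_all <- infiltration$scores[cd8_label, ]
  tum_scored <- intersect(tumor, colnames(infiltration$scores))
  cd8 <- cd8_all[tum_scored]

  present <- candidates[toupper(candidates) %in% toupper(rownames(cohort$values))]
  not_evaluated <- setdiff(candidates, present)
  if (length(present) == 0L) stop("no candidate present in the cohort",
                                  call. = FALSE)
  idx <- match_genes(present, rownames(cohort$values))

  paired <- dplyr::bind_rows(lapply(seq_along(present), function(i) {
    g <- idx[i]
    res <- paired_t_test(cohort$values[g, t_ids], cohort$values[g, n_ids])
    res$gene <- present[i]
    res
  }))
  paired$fdr <- bh_fdr(paired$p)

  corr <- dplyr::bind_rows(lapply(seq_along(present), function(i) {
    g <- idx[i]
    res <- spearman_cor(cohort$values[g, tum_scored], cd8)
    res$gene <- present[i]
    res
  }))
  corr$fdr <- bh_fdr(corr$p)

  stats <- dplyr::left_join(
    dplyr::rename(paired, paired_p = p, paired_fdr = fdr),
    dplyr::rename(corr, cd8_rho = rho, rho_p = p, rho_fdr = fdr, n_cor = n),
    by = "gene"
  )
  stats$enriched <- stats$paired_fdr < fdr_threshold &
    stats$mean_diff >= log2(fold_threshold)
  stats$infiltration_linked <- stats$rho_fdr < fdr_threshold &
    stats$cd8_rho > rho_threshold
  stats$selected <- stats$enriched & stats$infiltration_linked
  stats <- stats[, c("gene", "mean_diff", "se", "t_stat", "cohens_d", "n",
                     "paired_p", "paired_fdr", "cd8_rho", "rho_p", "rho_fdr",
                     "n_cor", "enriched", "infiltration_linked", "selected")]

  list(selected = stats$gene[stats$selected], stats = stats,
       not_evaluated = not_evaluated)
}

#' Gene/infiltration correlation network
#'
#' Computes Spearman correlations for all gene-gene and gene-cell-type pairs
#' and keeps edges with `rho` above the threshold (the paper-style
#' "moderate-to-large strength" rule, default 0.4).
#'
#' @param cohort An `expression_cohort` (tumor samples are used).
#' @param infiltration An `infiltration_table`.
#' @param genes Gene symbols forming the network core.
#' @param rho_threshold Edge inclusion threshold in `(0, 1]`; default 0.4.
#' @return Tibble edge list (`from`, `to`, `rho`, `type`) with a `nodes`
#'   attribute (genes plus retained cell types).
#' @export
correlation_network <- function(cohort, infiltration, genes,
                                rho_threshold = 0.4) {
  stopifnot(rho_threshold > 0, rho_threshold <= 1)
  meta <- cohort$sample_meta
  tumor <- if ("tissue" %in% names(meta)) {
    meta$sample_id[meta$tissue == "tumor"]
  } else meta$sample_id
  tumor <- intersect(tumor, colnames(infiltration$scores))
  idx <- match_genes(genes, rownames(cohort$values))
  expr <- cohort$values[idx, tumor, drop = FALSE]
  rownames(expr) <- genes
  scores <- infiltration$scores[, tumor, drop = FALSE]

  edges <- list()
  if (length(genes) > 1L) {
    for (i in seq_len(length(genes) - 1L)) {
      for (j in seq(i + 1L, length(genes))) {
        r <- spearman_cor(expr[i, ], expr[j, ])$rho
        if (r > rho_threshold) {
          edges[[length(edges) + 1L]] <-
            tibble(from = genes[i], to = genes[j], rho = r,
                   type = "gene-gene")
        }
      }
    }
  }
  for (g in genes) {
    for (ct in rownames(scores)) {
      r <- spearman_cor(expr[g, ], scores[ct, ])$rho
      if (r > rho_threshold) {
        edges[[length(edges) + 1L]] <-
          tibble(from = g, to = ct, rho = r, type = "gene-cell")
      }
    }
  }
  out <- if (length(edges) == 0L) {
    tibble(from = character(0L), to = character(0L), rho = numeric(0L),
           type = character(0L))
  } else {
    dplyr::bind_rows(edges)
  }
  attr(out, "nodes") <- union(genes,
                              unique(out$to[out$type == "gene-cell"]))
  out
}
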