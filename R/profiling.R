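# Cluster profiling: differential expression with a fold filter,
# single-sample gene-set scores, and categorical/rank contrasts.

#' Differential expression between two clusters
#'
#' Per-gene Welch (unequal-variance) two-sided t-test of the first group
#' versus the second on log2 expression, with BH-FDR across genes. A gene is
#' "regulated" when FDR < `fdr_threshold` and its linear fold change exceeds
#' `fold_threshold` (or falls below its reciprocal). The `mean_diff`/`se`
#' columns feed [estimate_reaction_regulation()] unchanged.
#'
#' @param cohort An `expression_cohort` (or genes x samples matrix).
#' @param assignments Named factor/character of cluster labels covering the
#'   samples to compare; exactly two levels are contrasted.
#' @param numerator,denominator Labels contrasted as numerator vs
#'   denominator (default `"high"` vs `"low"`).
#' @param fold_threshold Linear fold filter (default 1.25).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Tibble with one row per gene: `gene`, `mean_diff` (log2),
#'   `se`, `t_stat`, `df`, `p`, `fdr`, `cohens_d`, `n`, `regulated`,
#'   `direction`.
#' @export
differential_expression <- function(cohort, assignments,
                                    numerator = "high", denominator = "low",
                                    fold_threshold = 1.25,
                                    fdr_threshold = 0.05) {
  x <- if (inherits(cohort, "expression_cohort")) cohort$values else cohort
  stopifnot(is.matrix(x))
  assignments <- assignments[names(assignments) %in% colnames(x)]
  s1 <- names(assignments)[assignments == numerator]
  s2 <- names(assignments)[assignments == denominator]
  if (length(s1) < 3L || length(s2) < 3L) {
    stop("both clusters need at least 3 samples", call. = FALSE)
  }
  res <- welch_rows(x[, s1, drop = FALSE], x[, s2, drop = FALSE])
  res <- tibble(gene = rownames(x), res)
  res$fdr <- bh_fdr(res$p)
  lf <- log2(fold_threshold)
  res$regulated <- res$fdr < fdr_threshold & abs(res$mean_diff) > lf
  res$direction <- ifelse(!res$regulated, "none",
                          ifelse(res$mean_diff > 0, "up", "down"))
  res
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Rank-based running-sum enrichment of each gene set within each sample.
#' Genes are ranked by expression (midranks for ties, highest expression =
#' rank G); walking the genes in decreasing order, the score is the summed
#' difference between the weighted in-set cumulative distribution
#' (weights `rank^alpha`) and the unweighted out-of-set cumulative
#' distribution. Scores are invariant to monotone transforms of each
#' sample's expression. Optional normalization divides the whole score
#' matrix by its range.
#'
#' @param cohort An `expression_cohort` or genes x samples matrix.
#' @param gene_sets A `gene_set_collection` or named list of gene vectors.
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide all scores by `max - min` of the score matrix
#'   (default `TRUE`).
#' @return Signatures x samples matrix of enrichment scores with attributes
#'   `alpha` and `normalized`.
#' @export
ssgsea <- function(cohort, gene_sets, alpha = 0.25, normalize = TRUE) {
  x <- if (inherits(cohort, "expression_cohort")) cohort$values else cohort
  sets <- if (inherits(gene_sets, "gene_set_collection")) {
    gene_sets$sets
  } else gene_sets
  genes <- rownames(x)
  g_tot <- length(genes)
  set_idx <- lapply(names(sets), function(nm) {
    hit <- which(toupper(genes) %in% toupper(sets[[nm]]))
    if (length(hit) == 0L) {
      stop("gene set '", nm, "' shares no gene with the cohort",
           call. = FALSE)
    }
    if (length(hit) == g_tot) {
      stop("gene set '", nm, "' covers every gene; enrichment undefined",
           call. = FALSE)
    }
    hit
  })
  names(set_idx) <- names(sets)

  scores <- matrix(0, nrow = length(sets), ncol = ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (s in seq_len(ncol(x))) {
    e <- x[, s]
    r <- rank(e, ties.method = "average")
    ord <- order(e, decreasing = TRUE)      # stable: ties keep gene order
    rw <- r[ord]^alpha
    for (k in seq_along(set_idx)) {
      inset <- ord %in% set_idx[[k]]
      win <- rw * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (g_tot - length(set_idx[[k]]))
      scores[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}

#' Compare gene-set scores between clusters
#'
#' Welch two-sided t-test per signature with BH-FDR across signatures.
#'
#' @param scores Signatures x samples matrix (from [ssgsea()]) — also
#'   accepts an infiltration score matrix.
#' @param assignments Named cluster labels covering the samples.
#' @param numerator,denominator Labels to contrast (default high vs low).
#' @return Tibble with `signature`, Welch statistics, `fdr` and `direction`.
#' @export
compare_scores <- function(scores, assignments,
                           numerator = "high", denominator = "low") {
  stopifnot(is.matrix(scores))
  assignments <- assignments[names(assignments) %in% colnames(scores)]
  s1 <- names(assignments)[assignments == numerator]
  s2 <- names(assignments)[assignments == denominator]
  if (length(s1) < 3L || length(s2) < 3L) {
    stop("both clusters need at least 3 samples", call. = FALSE)
  }
  res <- welch_rows(scores[, s1, drop = FALSE], scores[, s2, drop = FALSE])
  res <- tibble(signature = rownames(scores), res)
  res$fdr <- bh_fdr(res$p)
  res$direction <- ifelse(res$fdr >= 0.05, "none",
                          ifelse(res$mean_diff > 0, "up", "down"))
  res
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The exact distribution is used when the smaller
#' group has at most 8 observations and there are no ties; otherwise the
#' normal approximation with the tie-corrected variance is applied (no
#' continuity correction). `U + U' = n1 * n2` always holds.
#'
#' @param x,y Numeric score vectors (both non-empty).
#' @return One-row tibble: `U`, `U_prime`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty group", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_prime <- n1 * n2 - u
  ties <- anyDuplicated(pooled) > 0L
  if (min(n1, n2) <= 8L && !ties) {
    p <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v == 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  tibble(U = u, U_prime = u_prime, p = p, method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with `(r - 1)(c - 1)` degrees of freedom, no
#' continuity correction. Used for stage / risk-group / therapy-response
#' contrasts between clusters.
#'
#' @param tab Counts matrix (all entries >= 0, no zero row or column sum).
#' @return One-row tibble: `chisq`, `df`, `p`.
#' @export
chisq_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chisq = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value))
}
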