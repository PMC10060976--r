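# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route than the code
# under test.

# GPR oracle: translate the rule into an R expression and let the R parser
# handle precedence. `%and%` (a user-defined operator, binding tighter than
# `+`) plays the complex rule, `+` the isoenzyme rule.
oracle_gpr_eval <- function(rule, activities) {
  expr <- gsub("\\b(and)\\b", "%and%", rule, ignore.case = TRUE)
  expr <- gsub("\\b(or)\\b", "+", expr, ignore.case = TRUE)
  env <- new.env()
  assign("%and%", function(a, b) pmin(a, b), envir = env)
  for (g in names(activities)) assign(g, activities[[g]], envir = env)
  eval(parse(text = expr), envir = env)
}

# Random GPR rule over a gene pool, nesting depth <= depth.
random_gpr_rule <- function(genes, depth = 3L) {
  build <- function(d) {
    if (d == 0L || runif(1) < 0.35) return(sample(genes, 1L))
    op <- sample(c(" and ", " or "), 1L)
    n_args <- sample(2:3, 1L)
    args <- vapply(seq_len(n_args), function(i) {
      a <- build(d - 1L)
      if (grepl(" ", a)) paste0("(", a, ")") else a
    }, character(1L))
    paste(args, collapse = op)
  }
  build(depth)
}

# ssGSEA oracle: literal running-sum with explicit loops.
oracle_ssgsea_sample <- function(expr, set_genes, alpha) {
  genes <- names(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(expr, decreasing = TRUE)
  g_tot <- length(genes)
  in_set <- genes[ord] %in% set_genes
  denom_in <- sum(r[ord][in_set]^alpha)
  denom_out <- g_tot - sum(in_set)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(g_tot)) {
    if (in_set[i]) {
      p_in <- p_in + r[ord][i]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / denom_out
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# BH oracle: literal step-up definition, adj_(i) = min_{j >= i} p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive k-medoids under cosine distance: global optimum by enumeration.
oracle_kmedoids <- function(x, k) {
  n <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- cosine_distance(x[, i], x[, j])
    }
  }
  best_cost <- Inf
  best_assign <- NULL
  for (med in utils::combn(n, k, simplify = FALSE)) {
    assign_i <- apply(d[, med, drop = FALSE], 1L, which.min)
    cost <- sum(d[cbind(seq_len(n), med[assign_i])])
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best_assign <- assign_i
    }
  }
  list(cost = best_cost, assignments = best_assign)
}

# All permutations of 1..n (n small).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (sub in combinat_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[sub])
    }
  }
  out
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) > 1 - 1e-9
}

# Small default-style design for fast unit tests.
small_design <- function(seed = 1L, ...) {
  simulation_design(n_samples = 60L, n_cohorts = 1L, seed = seed, ...)
}
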