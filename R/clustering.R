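# Chemokine cluster definition: PAM with cosine distance, k diagnostics,
# cross-validated stability, and cross-cohort k-NN label projection.

#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`, ranging from 0 (collinear) through 1 (orthogonal) to 2
#' (antipodal).
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Distance in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction", call. = FALSE)
  min(max(1 - sum(u * v) / (nu * nv), 0), 2)
}

# Pairwise cosine distances between the columns of x (observations).
cosine_dist_matrix <- function(x) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) {
    stop("zero-norm sample(s): ",
         paste(head(colnames(x)[nrm == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  xn <- sweep(x, 2L, nrm, "/")
  d <- 1 - crossprod(xn)
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Partition around medoids on a scaled panel matrix
#'
#' K-medoids clustering of the samples (columns) under cosine distance.
#' Small instances (at most 500 candidate medoid sets) are solved exactly by
#' enumeration; larger ones use BUILD + SWAP, which is locally optimal: no
#' single medoid swap lowers the total distance. `k = n` is the trivial
#' partition with every sample its own medoid. The fit is deterministic.
#'
#' @param x Scaled panel matrix, genes x samples (e.g. `zscore_genes()$scaled`).
#' @param k Number of clusters (`2 <= k <= n`).
#' @param seed Unused placeholder kept for interface stability; the fit is
#'   deterministic.
#' @return List with `assignments` (named integer cluster ids), `medoid_ids`,
#'   `cost` (total within-cluster distance) and `distance = "cosine"`.
#' @export
pam_fit <- function(x, k, seed = NULL) {
  n <- ncol(x)
  if (k < 1L || k > n) stop("`k` must lie in [1, n]", call. = FALSE)
  n_distinct <- sum(!duplicated(t(x)))
  if (n_distinct < k) {
    stop("fewer than k distinct samples (", n_distinct, " < ", k, ")",
         call. = FALSE)
  }
  ids <- colnames(x)
  if (k == n) {
    return(list(assignments = setNames(seq_len(n), ids), medoid_ids = ids,
                cost = 0, distance = "cosine"))
  }
  d <- cosine_dist_matrix(x)
  if (choose(n, k) <= 500) {
    # small instances: exact k-medoids by enumeration (globally optimal,
    # lowest-index medoid set wins cost ties)
    best <- NULL
    best_cost <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      nearest <- apply(d[, med, drop = FALSE], 1L, which.min)
      cost <- sum(d[cbind(seq_len(n), med[nearest])])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- list(med = med, nearest = nearest)
      }
    }
    assignments <- setNames(as.integer(best$nearest), ids)
    medoid_ids <- ids[best$med]
  } else {
    fit <- cluster::pam(as.dist(d), k = k, diss = TRUE)
    assignments <- setNames(as.integer(fit$clustering), ids)
    medoid_ids <- ids[fit$id.med]
  }
  cost <- sum(d[cbind(seq_len(n), match(medoid_ids[assignments], ids))])
  list(assignments = assignments, medoid_ids = medoid_ids, cost = cost,
       distance = "cosine")
}

#' Fit a chemokine cluster model on a training cohort
#'
#' Z-scores the gene panel within the cohort, runs PAM with cosine distance,
#' and names clusters by mean scaled panel expression: for `k = 2` the
#' cluster with the greater mean is `"high"`, the other `"low"` (for larger
#' k, clusters are `C1, C2, ...` in decreasing mean panel expression).
#' Naming therefore never depends on input order.
#'
#' @param cohort Training `expression_cohort` (tumor samples).
#' @param gene_panel Character vector of panel genes.
#' @param k Number of clusters (default 2).
#' @return Object of class `cluster_model`: panel, per-gene scaling
#'   parameters, medoid ids and vectors, named assignments, and the scaled
#'   training matrix used for projection.
#' @export
chemokine_clusters <- function(cohort, gene_panel, k = 2L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  sc <- zscore_genes(cohort, gene_panel)
  fit <- pam_fit(sc$scaled, k = k)
  panel_mean <- colMeans(sc$scaled)
  cl_mean <- tapply(panel_mean, fit$assignments, mean)
  ord <- order(cl_mean, decreasing = TRUE)      # 1st = highest panel expression
  labels <- if (k == 2L) c("high", "low") else paste0("C", seq_len(k))
  relabel <- setNames(labels, names(cl_mean)[ord])
  assignments <- factor(relabel[as.character(fit$assignments)],
                        levels = labels)
  names(assignments) <- names(fit$assignments)
  structure(
    list(
      gene_panel = gene_panel,
      center = sc$center,
      scale = sc$scale,
      k = k,
      distance = "cosine",
      medoid_ids = fit$medoid_ids,
      medoids = sc$scaled[, fit$medoid_ids, drop = FALSE],
      assignments = assignments,
      train_scaled = sc$scaled,
      cohort_id = cohort$cohort_id
    ),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$k, " clusters (", x$distance, " PAM) on ",
      length(x$gene_panel), "-gene panel, trained on ", x$cohort_id,
      "\n", sep = "")
  print(table(x$assignments))
  invisible(x)
}

#' Cluster-number diagnostics
#'
#' Fits PAM for each candidate k and reports the within-cluster sum of
#' squared cosine distances to the medoid (WSS, for elbow inspection) and
#' the mean silhouette width (singletons scored 0 by convention). The
#' recommended k is the silhouette peak; the WSS bend is reported, not
#' auto-decided.
#'
#' @param x Scaled panel matrix, genes x samples.
#' @param ks Integer vector of candidate cluster numbers within `[2, n-1]`.
#' @return List with `metrics` (tibble: `k`, `wss`, `avg_silhouette`) and
#'   `recommended_k`.
#' @export
choose_k <- function(x, ks = 2:6) {
  n <- ncol(x)
  stopifnot(all(ks >= 2L), all(ks <= n - 1L))
  d <- cosine_dist_matrix(x)
  rows <- lapply(ks, function(k) {
    fit <- pam_fit(x, k = k)
    med_idx <- match(fit$medoid_ids[fit$assignments], colnames(x))
    wss <- sum(d[cbind(seq_len(n), med_idx)]^2)
    sil <- cluster::silhouette(unname(fit$assignments), dmatrix = d)
    tibble(k = k, wss = wss, avg_silhouette = mean(sil[, "sil_width"]))
  })
  metrics <- dplyr::bind_rows(rows)
  list(metrics = metrics,
       recommended_k = metrics$k[which.max(metrics$avg_silhouette)])
}

#' Fraction of variance explained by a clustering
#'
#' Standard between/total sum-of-squares decomposition, `1 - SSW/SST`,
#' computed with Euclidean geometry on the scaled matrix (the decomposition
#' exists only for squared Euclidean distances, whatever metric was used for
#' clustering). Used to compare the training clustering with its projection
#' onto test cohorts.
#'
#' @param x Scaled panel matrix, genes x samples.
#' @param assignments Cluster labels, one per column of `x`.
#' @return Fraction in `[0, 1]`.
#' @export
explained_variance <- function(x, assignments) {
  stopifnot(ncol(x) == length(assignments))
  grand <- rowMeans(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) stop("all samples identical; variance undefined",
                     call. = FALSE)
  ssw <- 0
  for (cl in unique(assignments)) {
    xi <- x[, assignments == cl, drop = FALSE]
    ssw <- ssw + sum((xi - rowMeans(xi))^2)
  }
  1 - ssw / sst
}

#' Cross-validated clustering stability
#'
#' Standard reproducibility check: for each fold, PAM is refit on the
#' remaining samples, held-out samples are assigned to the nearest medoid,
#' and the predictions are compared with the full-data labels by the
#' adjusted Rand index. Returns the mean ARI across folds.
#'
#' @param x Scaled panel matrix, genes x samples.
#' @param k Number of clusters.
#' @param folds Number of folds (default 10; must be >= 2).
#' @param seed Optional seed for the fold split.
#' @return List with `mean_ari` and per-fold `ari`.
#' @export
crossvalidate <- function(x, k = 2L, folds = 10L, seed = NULL) {
  n <- ncol(x)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  full <- pam_fit(x, k = k)$assignments
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (any(tabulate(fold_id, folds) < 1L) || min(table(fold_id)) < 1L) {
    stop("empty fold", call. = FALSE)
  }
  if (min(n - table(fold_id)) < k) {
    stop("a training fold has fewer than k samples", call. = FALSE)
  }
  aris <- vapply(seq_len(folds), function(f) {
    test <- which(fold_id == f)
    if (length(test) < 1L) stop("fold with too few samples", call. = FALSE)
    fit <- pam_fit(x[, -test, drop = FALSE], k = k)
    med <- x[, fit$medoid_ids, drop = FALSE]
    pred <- vapply(test, function(i) {
      dists <- vapply(seq_len(k), function(m) cosine_distance(x[, i], med[, m]),
                      numeric(1L))
      which.min(dists)
    }, integer(1L))
    mclust::adjustedRandIndex(pred, unname(full[test]))
  }, numeric(1L))
  list(mean_ari = mean(aris), ari = aris)
}

#' Project cluster labels onto a test cohort by weighted k-NN
#'
#' Assigns each test sample the label winning the inverse-distance-weighted
#' vote of its `k_neighbors` nearest training samples under cosine distance
#' in the scaled panel space. A test sample at zero distance from a training
#' sample copies that sample's label (lowest training index if several).
#' Weight ties between clusters are broken toward the cluster of the tied
#' neighbor with the smallest training index — a deterministic rule recorded
#' here rather than left to chance.
#'
#' By default the test cohort is z-scored with its own per-gene parameters
#' (cross-platform transfer); `scaling = "train"` applies the training
#' cohort's parameters instead.
#'
#' @param model A `cluster_model`.
#' @param cohort Test `expression_cohort` containing all panel genes.
#' @param k_neighbors Number of neighbors (default 15).
#' @param scaling `"test"` (default) or `"train"`.
#' @return Named factor of projected labels for the test samples.
#' @export
knn_project <- function(model, cohort, k_neighbors = 15L,
                        scaling = c("test", "train")) {
  stopifnot(inherits(model, "cluster_model"))
  scaling <- match.arg(scaling)
  n_train <- ncol(model$train_scaled)
  if (k_neighbors > n_train) {
    stop("`k_neighbors` exceeds the number of training samples",
         call. = FALSE)
  }
  x <- if (inherits(cohort, "expression_cohort")) cohort$values else cohort
  idx <- tryCatch(match_genes(model$gene_panel, rownames(x), "panel gene"),
                  error = function(e) stop(conditionMessage(e), call. = FALSE))
  sub <- x[idx, , drop = FALSE]
  rownames(sub) <- model$gene_panel
  scaled <- if (scaling == "test") {
    zscore_genes(sub, model$gene_panel)$scaled
  } else {
    (sub - model$center) / model$scale
  }

  tr <- model$train_scaled
  tr_n <- sweep(tr, 2L, sqrt(colSums(tr^2)), "/")
  te_n <- sweep(scaled, 2L, sqrt(colSums(scaled^2)), "/")
  d <- 1 - crossprod(te_n, tr_n)           # test x train
  d[d < 0] <- 0

  labels <- model$assignments
  lvls <- levels(labels)
  out <- character(ncol(scaled))
  for (i in seq_len(ncol(scaled))) {
    di <- d[i, ]
    zero <- which(di <= .Machine$double.eps * 8)
    if (length(zero) > 0L) {
      out[i] <- as.character(labels[zero[1L]])
      next
    }
    nn <- order(di)[seq_len(k_neighbors)]   # stable order: ties -> lower index
    w <- tapply(1 / di[nn], as.character(labels[nn]), sum)
    best <- names(w)[w >= max(w) - .Machine$double.eps * max(w) * 8]
    if (length(best) == 1L) {
      out[i] <- best
    } else {
      first_tied <- nn[which(as.character(labels[nn]) %in% best)[1L]]
      out[i] <- as.character(labels[first_tied])
    }
  }
  setNames(factor(out, levels = lvls), colnames(scaled))
}
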