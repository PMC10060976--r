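# Expression cohort container and core transforms.

#' Construct an expression cohort
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' per-sample metadata. This is the central data container of the package:
#' all downstream stages (screening, clustering, profiling, survival) operate
#' on it.
#'
#' @param cohort_id Single string identifying the cohort.
#' @param values Numeric matrix of log2 expression, genes x samples, with
#'   unique row names (gene symbols) and column names (sample ids).
#' @param sample_meta Data frame with one row per sample. Must contain a
#'   `sample_id` column covering every column of `values`. Recognized columns:
#'   `tissue` ("tumor"/"normal"), `donor_id`, `os_time` (days), `os_event`
#'   (0/1), `stage`, `grade`, `response`. Missing clinical fields stay `NA`;
#'   nothing is imputed.
#'
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(cohort_id, values, sample_meta) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  }
  genes <- trimws(rownames(values))
  rownames(values) <- genes
  folded <- toupper(genes)
  if (anyDuplicated(folded)) {
    dup <- unique(genes[duplicated(folded) | duplicated(folded, fromLast = TRUE)])
    stop("gene symbols collide after case-folding: ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  sample_meta <- as_tibble(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) {
    stop("`sample_meta` needs a `sample_id` column", call. = FALSE)
  }
  missing <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from `sample_meta`: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if ("os_event" %in% names(sample_meta)) {
    ev <- sample_meta$os_event
    bad <- !is.na(ev) & !(ev %in% c(0, 1))
    if (any(bad)) stop("`os_event` must be 0 or 1", call. = FALSE)
  }
  structure(
    list(cohort_id = cohort_id, values = values, sample_meta = sample_meta),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", x$cohort_id, "\n", sep = "")
  cat("  ", nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  if ("tissue" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$tissue)
    cat("  tissue: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Subset a cohort to a set of samples
#'
#' @param cohort An `expression_cohort`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return The restricted `expression_cohort`.
#' @export
subset_cohort <- function(cohort, samples) {
  stopifnot(inherits(cohort, "expression_cohort"))
  missing <- setdiff(samples, colnames(cohort$values))
  if (length(missing) > 0L) {
    stop("unknown samples: ", paste(head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  expression_cohort(
    cohort$cohort_id,
    cohort$values[, samples, drop = FALSE],
    cohort$sample_meta[match(samples, cohort$sample_meta$sample_id), ]
  )
}

#' Keep only tumor samples of a cohort
#'
#' @param cohort An `expression_cohort` whose metadata carries a `tissue`
#'   column.
#' @return The tumor-only `expression_cohort`.
#' @export
tumor_only <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  ids <- cohort$sample_meta$sample_id[cohort$sample_meta$tissue == "tumor"]
  subset_cohort(cohort, ids)
}

# Case-insensitive gene lookup; returns row indices into `genes`.
match_genes <- function(wanted, genes, context = "gene") {
  idx <- match(toupper(trimws(wanted)), toupper(trimws(genes)))
  if (anyNA(idx)) {
    stop("missing ", context, "(s): ",
         paste(head(wanted[is.na(idx)], 10L), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Log2 transform of non-negative expression values
#'
#' Applies `log2(x + 1)` entry-wise; the standard variance-stabilizing
#' transform for RNA-seq counts and linear-scale intensities.
#'
#' @param x Numeric matrix or vector with finite, non-negative entries.
#' @return Object of the same shape with transformed values.
#' @export
log2_transform <- function(x) {
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    loc <- if (is.matrix(x)) {
      rc <- arrayInd(i, dim(x))
      paste0("row ", rc[1L], ", column ", rc[2L])
    } else {
      paste0("position ", i)
    }
    stop("negative or non-finite value at ", loc, call. = FALSE)
  }
  log2(x + 1)
}

#' Collapse probe-level rows to genes by geometric mean
#'
#' Microarray platforms measure many genes with several probes; rows mapping
#' to the same gene are merged on the linear scale by their geometric mean
#' (so one zero probe among several yields 0 for the gene, by construction).
#' Apply before [log2_transform()].
#'
#' @param probe_matrix Non-negative numeric matrix, probes x samples, with
#'   probe row names.
#' @param probe_to_gene Named character vector mapping every probe id to a
#'   gene symbol.
#' @return Gene x sample matrix; single-probe genes pass through unchanged.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(is.matrix(probe_matrix))
  if (any(!is.finite(probe_matrix) | probe_matrix < 0)) {
    stop("probe values must be finite and >= 0 (collapse runs on the linear scale)",
         call. = FALSE)
  }
  probes <- rownames(probe_matrix)
  unmapped <- setdiff(probes, names(probe_to_gene))
  if (length(unmapped) > 0L) {
    stop("unmapped probe(s): ", paste(head(unmapped, 5L), collapse = ", "),
         call. = FALSE)
  }
  grp <- unname(probe_to_gene[probes])
  lg <- log(probe_matrix)            # log(0) = -Inf -> geometric mean 0
  sums <- rowsum(lg, group = grp)
  counts <- as.vector(table(grp)[rownames(sums)])
  out <- exp(sums / counts)
  folded <- toupper(trimws(rownames(out)))
  if (anyDuplicated(folded)) {
    stop("gene symbols collide after case-folding in the probe map",
         call. = FALSE)
  }
  out
}

#' Per-gene z-scoring of a gene panel
#'
#' Standardizes each panel gene to mean 0, SD 1 within the cohort and keeps
#' the scaling parameters so the same transform (or a test cohort's own) can
#' be reused when projecting cluster labels across cohorts.
#'
#' @param cohort An `expression_cohort` (or bare genes x samples matrix).
#' @param gene_panel Character vector of genes to scale (matched
#'   case-insensitively).
#' @return List with `scaled` (panel x samples matrix, rows in `gene_panel`
#'   order), `center` and `scale` (named per-gene mean and SD).
#' @export
zscore_genes <- function(cohort, gene_panel) {
  x <- if (inherits(cohort, "expression_cohort")) cohort$values else cohort
  stopifnot(is.matrix(x))
  idx <- match_genes(gene_panel, rownames(x), "panel gene")
  sub <- x[idx, , drop = FALSE]
  rownames(sub) <- gene_panel
  ctr <- rowMeans(sub)
  centered <- sub - ctr
  sds <- sqrt(rowSums(centered^2) / (ncol(sub) - 1L))
  if (any(sds <= 0 | !is.finite(sds))) {
    stop("constant gene(s), cannot z-score: ",
         paste(gene_panel[sds <= 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  }
  list(scaled = centered / sds, center = ctr, scale = sds)
}
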