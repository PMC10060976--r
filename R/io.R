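# Readers and writers for the tabular/JSON formats used by the pipeline.

#' Read a tab-separated expression matrix
#'
#' Canonical layout: first column gene ids, header row sample ids. Files with
#' samples in rows are accepted via `samples_in_rows = TRUE`.
#'
#' @param path Path to a tab-separated text file.
#' @param samples_in_rows Logical; set `TRUE` for transposed files.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
read_expression_matrix <- function(path, samples_in_rows = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, " at line ", bad, call. = FALSE)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr)) {
    stop("duplicated header id(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path,
                             call. = FALSE)
  rownames(mat) <- ids
  if (samples_in_rows) t(mat) else mat
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so a write/read cycle
#' reproduces finite doubles bit-identically.
#'
#' @param mat Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Header of the gene id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(
    paste(c(id_column, colnames(mat)), collapse = "\t"),
    paste(rownames(mat), body, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (set name -> gene symbols).
#' @param source Free-text provenance label.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "unknown") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  ok <- vapply(sets, function(g) is.character(g) && all(nzchar(g)), logical(1L))
  if (!all(ok)) stop("gene symbols must be non-empty strings", call. = FALSE)
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets (source: ",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, source = path)
}

#' Construct an infiltration score table
#'
#' Carries externally supplied (or synthetic) immune-cell infiltration
#' estimates; the deconvolution itself is out of scope for this package.
#'
#' @param scores Non-negative numeric matrix, cell types x samples, with
#'   dimnames.
#' @return Object of class `infiltration_table`.
#' @export
infiltration_table <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (any(!is.finite(scores))) stop("infiltration scores must be finite",
                                    call. = FALSE)
  if (any(scores < 0)) stop("infiltration scores must be >= 0", call. = FALSE)
  structure(list(scores = scores), class = "infiltration_table")
}

#' @export
print.infiltration_table <- function(x, ...) {
  cat("<infiltration_table> ", nrow(x$scores), " cell types x ",
      ncol(x$scores), " samples\n", sep = "")
  invisible(x)
}

#' Construct a metabolic model specification
#'
#' Reactions with their gene-protein-reaction (GPR) rules and subsystem
#' labels, as used for regulation inference. GPR strings are parsed at
#' construction time; reactions with an empty rule are retained but flagged
#' and later excluded from inference.
#'
#' @param reactions Data frame with columns `reaction_id`, `gpr`,
#'   `subsystem`.
#' @param genes Character vector of model gene identifiers.
#' @return Object of class `metabolic_model` whose `reactions` tibble gains a
#'   `tree` list-column (parsed GPR or `NULL`) and `has_gpr` flag.
#' @export
metabolic_model <- function(reactions, genes) {
  reactions <- as_tibble(reactions)
  stopifnot(all(c("reaction_id", "gpr", "subsystem") %in% names(reactions)))
  if (anyDuplicated(reactions$reaction_id)) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  genes <- unique(as.character(genes))
  trees <- vector("list", nrow(reactions))
  for (i in seq_len(nrow(reactions))) {
    rule <- reactions$gpr[i]
    if (is.na(rule) || !nzchar(trimws(rule))) next
    trees[[i]] <- tryCatch(
      parse_gpr(rule),
      error = function(e) {
        stop("reaction ", reactions$reaction_id[i], ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    used <- gpr_genes(trees[[i]])
    unknown <- setdiff(used, genes)
    if (length(unknown) > 0L) {
      stop("reaction ", reactions$reaction_id[i],
           " references unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  reactions$tree <- trees
  reactions$has_gpr <- !vapply(trees, is.null, logical(1L))
  structure(list(reactions = reactions, genes = genes),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions (",
      sum(x$reactions$has_gpr), " with GPR), ", length(x$genes),
      " genes, ", length(unique(x$reactions$subsystem)), " subsystems\n",
      sep = "")
  invisible(x)
}

#' Read a BiGG-dialect metabolic model from JSON
#'
#' Understands the subset of the BiGG JSON schema needed for GPR-based
#' inference: `reactions[].id`, `reactions[].gene_reaction_rule`,
#' `reactions[].subsystem` and `genes[].id`. A full genome-scale model in
#' this dialect loads the same way.
#'
#' @param path Path to the JSON file.
#' @return A `metabolic_model`.
#' @export
read_metabolic_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$reactions) || is.null(obj$genes)) {
    stop("model JSON needs `reactions` and `genes` arrays", call. = FALSE)
  }
  reactions <- tibble(
    reaction_id = vapply(obj$reactions, function(r) as.character(r$id),
                         character(1L)),
    gpr = vapply(obj$reactions, function(r) {
      g <- r$gene_reaction_rule
      if (is.null(g)) "" else as.character(g)
    }, character(1L)),
    subsystem = vapply(obj$reactions, function(r) {
      s <- r$subsystem
      if (is.null(s)) "" else as.character(s)
    }, character(1L))
  )
  genes <- vapply(obj$genes, function(g) as.character(g$id), character(1L))
  metabolic_model(reactions, genes)
}

#' Write a metabolic model as BiGG-dialect JSON
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- list(
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      list(id = model$reactions$reaction_id[i],
           gene_reaction_rule = model$reactions$gpr[i],
           subsystem = model$reactions$subsystem[i])
    }),
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
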