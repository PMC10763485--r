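# Readers and writers for the pipeline's plain-text formats: dose-response
# CSV, expression TSV, GMT gene-set collections, and the compendium gene
# list. Dialects are fixed: UTF-8, '.' decimal, header required.

#' Read per-cell-line dose-response observations from CSV
#'
#' Expects columns `cell_line,tissue,dose_gy,survival` (one row per
#' observation; replicate doses allowed). Rows are grouped by cell line;
#' survival values are sanitized by clipping to `[1e-6, cap]` with a
#' warning. Malformed rows raise line-numbered errors.
#'
#' @param path CSV file path.
#' @param cap survival clip cap (default 1.5).
#' @return List of [dose_response()] objects, one per cell line.
#' @export
read_dose_response <- function(path, cap = 1.5) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cell_line", "tissue", "dose_gy", "survival")
  if (!all(need %in% names(raw)))
    .stop_invalid("missing required column(s): ",
                  paste(setdiff(need, names(raw)), collapse = ", "))
  for (col in c("dose_gy", "survival")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0)
      .stop_invalid(sprintf("non-numeric %s on line %d: '%s'",
                            col, bad[1] + 1L, raw[[col]][bad[1]]))
    raw[[col]] <- v
  }
  groups <- split(raw, raw$cell_line)
  lapply(groups, function(g) {
    g <- g[order(g$dose_gy), , drop = FALSE]
    dose_response(g$cell_line[1], g$dose_gy, g$survival,
                  tissue = g$tissue[1], cap = cap)
  })
}

#' Write cohort LQ fits to TSV
#'
#' Columns: `cell_line,alpha,beta,auc,sf2,dmax,rss,n_points,group`.
#'
#' @param fits a `cohort_fits` data frame from [fit_cohort()].
#' @param path output TSV path.
#' @export
write_fits <- function(fits, path) {
  cols <- c("cell_line", "alpha", "beta", "auc", "sf2", "dmax", "rss",
            "n_points", "group")
  write.table(as.data.frame(fits)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column is the gene id, remaining columns are samples. Gene and
#' sample ids must be unique; missing values are rejected unless
#' `na_policy = "drop-gene"`, in which case genes with any missing value are
#' removed with a message.
#'
#' @param path TSV file path.
#' @param na_policy `"error"` (default) or `"drop-gene"`.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, na_policy = c("error", "drop-gene")) {
  na_policy <- match.arg(na_policy)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene <- as.character(raw[[1]])
  dup <- unique(gene[duplicated(gene)])
  if (length(dup) > 0)
    .stop_invalid("duplicated gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) .stop_invalid("non-numeric expression values in ", path)
  rownames(m) <- gene
  if (anyDuplicated(colnames(m)))
    .stop_invalid("duplicated sample ids in ", path)
  if (anyNA(m)) {
    if (na_policy == "error")
      .stop_invalid("missing values in expression matrix (use na_policy = 'drop-gene')")
    drop <- rowSums(is.na(m)) > 0
    message(sprintf("dropped %d gene(s) with missing values", sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: tab-separated `name<TAB>description<TAB>member1<TAB>...`.
#' Duplicate member ids within a set are deduplicated with a warning;
#' duplicate set names or lines with fewer than 3 fields are errors.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with attribute `source` = path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .stop_invalid(sprintf("GMT line %d has fewer than 3 fields", i))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate member ids deduplicated", f[1]))
      members <- unique(members)
    }
    if (f[1] %in% names(sets))
      .stop_invalid("duplicate set name: ", f[1])
    sets[[f[1]]] <- members
  }
  attr(sets, "source") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection named list of character vectors.
#' @param path output path.
#' @param description description field (recycled; default "na").
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], description, collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a compendium gene list
#'
#' Plain text, one gene id per line; blank lines ignored; duplicates
#' deduplicated.
#'
#' @param path file path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write an enrichment result to TSV
#'
#' Columns: `pathway,es,p_nominal,fdr,direction,set_size_used,leading_edge`
#' with the leading edge semicolon-joined.
#'
#' @param res `enrichment_result` from [enrich_collection()].
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  df <- as.data.frame(res[, c("pathway", "es", "p_nominal", "fdr",
                              "direction", "set_size_used")])
  df$leading_edge <- vapply(res$leading_edge, paste, character(1),
                            collapse = ";")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a signature model to JSON
#'
#' @param model a `signature_model`.
#' @param path output path.
#' @param provenance optional named list recorded verbatim.
#' @export
write_model <- function(model, path, provenance = list()) {
  jsonlite::write_json(
    list(features = model$features,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         center = as.list(model$center), scale = as.list(model$scale),
         k = model$k, cohort_id = model$cohort_id,
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model from JSON
#'
#' @param path path written by [write_model()].
#' @return A `signature_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(features = j$features,
         coefficients = setNames(unlist(j$coefficients), names(j$coefficients)),
         intercept = j$intercept,
         center = setNames(unlist(j$center), names(j$center)),
         scale = setNames(unlist(j$scale), names(j$scale)),
         k = j$k, cohort_id = j$cohort_id),
    class = "signature_model"
  )
}

#' Write a synthetic cohort to disk
#'
#' Emits the same CSV/TSV/GMT dialects the pipeline reads, plus a `truth/`
#' subdirectory with the ground-truth tables.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p_dr <- file.path(dir, paste0(cohort$role, "_dose_response.csv"))
  write.csv(cohort$dose_table, p_dr, row.names = FALSE, quote = FALSE)
  p_ex <- file.path(dir, paste0(cohort$role, "_expression.tsv"))
  write_expression(cohort$expression, p_ex)
  tt <- truth_table(cohort)
  p_tl <- file.path(dir, "truth", paste0(cohort$role, "_cell_lines.tsv"))
  write.table(tt$cell_lines, p_tl, sep = "\t", quote = FALSE, row.names = FALSE)
  p_tg <- file.path(dir, "truth", paste0(cohort$role, "_genes.tsv"))
  write.table(tt$genes, p_tg, sep = "\t", quote = FALSE, row.names = FALSE)
  c(dose_response = p_dr, expression = p_ex, truth_cell_lines = p_tl,
    truth_genes = p_tg)
}
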