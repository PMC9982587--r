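# Plain-text formats: TSV tables, GMT gene-set collections, YAML configs,
# JSON sidecars. Everything is header-ed, diff-able and round-trips.

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_ <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a region x gene expression matrix as TSV
#'
#' Header row of gene ids, first column (`region`) of region ids.
#'
#' @param X regions x genes matrix with dimnames.
#' @param path file path.
#' @return `write_expression_tsv` the path, invisibly; `read_expression_tsv`
#'   the numeric matrix.
#' @export
write_expression_tsv <- function(X, path) {
  df <- data.frame(region = rownames(X), X, check.names = FALSE)
  write_tsv_(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_(path)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$region
  X
}

#' Write / read a subject x region measure table as TSV
#'
#' @param table subject table (see [gen_subjects()]).
#' @param path file path.
#' @export
write_subject_tsv <- function(table, path) write_tsv_(table, path)

#' @rdname write_subject_tsv
#' @export
read_subject_tsv <- function(path) read_tsv_(path)

#' Write / read a gene-level DGE table as TSV
#'
#' Columns gene, disorder, beta.
#'
#' @param dge DGE table (see [gen_dge()]).
#' @param path file path.
#' @export
write_dge_tsv <- function(dge, path) write_tsv_(dge, path)

#' @rdname write_dge_tsv
#' @export
read_dge_tsv <- function(path) read_tsv_(path)

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path file path.
#' @param sets named list of gene id vectors.
#' @param descriptions optional character vector (recycled) for the second
#'   GMT column.
#' @return `read_gmt` a named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) character(0) else f[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (is.null(names(sets))) stop_("gene sets must be named")
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write a plain gene list (one id per line)
#'
#' @param genes character vector of gene ids.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write a pipeline configuration as a flat YAML file
#'
#' The configuration round-trips losslessly: `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config a [pipeline_config()] list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
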