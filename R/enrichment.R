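# Over-representation analysis of selected gene sets against gene-set
# collections (cell classes, up/down DGE sets, pathway collections).

#' Fisher's exact enrichment of one query set in one annotation set
#'
#' One-sided (over-representation) hypergeometric p on the 2x2 table with
#' cells a = |query n annotation|, b = |query \ annotation|,
#' c = |annotation \ query|, d = the rest of the background. The odds ratio
#' is `ad / bc`; when any cell is zero a Haldane 0.5 continuity correction
#' is applied to the odds ratio only (flagged in the output), the p value
#' is unaffected.
#'
#' @param query,annotation character vectors of gene ids, both subsets of
#'   `background`.
#' @param background character vector: the gene universe (normally all
#'   genes entering the correlate screen).
#' @param query_name,annotation_name labels for the output row.
#' @return one-row `data.frame`: query, annotation, overlap, query_size,
#'   annotation_size, background_size, odds_ratio, or_continuity, p.
#' @export
fisher_enrich <- function(query, annotation, background,
                          query_name = "query",
                          annotation_name = "annotation") {
  query <- unique(query); annotation <- unique(annotation)
  background <- unique(background)
  off_q <- setdiff(query, background)
  if (length(off_q) > 0)
    stop_("query genes outside the background: ",
          paste(utils::head(off_q, 5), collapse = ", "),
          if (length(off_q) > 5) sprintf(" (+%d more)", length(off_q) - 5))
  off_a <- setdiff(annotation, background)
  if (length(off_a) > 0)
    stop_("annotation genes outside the background: ",
          paste(utils::head(off_a, 5), collapse = ", "),
          if (length(off_a) > 5) sprintf(" (+%d more)", length(off_a) - 5))
  n_bg <- length(background)
  a <- length(intersect(query, annotation))
  b <- length(query) - a
  c_ <- length(annotation) - a
  d <- n_bg - a - b - c_
  # P(X >= a), X ~ Hypergeom(drawing |query| from |annotation| successes)
  p <- stats::phyper(a - 1, length(annotation), n_bg - length(annotation),
                     length(query), lower.tail = FALSE)
  continuity <- any(c(a, b, c_, d) == 0)
  cells <- c(a, b, c_, d) + if (continuity) 0.5 else 0
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  data.frame(query = query_name, annotation = annotation_name,
             overlap = a, query_size = length(query),
             annotation_size = length(annotation), background_size = n_bg,
             odds_ratio = or, or_continuity = continuity, p = min(p, 1),
             stringsAsFactors = FALSE)
}

#' Enrichment of several query sets against a gene-set collection
#'
#' Runs [fisher_enrich()] for every query x annotation pair and applies
#' Benjamini-Hochberg correction within each query across the collection's
#' sets. Empty annotation sets are skipped with a warning. Output rows are
#' ordered by query then annotation (the collection's order), so results
#' are deterministic.
#'
#' @param queries named list of gene id vectors (e.g. the four selected
#'   sets: funcPC1+, funcPC1-, GMV+, GMV-).
#' @param collection named list of annotation gene sets (e.g. from
#'   [read_gmt()]).
#' @param background the gene universe.
#' @return `data.frame` of [fisher_enrich()] rows plus `q` and
#'   `significant` (q <= alpha).
#' @param alpha FDR level for the significance flag, default 0.05.
#' @export
enrich_collection <- function(queries, collection, background, alpha = 0.05) {
  if (length(collection) == 0) stop_("empty gene-set collection")
  if (is.null(names(queries)) || is.null(names(collection)))
    stop_("queries and collection must be named lists")
  empty <- names(collection)[lengths(collection) == 0]
  if (length(empty) > 0) {
    warning("empty annotation sets skipped: ", paste(empty, collapse = ", "),
            call. = FALSE)
    collection <- collection[lengths(collection) > 0]
  }
  rows <- lapply(names(queries), function(qn) {
    per_q <- do.call(rbind, lapply(names(collection), function(an)
      fisher_enrich(queries[[qn]], collection[[an]], background, qn, an)))
    adj <- fdr_bh(per_q$p, alpha)
    per_q$q <- adj$q
    per_q$significant <- adj$significant
    per_q
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
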