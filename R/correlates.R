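# Mass-univariate spatial association of gene expression with a target map.

#' Spearman rank correlation with a two-sided p value
#'
#' Rank correlation with average ranks for ties. The two-sided p comes from
#' the t approximation `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df; for
#' tiny samples (`n < 10`, no ties) the exact permutation-null p is used
#' instead, where the approximation is unreliable. `|r| = 1` returns p = 0
#' by convention.
#'
#' @param x,y numeric vectors of equal length, at least 4.
#' @return list with `r_s` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_("x and y must have equal length")
  if (n < 4) stop_("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("constant vector: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (abs(r) >= 1 - 1e-15) return(list(r_s = sign(r), p = 0))
  if (n < 10 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  }
  list(r_s = r, p = min(p, 1))
}

# vectorized spearman of many columns against one target (t approximation)
spearman_many <- function(X, target) {
  n <- nrow(X)
  rt <- zscale(rank(target, ties.method = "average"))
  RX <- col_ranks(X)
  RX <- scale(RX)
  r <- as.numeric(crossprod(RX, rt)) / (n - 1)
  r <- pmin(1, pmax(-1, r))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  list(r_s = r, p = p)
}

#' Spatial transcriptional correlates of a target map
#'
#' Correlates every gene's regional expression profile with a per-region
#' target map (Spearman), gene order preserved. Regions must match by name
#' and order; mismatches are an error, never silently reordered.
#'
#' @param X regions x genes expression matrix with dimnames.
#' @param target named per-region numeric vector (e.g. funcPC1 scores or the
#'   GMV d map).
#' @param target_name label stored in the table.
#' @return `data.frame` (one row per gene): gene, r_s, p, target; attribute
#'   `n_regions`.
#' @export
gene_correlates <- function(X, target, target_name = "target") {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || is.null(names(target)))
    stop_("expression matrix and target map must carry region names")
  if (!identical(rownames(X), names(target)))
    stop_("region sets differ or are ordered differently between the ",
          "expression matrix and the target map")
  if (nrow(X) < 4) stop_("need at least 4 regions")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop_("constant expression profile for gene(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  res <- if (nrow(X) < 10) {
    per_gene <- apply(X, 2L, spearman, y = target)
    list(r_s = vapply(per_gene, `[[`, numeric(1), "r_s"),
         p = vapply(per_gene, `[[`, numeric(1), "p"))
  } else {
    spearman_many(X, target)
  }
  structure(data.frame(gene = colnames(X), r_s = res$r_s, p = res$p,
                       target = target_name, stringsAsFactors = FALSE),
            n_regions = nrow(X))
}

#' Select significantly correlated genes with Bonferroni control
#'
#' Thresholds raw p values at `alpha / G` (G = number of genes in the
#' table) and splits the survivors by the sign of `r_s` into a positive and
#' a negative set; the sets are disjoint by construction. Each target map is
#' its own Bonferroni family.
#'
#' @param table a [gene_correlates()] table.
#' @param alpha family-wise error level, default 0.05.
#' @param method only `"bonferroni"` is implemented.
#' @return list with `positive`, `negative` (gene id vectors), `threshold`
#'   (= alpha / G), `n_genes`, and `table` (the input with a `class` column:
#'   positive-significant / negative-significant / non-significant).
#' @export
select_significant <- function(table, alpha = 0.05, method = "bonferroni") {
  method <- match.arg(method, "bonferroni")
  check_number(alpha, "alpha", lower = 1e-300, upper = 1)
  if (!all(c("gene", "r_s", "p") %in% names(table)))
    stop_("expected a gene-correlate table with gene, r_s, p")
  g <- nrow(table)
  if (g < 1) stop_("empty correlate table")
  thr <- alpha / g
  sig <- table$p < thr
  cls <- rep("non-significant", g)
  cls[sig & table$r_s > 0] <- "positive-significant"
  cls[sig & table$r_s < 0] <- "negative-significant"
  table$class <- cls
  list(positive = table$gene[cls == "positive-significant"],
       negative = table$gene[cls == "negative-significant"],
       threshold = thr, n_genes = g, table = table)
}
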