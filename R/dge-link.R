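# Link transcriptional correlates to postmortem differential-expression
# betas: direct gene-level correlation, the bin-based estimator, and the
# top-K up/down-regulated gene sets.

#' Intersect the gene universes of a correlate table and a DGE table
#'
#' @param correlates a [gene_correlates()] table (or anything with a `gene`
#'   column).
#' @param dge a DGE `data.frame` with a `gene` column (see [gen_dge()]).
#' @return sorted character vector of shared gene ids; attributes
#'   `n_correlates`, `n_dge` record the input universe sizes.
#' @export
intersect_genes <- function(correlates, dge) {
  for (x in list(correlates, dge))
    if (!"gene" %in% names(x)) stop_("both tables must have a `gene` column")
  common <- sort(intersect(correlates$gene, dge$gene))
  if (length(common) == 0)
    stop_("no genes shared between the correlate and DGE tables")
  structure(common, n_correlates = length(unique(correlates$gene)),
            n_dge = length(unique(dge$gene)))
}

#' Partition genes into contiguous bins ranked by transcriptional correlate
#'
#' Genes are sorted by `r_s` descending (ties broken by gene id ascending)
#' and split into `B` contiguous bins: the first `N mod B` bins hold
#' `ceiling(N / B)` genes, the rest `floor(N / B)`, so bin sizes differ by
#' at most one and bin 1 holds the most positive correlates. Per-bin means
#' of the correlate and of the DGE beta are computed.
#'
#' @param correlates table with `gene` and `r_s`.
#' @param dge table with `gene` and `beta` (one disorder's values).
#' @param B number of bins, `1 <= B <= N`.
#' @param genes optional gene universe (defaults to
#'   [intersect_genes()] of the two tables).
#' @return `data.frame`: bin, n_genes, mean_correlate, mean_beta; attribute
#'   `members` is the list of gene ids per bin.
#' @export
bin_genes <- function(correlates, dge, B, genes = NULL) {
  genes <- genes %||% intersect_genes(correlates, dge)
  n <- length(genes)
  check_number(B, "B", lower = 1, integer = TRUE)
  if (B > n) stop_(sprintf("B = %d exceeds the %d available genes", B, n))
  r <- correlates$r_s[match(genes, correlates$gene)]
  b <- dge$beta[match(genes, dge$gene)]
  if (anyNA(r) || anyNA(b)) stop_("gene universe not covered by both tables")
  ord <- order(-r, genes) # descending correlate, gene id ascending on ties
  sizes <- rep(floor(n / B), B)
  rem <- n %% B
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  idx <- rep(seq_len(B), times = sizes)
  members <- split(genes[ord], idx)
  out <- data.frame(
    bin = seq_len(B),
    n_genes = as.integer(sizes),
    mean_correlate = as.numeric(tapply(r[ord], idx, mean)),
    mean_beta = as.numeric(tapply(b[ord], idx, mean))
  )
  attr(out, "members") <- unname(members)
  out
}

#' Spearman correlation over bin means
#'
#' The bin-based estimator: Spearman correlation between the per-bin mean
#' transcriptional correlate and the per-bin mean DGE beta. With `B = N`
#' (one gene per bin) it collapses exactly to the direct gene-level
#' Spearman correlation.
#'
#' @param bins a [bin_genes()] table.
#' @return list with `r_s` and `p` (from [spearman()]).
#' @export
bin_correlation <- function(bins) {
  if (!all(c("mean_correlate", "mean_beta") %in% names(bins)))
    stop_("expected a bin table from bin_genes()")
  if (nrow(bins) < 4) stop_("need at least 4 bins")
  spearman(bins$mean_correlate, bins$mean_beta)
}

#' Top-K up- and down-regulated gene sets from DGE betas
#'
#' `up` holds the K largest positive betas, `down` the K most negative; the
#' sets are disjoint. If fewer than K positive (or negative) betas exist the
#' set is truncated with a warning.
#'
#' @param dge table with `gene` and `beta`.
#' @param K set size, default 500.
#' @return list with `up` and `down` gene id vectors.
#' @export
topk_updown <- function(dge, K = 500) {
  check_number(K, "K", lower = 1, integer = TRUE)
  if (!all(c("gene", "beta") %in% names(dge)))
    stop_("expected a DGE table with gene and beta")
  pos <- dge[dge$beta > 0, , drop = FALSE]
  neg <- dge[dge$beta < 0, , drop = FALSE]
  if (nrow(pos) < K || nrow(neg) < K)
    warning(sprintf("fewer than K = %d positive (%d) or negative (%d) betas; truncating",
                    K, nrow(pos), nrow(neg)), call. = FALSE)
  up <- pos$gene[order(-pos$beta, pos$gene)][seq_len(min(K, nrow(pos)))]
  down <- neg$gene[order(neg$beta, neg$gene)][seq_len(min(K, nrow(neg)))]
  list(up = up, down = down)
}
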