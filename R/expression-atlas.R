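# Probe-level samples -> region x gene expression matrix.
#
# Mirrors the standard atlas-construction strategy for multi-donor
# microarray data: intensity-based background filtering, selection of one
# representative probe per gene by differential stability, within-donor
# normalisation, then aggregation within regions and across donors. Samples
# arrive pre-labelled with regions; no coordinate matching is performed.

check_probe_samples <- function(samples) {
  need <- c("donor", "sample", "region", "probe", "gene", "intensity")
  if (!is.data.frame(samples) || nrow(samples) == 0)
    stop_("probe samples must be a non-empty data.frame")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    stop_("probe samples lack columns: ", paste(miss, collapse = ", "))
  # a probe must map to exactly one gene
  map <- unique(samples[, c("probe", "gene")])
  dup <- map$probe[duplicated(map$probe)]
  if (length(dup) > 0)
    stop_("probes mapped to multiple genes: ", paste(unique(dup), collapse = ", "))
  invisible(samples)
}

#' Filter probes by above-background fraction
#'
#' Retains probes whose fraction of samples flagged above background reaches
#' `threshold_fraction` (default 0.5, the conventional 50% background-noise
#' cut). Genes that lose every probe are dropped and reported.
#'
#' @param samples probe-level `data.frame` (see [gen_probe_samples()]) with a
#'   logical `above_background` column.
#' @param threshold_fraction required above-background fraction, in `(0, 1]`.
#' @return list with `samples` (the retained rows), `kept_probes`,
#'   `dropped_probes`, and `dropped_genes` (genes with no surviving probe).
#' @export
filter_probes <- function(samples, threshold_fraction = 0.5) {
  check_probe_samples(samples)
  check_number(threshold_fraction, "threshold_fraction",
               lower = 1e-12, upper = 1)
  if (!is.logical(samples$above_background))
    stop_("`above_background` must be a logical column")
  frac <- tapply(samples$above_background, samples$probe, mean)
  kept <- names(frac)[frac >= threshold_fraction]
  dropped <- setdiff(names(frac), kept)
  all_genes <- unique(samples$gene)
  out <- samples[samples$probe %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  dropped_genes <- setdiff(all_genes, unique(out$gene))
  list(samples = out, kept_probes = kept, dropped_probes = dropped,
       dropped_genes = dropped_genes)
}

# per-probe donor profile matrix: regions x donors of mean intensity
probe_donor_profiles <- function(sub) {
  tapply(sub$intensity, list(sub$region, sub$donor), mean)
}

# differential stability: mean over donor pairs of the Pearson correlation
# between the donors' regional profiles (pairwise-complete regions)
differential_stability <- function(profiles) {
  d <- ncol(profiles)
  if (d < 2) return(NA_real_)
  cors <- c()
  for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
    ok <- is.finite(profiles[, i]) & is.finite(profiles[, j])
    if (sum(ok) >= 3 && stats::sd(profiles[ok, i]) > 0 &&
        stats::sd(profiles[ok, j]) > 0)
      cors <- c(cors, stats::cor(profiles[ok, i], profiles[ok, j]))
  }
  if (length(cors) == 0) NA_real_ else mean(cors)
}

#' Select one representative probe per gene by differential stability
#'
#' For each gene, picks the probe whose regional expression profile is most
#' consistent across donors: the mean, over all donor pairs, of the Pearson
#' correlation between the two donors' regional profiles. Ties (including
#' all-NA stability) are broken by the lexicographically smallest probe id.
#' With a single donor no stability can be computed; the probe with the
#' highest mean intensity is used instead, with a warning.
#'
#' @param samples probe-level `data.frame`, normally already background
#'   filtered (the `samples` element of [filter_probes()]).
#' @return named character vector mapping gene id -> probe id.
#' @export
select_representative_probe <- function(samples) {
  check_probe_samples(samples)
  single_donor <- length(unique(samples$donor)) < 2
  if (single_donor)
    warning("single donor: falling back to highest mean intensity",
            call. = FALSE)
  by_probe <- split(samples, samples$probe)
  probe_gene <- vapply(by_probe, function(s) s$gene[1], character(1))
  score <- if (single_donor) {
    vapply(by_probe, function(s) mean(s$intensity), numeric(1))
  } else {
    vapply(by_probe, function(s)
      differential_stability(probe_donor_profiles(s)), numeric(1))
  }
  genes <- sort(unique(probe_gene))
  rep_map <- vapply(genes, function(g) {
    probes <- sort(names(by_probe)[probe_gene == g]) # lexicographic tie-break
    sc <- score[probes]
    if (all(!is.finite(sc))) return(probes[1])
    sc[!is.finite(sc)] <- -Inf
    probes[which.max(sc)] # which.max takes the first (smallest id) on ties
  }, character(1))
  stats::setNames(rep_map, genes)
}

scaled_robust_sigmoid <- function(x) {
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  if (iqr == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  (y - min(y)) / (max(y) - min(y))
}

#' Aggregate representative-probe samples into a region x gene matrix
#'
#' Per donor and gene, intensities are normalised across that donor's
#' samples (`zscore`, the default, or `srs`, a scaled robust sigmoid), then
#' averaged within regions; finally regions are averaged across donors.
#' Regions of the target parcellation with no sample in any donor are
#' excluded with a warning, never imputed.
#'
#' @param samples probe-level `data.frame` (filtered).
#' @param representative_map named gene -> probe vector from
#'   [select_representative_probe()].
#' @param normalization `"zscore"` or `"srs"`.
#' @param regions optional character vector declaring the target
#'   parcellation; defaults to the region labels present in `samples`.
#' @return numeric matrix (regions x genes) with dimnames; attribute
#'   `excluded_regions` lists parcellation regions that had no data.
#' @export
aggregate_to_regions <- function(samples, representative_map,
                                 normalization = c("zscore", "srs"),
                                 regions = NULL) {
  check_probe_samples(samples)
  normalization <- match.arg(normalization)
  keep <- samples$probe %in% representative_map &
    samples$gene %in% names(representative_map)
  sub <- samples[keep, , drop = FALSE]
  # only rows where the probe is the gene's representative
  sub <- sub[sub$probe == unname(representative_map[sub$gene]), , drop = FALSE]
  if (nrow(sub) == 0) stop_("no samples left for the representative probes")

  all_regions <- regions %||% sort(unique(sub$region))
  stray <- setdiff(unique(sub$region), all_regions)
  if (length(stray) > 0)
    stop_("samples carry region labels outside the parcellation: ",
          paste(stray, collapse = ", "))
  genes <- sort(unique(sub$gene))
  donors <- unique(sub$donor)

  norm_fun <- switch(normalization, zscore = function(x) zscale(x, TRUE),
                     srs = scaled_robust_sigmoid)
  acc <- array(NA_real_, dim = c(length(all_regions), length(genes),
                                 length(donors)),
               dimnames = list(all_regions, genes, donors))
  for (di in seq_along(donors)) {
    ds <- sub[sub$donor == donors[di], , drop = FALSE]
    for (g in unique(ds$gene)) {
      gs <- ds[ds$gene == g, , drop = FALSE]
      v <- norm_fun(gs$intensity) # across this donor's samples
      m <- tapply(v, gs$region, mean) # within-region average
      acc[names(m), g, di] <- m
    }
  }
  X <- apply(acc, c(1, 2), mean, na.rm = TRUE) # across donors
  X[is.nan(X)] <- NA_real_
  empty <- rownames(X)[rowSums(is.na(X)) == ncol(X)]
  if (length(empty) > 0) {
    warning("regions with no sample in any donor excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    X <- X[!rownames(X) %in% empty, , drop = FALSE]
  }
  if (anyNA(X))
    stop_("aggregation left missing (region, gene) cells; ",
          "supply data covering every region or drop incomplete genes")
  attr(X, "excluded_regions") <- empty
  X
}

#' Build an expression matrix from probe-level samples in one call
#'
#' Convenience wrapper chaining [filter_probes()],
#' [select_representative_probe()] and [aggregate_to_regions()].
#'
#' @inheritParams filter_probes
#' @inheritParams aggregate_to_regions
#' @return as [aggregate_to_regions()], with attributes `dropped_genes` and
#'   `representative` recording the filter report and the probe map.
#' @export
build_expression_atlas <- function(samples, threshold_fraction = 0.5,
                                   normalization = c("zscore", "srs"),
                                   regions = NULL) {
  flt <- filter_probes(samples, threshold_fraction)
  if (nrow(flt$samples) == 0)
    stop_("all probes fell below background; nothing to aggregate")
  rep_map <- select_representative_probe(flt$samples)
  X <- aggregate_to_regions(flt$samples, rep_map, normalization, regions)
  attr(X, "dropped_genes") <- flt$dropped_genes
  attr(X, "representative") <- rep_map
  X
}
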