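# Subject-level regional measures -> per-region case-control effect sizes
# and first-principal-component summaries of effect maps and expression.

covariate_names <- function() c("age", "sex", "education", "motion")

check_subject_table <- function(table) {
  need <- c("subject", "group", covariate_names())
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop_("subject table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(table$group %in% c("case", "control")))
    stop_("group must be 'case' or 'control'")
  if (sum(table$group == "case") < 2 || sum(table$group == "control") < 2)
    stop_("need at least 2 subjects per group")
  covs <- table[, covariate_names()]
  if (anyNA(covs)) stop_("missing covariate values")
  invisible(table)
}

region_columns <- function(table) {
  setdiff(names(table), c("subject", "group", covariate_names()))
}

#' Regress covariates out of every regional measure
#'
#' Replaces each region's measure by the residuals of an ordinary
#' least-squares fit on the covariates (age, sex, education, head motion)
#' plus an intercept, fitted on all subjects pooled. Residuals are exactly
#' orthogonal to every covariate column. Covariates constant within the
#' table (e.g. sex inside a sex-stratified subgroup) are dropped from the
#' design with a message; rank deficiency among the remaining columns is an
#' error naming the offending columns.
#'
#' @param table subject table: `subject`, `group`, the four covariates, then
#'   one numeric column per region.
#' @return the table with region columns replaced by residuals.
#' @export
residualize <- function(table) {
  check_subject_table(table)
  regions <- region_columns(table)
  covs <- as.matrix(table[, covariate_names()])
  # covariates constant within the table (e.g. sex inside a sex-stratified
  # subgroup) carry no information beyond the intercept and are dropped
  const <- apply(covs, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    message("constant covariate(s) dropped from the design: ",
            paste(colnames(covs)[const], collapse = ", "))
    covs <- covs[, !const, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, covs)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    stop_("covariate design matrix is rank deficient; offending columns: ",
          paste(bad, collapse = ", "))
  }
  Y <- as.matrix(table[, regions, drop = FALSE])
  table[, regions] <- qr.resid(qr_x, Y)
  table
}

#' Per-region two-sample t statistics (case minus control)
#'
#' Pooled-variance (Student) two-sample t per region with
#' `df = n1 + n2 - 2` and two-sided p; `welch = TRUE` switches to the
#' Welch unequal-variance form.
#'
#' @param table subject table (typically after [residualize()]).
#' @param welch use Welch's t instead of the pooled form.
#' @return `data.frame` with region, t, p plus attributes `n_case`,
#'   `n_control`.
#' @export
case_control_t <- function(table, welch = FALSE) {
  check_subject_table(table)
  regions <- region_columns(table)
  Y <- as.matrix(table[, regions, drop = FALSE])
  is_case <- table$group == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  m1 <- colMeans(Y[is_case, , drop = FALSE])
  m2 <- colMeans(Y[!is_case, , drop = FALSE])
  v1 <- apply(Y[is_case, , drop = FALSE], 2L, stats::var)
  v2 <- apply(Y[!is_case, , drop = FALSE], 2L, stats::var)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  }
  bad <- regions[!is.finite(se) | se == 0]
  if (length(bad) > 0)
    stop_("zero pooled variance in region(s): ", paste(bad, collapse = ", "))
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  structure(data.frame(region = regions, t = unname(t_stat), p = unname(p),
                       stringsAsFactors = FALSE),
            n_case = n1, n_control = n2)
}

#' Convert a two-sample t statistic to Cohen's d
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, the standard conversion for a two-sample
#' design; d and t always share their sign.
#'
#' @param t t statistic(s).
#' @param n1,n2 group sizes (each at least 2).
#' @return Cohen's d, same length as `t`.
#' @export
t_to_d <- function(t, n1, n2) {
  check_number(n1, "n1", lower = 2, integer = TRUE)
  check_number(n2, "n2", lower = 2, integer = TRUE)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Benjamini-Hochberg FDR q values and significance mask
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with a significance mask
#' at `alpha`.
#'
#' @param pvals p values in `(0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return list with `q` and logical `significant`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop_("p values must lie in (0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Full effect-size map for one measure
#'
#' Chains [residualize()] (optional), [case_control_t()], [t_to_d()] and
#' [fdr_bh()] into the per-region effect table.
#'
#' @param table subject table for one measure.
#' @param measure measure name stored in the table.
#' @param residualize_covariates regress covariates out first (default TRUE).
#' @param alpha FDR level.
#' @param welch passed to [case_control_t()].
#' @return `data.frame`: region, t, d, p, q, significant, measure.
#' @export
effect_size_map <- function(table, measure = "measure",
                            residualize_covariates = TRUE, alpha = 0.05,
                            welch = FALSE) {
  if (residualize_covariates) table <- residualize(table)
  tt <- case_control_t(table, welch = welch)
  d <- t_to_d(tt$t, attr(tt, "n_case"), attr(tt, "n_control"))
  adj <- fdr_bh(tt$p, alpha)
  data.frame(region = tt$region, t = tt$t, d = d, p = tt$p, q = adj$q,
             significant = adj$significant, measure = measure,
             stringsAsFactors = FALSE)
}

pc_summary <- function(scores, var_explained, loadings, sign_convention) {
  structure(list(scores = scores, var_explained = var_explained,
                 loadings = loadings, sign_convention = sign_convention),
            class = "pc_summary")
}

#' @export
print.pc_summary <- function(x, ...) {
  cat(sprintf("PC1 summary: %d observations, %.1f%% variance explained (%s)\n",
              length(x$scores), 100 * x$var_explained, x$sign_convention))
  invisible(x)
}

# PC1 via SVD of the centred (and by default column-standardized) matrix;
# deterministic solver.
pc1_standardized <- function(M, standardize = TRUE) {
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    drop <- colnames(M)[sds == 0] %||% which(sds == 0)
    warning("constant columns dropped before PCA: ",
            paste(drop, collapse = ", "), call. = FALSE)
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) < 2) stop_("fewer than 2 non-constant columns left for PCA")
  }
  Z <- scale(M, center = TRUE, scale = standardize)
  sv <- svd(Z)
  list(scores = sv$u[, 1] * sv$d[1],
       loadings = stats::setNames(sv$v[, 1], colnames(M)),
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       M = M)
}

#' First principal component of stacked effect-size maps (funcPC1)
#'
#' PC1 of the regions x measures matrix of Cohen's d values (columns
#' standardized), computed by SVD. Scores are z-scored across regions and
#' the sign is fixed so the component correlates positively with the mean
#' of the input maps — PCA sign is otherwise arbitrary, and directional
#' statements about the component require a reproducible convention.
#'
#' @param maps regions x measures numeric matrix (or data.frame) of effect
#'   sizes; typically the three functional measures' d maps.
#' @param standardize_maps standardize columns before PCA (default TRUE;
#'   FALSE uses the covariance-scale PCA).
#' @return a `pc_summary`: z-scored per-region `scores`, `var_explained`,
#'   `loadings`, `sign_convention`.
#' @export
pc1_of_effects <- function(maps, standardize_maps = TRUE) {
  M <- as.matrix(maps)
  if (nrow(M) < 3 || ncol(M) < 2)
    stop_("need at least 3 regions and 2 maps")
  pc <- pc1_standardized(M, standardize = standardize_maps)
  # sign: positive correlation with the mean input map (non-constant maps)
  mean_map <- rowMeans(scale(pc$M, scale = standardize_maps))
  s <- sum(pc$scores * mean_map)
  flip <- if (s < 0) -1 else 1
  pc_summary(stats::setNames(zscale(flip * pc$scores), rownames(M)),
             pc$var_explained, flip * pc$loadings,
             "positive correlation with mean input map")
}

#' First principal component of a regional expression matrix (genePC1)
#'
#' Regions are observations and genes variables; gene columns are
#' standardized and PC1 extracted by SVD. Scores are z-scored across
#' regions. The sign is fixed so the sum of gene loadings is positive (the
#' majority-positive-loading convention): the dominant expression axis of a
#' cortical atlas is carried by many coherently oriented genes, and this
#' convention pins its direction reproducibly.
#'
#' @param X regions x genes numeric matrix; zero-variance genes are dropped
#'   with a warning.
#' @return a `pc_summary` as in [pc1_of_effects()].
#' @export
pc1_of_expression <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3 || ncol(X) < 2)
    stop_("need at least 3 regions and 2 genes")
  pc <- pc1_standardized(X)
  flip <- if (sum(pc$loadings) < 0) -1 else 1
  pc_summary(stats::setNames(zscale(flip * pc$scores), rownames(X)),
             pc$var_explained, flip * pc$loadings,
             "positive loading sum")
}
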