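# End-to-end orchestration: synthetic or file-based inputs -> effect maps,
# PC summaries, correlate tables, bin tables, enrichment tables, and (in
# synthetic mode) a ground-truth recovery report.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one flat list that round-trips
#' through YAML ([write_config()] / [read_config()]). Every stochastic stage
#' receives an explicit seed derived from `seed`.
#'
#' @param mode `"synthetic"` (generate inputs) or `"files"` (read them).
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_regions,n_genes,n_causal expression-generator dimensions.
#' @param gradient_loading_sd,expression_noise_sd expression-generator scales.
#' @param n_case,n_control group sizes.
#' @param rho_func,rho_gmv planted Spearman-scale couplings.
#' @param subject_noise_sd residual subject noise sd.
#' @param effect_sd_func,effect_sd_gmv spread of the true d maps.
#' @param measure_cor true correlation between functional measures' maps.
#' @param dge_coupling named numeric: coupling sign per simulated disorder.
#' @param dge_zero_inflation zero-inflation fraction of the DGE generator.
#' @param alpha significance level (Bonferroni selection and FDR flags).
#' @param bins bin counts for the bin-based estimator; the first entry is
#'   the primary one.
#' @param top_k K for the up/down DGE sets.
#' @param residualize regress covariates out before the t-tests.
#' @param welch use Welch instead of pooled t.
#' @param standardize_maps standardize effect maps before PCA.
#' @param normalization expression-atlas normalization
#'   (`"zscore"`/`"srs"`), used when building from probe samples.
#' @param expression_tsv,dge_tsv,gmt,subject_tsvs input paths for
#'   `mode = "files"`; `subject_tsvs` is a named list
#'   (GMV/ALFF/fALFF/ReHo).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "synthetic", seed = 1L,
                            n_regions = 210L, n_genes = 2000L,
                            n_causal = 600L, gradient_loading_sd = 1,
                            expression_noise_sd = 0.5,
                            n_case = 200L, n_control = 200L,
                            rho_func = -0.3, rho_gmv = 0.35,
                            subject_noise_sd = 1,
                            effect_sd_func = 0.15, effect_sd_gmv = 0.12,
                            measure_cor = 0.7,
                            dge_coupling = c(MDD = -1),
                            dge_zero_inflation = 0.8,
                            alpha = 0.05, bins = c(100L, 50L, 150L, 200L),
                            top_k = 500L, residualize = TRUE, welch = FALSE,
                            standardize_maps = TRUE,
                            normalization = "zscore",
                            expression_tsv = NULL, dge_tsv = NULL,
                            gmt = NULL, subject_tsvs = NULL) {
  mode <- match.arg(mode, c("synthetic", "files"))
  check_number(seed, "seed", integer = TRUE)
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

# derived stage seeds, kept below 2^31 (double arithmetic avoids integer
# overflow for large master seeds)
stage_seed <- function(seed, stage) {
  offsets <- c(expression = 11, subjects = 23, dge = 37, extra = 53)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %%
               .Machine$integer.max)
}

simulate_inputs <- function(cfg) {
  expr <- gen_expression(cfg$n_regions, cfg$n_genes, cfg$n_causal,
                         cfg$gradient_loading_sd, cfg$expression_noise_sd,
                         seed = stage_seed(cfg$seed, "expression"))
  subj <- gen_subjects(cfg$n_case, cfg$n_control, expr$truth$gradient,
                       rho_func = cfg$rho_func, rho_gmv = cfg$rho_gmv,
                       noise_sd = cfg$subject_noise_sd,
                       seed = stage_seed(cfg$seed, "subjects"),
                       effect_sd_func = cfg$effect_sd_func,
                       effect_sd_gmv = cfg$effect_sd_gmv,
                       measure_cor = cfg$measure_cor)
  # DGE is coupled to each gene's true funcPC1 transcriptional correlate:
  # its gradient loading (0 for non-causal genes) times the sign of the
  # gradient -> functional-map coupling.
  loading_truth <- stats::setNames(numeric(cfg$n_genes),
                                   colnames(expr$expression))
  loading_truth[names(expr$truth$loadings)] <- expr$truth$loadings
  correlate_truth <- loading_truth *
    (if (cfg$rho_func < 0) -1 else 1)
  dge <- lapply(seq_along(cfg$dge_coupling), function(i)
    gen_dge(correlate_truth, cfg$dge_coupling[[i]], cfg$dge_zero_inflation,
            seed = (stage_seed(cfg$seed, "dge") + i) %% .Machine$integer.max,
            disorder = names(cfg$dge_coupling)[i]))
  names(dge) <- names(cfg$dge_coupling)
  list(expression = expr$expression, measures = subj$measures, dge = dge,
       truth = c(expr$truth, subj$truth[setdiff(names(subj$truth), "seed")]),
       collection = NULL)
}

read_inputs <- function(cfg) {
  if (is.null(cfg$expression_tsv) || is.null(cfg$subject_tsvs))
    stop_("mode = 'files' needs expression_tsv and subject_tsvs")
  measures <- lapply(cfg$subject_tsvs, read_subject_tsv)
  dge <- NULL
  if (!is.null(cfg$dge_tsv)) {
    tab <- read_dge_tsv(cfg$dge_tsv)
    dge <- split(tab, tab$disorder)
  }
  list(expression = read_expression_tsv(cfg$expression_tsv),
       measures = measures, dge = dge, truth = NULL,
       collection = if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL)
}

apply_subset <- function(measures, subset) {
  if (is.null(subset)) return(measures)
  lapply(measures, function(tab) {
    keep <- rep(TRUE, nrow(tab))
    for (nm in names(subset)) keep <- keep & tab[[nm]] %in% subset[[nm]]
    tab[keep, , drop = FALSE]
  })
}

truth_report <- function(res, truth) {
  grad <- truth$gradient
  g_rs <- spearman(res$gene_pc1$scores[names(grad)], grad)$r_s
  sel <- unique(c(res$selected$funcPC1$positive, res$selected$funcPC1$negative,
                  res$selected$GMV$positive, res$selected$GMV$negative))
  causal <- truth$causal_genes
  list(
    genePC1_vs_gradient_rs = g_rs,
    planted_rho_func = truth$rho_func,
    recovered_rho_func = res$gene_pc1_vs_func_pc1$r_s,
    planted_rho_gmv = truth$rho_gmv,
    recovered_rho_gmv = res$gene_pc1_vs_gmv$r_s,
    causal_recall = if (length(causal)) mean(causal %in% sel) else NA_real_,
    false_positive_genes = sum(!sel %in% causal)
  )
}

#' Run the full transcriptome-neuroimaging pipeline
#'
#' Generates (or reads) the inputs, computes per-measure effect-size maps,
#' funcPC1 and genePC1, the headline genePC1 associations, per-gene
#' transcriptional correlates with Bonferroni selection against both target
#' maps, the bin-based DGE linkage per disorder, top-K up/down DGE sets and
#' their enrichment in the selected gene sets, plus a ground-truth recovery
#' report in synthetic mode. With `output_dir` set, every stage's table is
#' written as TSV/GMT/JSON together with a manifest of file hashes and
#' seeds; re-running an identical config reproduces byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for stage outputs and manifest.
#' @param subset optional named list of covariate values to keep (e.g.
#'   `list(sex = 1)`), applied to the subject tables before the effect-map
#'   stage.
#' @param collection optional named list of annotation gene sets to test
#'   beyond the up/down DGE sets.
#' @return result bundle (list): `effects`, `func_pc1`, `gene_pc1`,
#'   `gene_pc1_vs_func_pc1`, `gene_pc1_vs_gmv`, `correlates`, `selected`,
#'   `dge_link`, `enrichment`, `truth_report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         subset = NULL, collection = NULL) {
  cfg <- config
  inputs <- switch(cfg$mode, synthetic = simulate_inputs(cfg),
                   files = read_inputs(cfg))
  measures <- apply_subset(inputs$measures, subset)
  need <- c("GMV", "ALFF", "fALFF", "ReHo")
  miss <- setdiff(need, names(measures))
  if (length(miss) > 0)
    stop_("stage effects: missing measure table(s): ",
          paste(miss, collapse = ", "))

  effects <- lapply(need, function(m)
    effect_size_map(measures[[m]], measure = m,
                    residualize_covariates = cfg$residualize,
                    alpha = cfg$alpha, welch = cfg$welch))
  names(effects) <- need

  d_maps <- vapply(effects[c("ALFF", "fALFF", "ReHo")], `[[`,
                   numeric(nrow(effects$GMV)), "d")
  rownames(d_maps) <- effects$GMV$region
  func_pc1 <- pc1_of_effects(d_maps, standardize_maps = cfg$standardize_maps)
  gene_pc1 <- pc1_of_expression(inputs$expression)

  gmv_d <- stats::setNames(effects$GMV$d, effects$GMV$region)
  common_regions <- rownames(inputs$expression)
  if (!identical(sort(common_regions), sort(names(gmv_d))))
    stop_("stage correlates: expression and subject tables cover different regions")
  gmv_d <- gmv_d[common_regions]
  func_scores <- func_pc1$scores[common_regions]

  hl_func <- spearman(gene_pc1$scores[common_regions], func_scores)
  hl_gmv <- spearman(gene_pc1$scores[common_regions], gmv_d)

  cors <- list(
    funcPC1 = gene_correlates(inputs$expression, func_scores, "funcPC1"),
    GMV = gene_correlates(inputs$expression, gmv_d, "GMV-d"))
  selected <- lapply(cors, select_significant, alpha = cfg$alpha)

  dge_link <- NULL
  enrichment <- NULL
  if (!is.null(inputs$dge)) {
    dge_link <- lapply(names(inputs$dge), function(dis) {
      dtab <- inputs$dge[[dis]]
      lapply(cors, function(ct) {
        genes <- intersect_genes(ct, dtab)
        direct <- {
          r <- ct$r_s[match(genes, ct$gene)]
          b <- dtab$beta[match(genes, dtab$gene)]
          spearman(r, b)
        }
        per_b <- lapply(cfg$bins, function(B) {
          bins <- bin_genes(ct, dtab, B, genes = genes)
          c(list(B = B), bin_correlation(bins))
        })
        list(n_common = length(genes), direct = direct,
             binned = per_b, primary = per_b[[1]])
      })
    })
    names(dge_link) <- names(inputs$dge)

    updown <- lapply(inputs$dge, topk_updown, K = cfg$top_k)
    background <- cors$funcPC1$gene
    anno <- list()
    for (dis in names(updown)) {
      anno[[paste0(dis, "_up")]] <- intersect(updown[[dis]]$up, background)
      anno[[paste0(dis, "_down")]] <- intersect(updown[[dis]]$down, background)
    }
    if (!is.null(collection %||% inputs$collection))
      anno <- c(anno, lapply(collection %||% inputs$collection,
                             intersect, background))
    queries <- list(`funcPC1+` = selected$funcPC1$positive,
                    `funcPC1-` = selected$funcPC1$negative,
                    `GMV+` = selected$GMV$positive,
                    `GMV-` = selected$GMV$negative)
    queries <- queries[lengths(queries) > 0]
    if (length(queries) > 0 && length(anno) > 0)
      enrichment <- enrich_collection(queries, anno, background,
                                      alpha = cfg$alpha)
  }

  res <- list(effects = effects, func_pc1 = func_pc1, gene_pc1 = gene_pc1,
              gene_pc1_vs_func_pc1 = hl_func, gene_pc1_vs_gmv = hl_gmv,
              correlates = cors, selected = selected, dge_link = dge_link,
              enrichment = enrichment, truth_report = NULL, config = cfg)
  if (!is.null(inputs$truth)) res$truth_report <- truth_report(res, inputs$truth)

  if (!is.null(output_dir)) write_bundle(res, inputs, output_dir)
  res
}

pc_summary_df <- function(pc) {
  data.frame(region = names(pc$scores), score = unname(pc$scores))
}

write_bundle <- function(res, inputs, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, paste0(...))
  write_expression_tsv(inputs$expression, fp("expression.tsv"))
  for (m in names(inputs$measures))
    write_subject_tsv(inputs$measures[[m]], fp("subjects_", m, ".tsv"))
  for (m in names(res$effects))
    write_tsv_(res$effects[[m]], fp("effects_", m, ".tsv"))
  write_tsv_(pc_summary_df(res$func_pc1), fp("func_pc1.tsv"))
  write_tsv_(pc_summary_df(res$gene_pc1), fp("gene_pc1.tsv"))
  jsonlite::write_json(
    list(func_pc1 = list(var_explained = res$func_pc1$var_explained,
                         sign_convention = res$func_pc1$sign_convention),
         gene_pc1 = list(var_explained = res$gene_pc1$var_explained,
                         sign_convention = res$gene_pc1$sign_convention),
         gene_pc1_vs_func_pc1 = res$gene_pc1_vs_func_pc1,
         gene_pc1_vs_gmv = res$gene_pc1_vs_gmv),
    fp("pc_metadata.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tn in names(res$correlates))
    write_tsv_(res$selected[[tn]]$table, fp("correlates_", tn, ".tsv"))
  sets <- list(`funcPC1+` = res$selected$funcPC1$positive,
               `funcPC1-` = res$selected$funcPC1$negative,
               `GMV+` = res$selected$GMV$positive,
               `GMV-` = res$selected$GMV$negative)
  write_gmt(sets, fp("selected_gene_sets.gmt"))
  if (!is.null(inputs$dge))
    write_dge_tsv(do.call(rbind, inputs$dge), fp("dge.tsv"))
  if (!is.null(res$dge_link)) {
    rows <- do.call(rbind, lapply(names(res$dge_link), function(dis)
      do.call(rbind, lapply(names(res$dge_link[[dis]]), function(tn) {
        lk <- res$dge_link[[dis]][[tn]]
        data.frame(disorder = dis, target = tn,
                   B = vapply(lk$binned, `[[`, numeric(1), "B"),
                   r_s = vapply(lk$binned, `[[`, numeric(1), "r_s"),
                   p = vapply(lk$binned, `[[`, numeric(1), "p"),
                   direct_r_s = lk$direct$r_s, direct_p = lk$direct$p,
                   n_common = lk$n_common)
      }))))
    write_tsv_(rows, fp("bin_correlations.tsv"))
  }
  if (!is.null(res$enrichment))
    write_tsv_(res$enrichment, fp("enrichment.tsv"))
  if (!is.null(res$truth_report))
    jsonlite::write_json(res$truth_report, fp("truth_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(inputs$truth)) {
    tr <- inputs$truth
    tr$delta <- lapply(tr$delta, as.list)
    write_ground_truth_json(tr, fp("ground_truth.json"))
  }
  write_config(unclass(res$config), fp("config.yaml"))

  files <- sort(setdiff(list.files(output_dir), "manifest.json"))
  manifest <- list(
    package = "transcortex",
    version = as.character(utils::packageVersion("transcortex")),
    seed = res$config$seed,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(output_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
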