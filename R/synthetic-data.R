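# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of its parameters and `seed`: the global
# RNG state is saved and restored, so identical calls give identical output
# and calls do not perturb the caller's random stream.

with_seed <- function(seed, code) {
  check_number(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a regional expression matrix with a planted spatial gradient
#'
#' Emulates a bulk microarray expression atlas sampled over a cortical
#' parcellation: a subset of "causal" genes load on a single latent spatial
#' gradient (the dominant expression axis real atlases show), the remaining
#' genes are independent noise. The gradient, the causal gene ids and the
#' seed are returned as ground truth so downstream recovery can be scored.
#'
#' Causal loadings are drawn from `N(gradient_loading_sd, gradient_loading_sd/2)`,
#' i.e. predominantly positive: coherently oriented loadings are what makes
#' the first principal component of a real expression atlas a reproducible
#' spatial gradient rather than an arbitrary-sign axis.
#'
#' @param n_regions number of parcellated regions (rows); at least 3.
#' @param n_genes number of genes (columns); at least 2.
#' @param n_causal number of genes loading on the gradient (0..n_genes).
#' @param gradient_loading_sd scale of the causal loadings (> 0).
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise (> 0).
#' @param seed integer RNG seed.
#' @return A list with `expression` (regions x genes numeric matrix with
#'   region/gene dimnames) and `truth` (list: `gradient` named per-region
#'   z-scaled scores, `causal_genes`, `loadings`, `seed`).
#' @examples
#' sim <- gen_expression(30, 100, 40, 1, 0.5, seed = 1)
#' dim(sim$expression)
#' @export
gen_expression <- function(n_regions, n_genes, n_causal,
                           gradient_loading_sd = 1, noise_sd = 0.5, seed) {
  check_number(n_regions, "n_regions", lower = 3, integer = TRUE)
  check_number(n_genes, "n_genes", lower = 2, integer = TRUE)
  check_number(n_causal, "n_causal", lower = 0, upper = n_genes, integer = TRUE)
  check_number(gradient_loading_sd, "gradient_loading_sd", positive = TRUE)
  check_number(noise_sd, "noise_sd", positive = TRUE)

  with_seed(seed, {
    regions <- pad_id("r", seq_len(n_regions), n_regions)
    genes <- pad_id("g", seq_len(n_genes), n_genes)
    gradient <- zscale(stats::rnorm(n_regions))
    names(gradient) <- regions

    X <- matrix(stats::rnorm(n_regions * n_genes, sd = noise_sd),
                nrow = n_regions, dimnames = list(regions, genes))
    causal <- integer(0)
    loadings <- numeric(0)
    if (n_causal > 0) {
      causal <- sort(sample.int(n_genes, n_causal))
      loadings <- stats::rnorm(n_causal, mean = gradient_loading_sd,
                               sd = gradient_loading_sd / 2)
      X[, causal] <- X[, causal] + outer(gradient, loadings)
    }
    truth <- list(gradient = gradient,
                  causal_genes = genes[causal],
                  loadings = stats::setNames(loadings, genes[causal]),
                  seed = as.integer(seed))
    list(expression = X, truth = truth)
  })
}

default_covariate_betas <- function() {
  c(age = 0.01, sex = 0.2, education = 0.02, motion = 0.5)
}

#' Generate case/control subject tables with a planted difference map
#'
#' Simulates regional measures (GMV plus the three resting-state measures
#' ALFF, fALFF, ReHo) for a case and a control group. The per-region true
#' case-control difference, in Cohen's d units, is coupled to a supplied
#' spatial `gradient` at a requested Spearman-scale strength: a latent map is
#' drawn as a Gaussian mixture `rho_p * gradient + sqrt(1 - rho_p^2) * noise`
#' with `rho_p = 2 sin(pi rho_s / 6)`, the Pearson coefficient whose
#' population Spearman correlation equals `rho_s`. The three functional
#' measures share one latent functional map (pairwise true correlation
#' `measure_cor`), GMV gets its own; this mirrors the empirical structure of
#' case-control maps where functional measures correlate strongly with each
#' other but only loosely with structure.
#'
#' Covariates (age, sex, education, head motion) are drawn independently of
#' group and enter every regional measure additively with the stated betas,
#' so they inflate variance until regressed out but do not confound the group
#' contrast.
#'
#' @param n_case,n_control group sizes (each at least 2).
#' @param gradient named per-region z-scaled latent scores
#'   (from [gen_expression()]).
#' @param rho_func,rho_gmv Spearman-scale coupling in `[-1, 1]` between the
#'   gradient and the true functional / GMV difference maps.
#' @param covariate_betas named numeric vector of additive covariate effects
#'   (units of the measure per unit covariate) for
#'   `age` (years), `sex` (0/1), `education` (years), `motion` (mm).
#' @param noise_sd residual within-group subject standard deviation.
#' @param seed integer RNG seed.
#' @param effect_sd_func,effect_sd_gmv spread (sd across regions) of the true
#'   Cohen's d maps; defaults 0.15 and 0.12 keep effects in the weak regime
#'   reported for large case-control samples (|d| mostly below 0.3, GMV
#'   weaker than function) while leaving the planted maps large enough
#'   relative to the d-estimation error `sqrt(1/n1 + 1/n2)` that downstream
#'   stages can recover the planted couplings at a few hundred subjects per
#'   group (the generator's recovery contract).
#' @param measure_cor true correlation between any two functional measures'
#'   difference maps, in `[0, 1)`.
#' @return list with `measures` (named list of four subject `data.frame`s:
#'   subject, group, age, sex, education, motion, then one column per region)
#'   and `truth` (true d maps per measure, latent maps `u_func`/`u_gmv`, the
#'   requested couplings, betas and seed).
#' @export
gen_subjects <- function(n_case, n_control, gradient,
                         rho_func = -0.3, rho_gmv = 0.35,
                         covariate_betas = default_covariate_betas(),
                         noise_sd = 1, seed,
                         effect_sd_func = 0.15, effect_sd_gmv = 0.12,
                         measure_cor = 0.7) {
  check_number(n_case, "n_case", lower = 2, integer = TRUE)
  check_number(n_control, "n_control", lower = 2, integer = TRUE)
  check_number(rho_func, "rho_func", lower = -1, upper = 1)
  check_number(rho_gmv, "rho_gmv", lower = -1, upper = 1)
  check_number(noise_sd, "noise_sd", positive = TRUE)
  check_number(measure_cor, "measure_cor", lower = 0, upper = 1 - 1e-12)
  stopifnot(is.numeric(gradient), length(gradient) >= 3, !is.null(names(gradient)))
  need <- c("age", "sex", "education", "motion")
  if (!all(need %in% names(covariate_betas)))
    stop_("covariate_betas must be named with: ", paste(need, collapse = ", "))

  with_seed(seed, {
    regions <- names(gradient)
    R <- length(gradient)
    u_func <- couple_to(gradient, rho_func)
    u_gmv <- couple_to(gradient, rho_gmv)
    fm <- c("ALFF", "fALFF", "ReHo")
    delta <- vector("list", 4L)
    names(delta) <- c("GMV", fm)
    delta$GMV <- effect_sd_gmv * u_gmv
    for (m in fm)
      delta[[m]] <- effect_sd_func *
        (sqrt(measure_cor) * u_func + sqrt(1 - measure_cor) * stats::rnorm(R))

    n <- n_case + n_control
    covs <- data.frame(
      subject = pad_id("s", seq_len(n), n),
      group = rep(c("case", "control"), c(n_case, n_control)),
      age = stats::runif(n, 18, 65),
      sex = stats::rbinom(n, 1, 0.5),
      education = sample(6:22, n, replace = TRUE),
      motion = stats::rlnorm(n, meanlog = -2, sdlog = 0.5),
      stringsAsFactors = FALSE
    )
    cov_shift <- as.matrix(covs[, need]) %*% covariate_betas[need]
    is_case <- covs$group == "case"

    measures <- lapply(delta, function(d_map) {
      Y <- matrix(stats::rnorm(n * R, sd = noise_sd), nrow = n,
                  dimnames = list(covs$subject, regions))
      # mean shift delta * noise_sd for cases => population Cohen's d = delta
      Y <- Y + tcrossprod(as.numeric(is_case), d_map * noise_sd)
      Y <- Y + matrix(cov_shift, nrow = n, ncol = R)
      cbind(covs, as.data.frame(Y))
    })
    truth <- list(delta = lapply(delta, stats::setNames, regions),
                  u_func = stats::setNames(u_func, regions),
                  u_gmv = stats::setNames(u_gmv, regions),
                  rho_func = rho_func, rho_gmv = rho_gmv,
                  covariate_betas = covariate_betas,
                  noise_sd = noise_sd, seed = as.integer(seed))
    list(measures = measures, truth = truth)
  })
}

#' Generate a voxel-neighbourhood time-series block
#'
#' Emulates one region's resting-state BOLD neighbourhood: every voxel is an
#' optional shared low-frequency sinusoid plus i.i.d. Gaussian noise. Used to
#' feed [alff()], [falff()] and [reho()].
#'
#' @param n_time number of time points.
#' @param n_voxels voxels in the neighbourhood (27 mirrors the common
#'   3 x 3 x 3 ReHo kernel).
#' @param tr sampling interval in seconds.
#' @param signal_freq frequency (Hz) of the shared sinusoid.
#' @param signal_amp amplitude of the shared sinusoid (0 = pure noise).
#' @param noise_sd voxelwise noise standard deviation.
#' @param seed integer RNG seed.
#' @return list of class `timeseries_block`: `tr` and `series`
#'   (n_time x n_voxels matrix).
#' @export
gen_timeseries <- function(n_time = 200, n_voxels = 27, tr = 2,
                           signal_freq = 0.04, signal_amp = 1,
                           noise_sd = 1, seed) {
  check_number(n_time, "n_time", lower = 4, integer = TRUE)
  check_number(n_voxels, "n_voxels", lower = 1, integer = TRUE)
  check_number(tr, "tr", positive = TRUE)
  with_seed(seed, {
    t_sec <- (seq_len(n_time) - 1) * tr
    phase <- stats::runif(1, 0, 2 * pi)
    shared <- signal_amp * sin(2 * pi * signal_freq * t_sec + phase)
    series <- shared + matrix(stats::rnorm(n_time * n_voxels, sd = noise_sd),
                              nrow = n_time)
    structure(list(tr = tr, series = series), class = "timeseries_block")
  })
}

#' Generate multi-donor probe-level microarray samples
#'
#' Emulates the probe-level input of an expression-atlas build: each gene is
#' measured by several probes across one sample per (donor, region); one
#' planted representative probe tracks the gene's true regional profile with
#' high cross-donor consistency, decoy probes track it weakly with large
#' donor-specific noise. A configurable fraction of probes is planted below
#' background: those are flagged `above_background` in 30% of samples, all
#' other probes in 95%, so a 50% background filter separates them exactly.
#' Below-background probes are drawn among decoys when decoys exist, keeping
#' the representative recoverable.
#'
#' @param n_donors number of donors (>= 1; >= 2 for stability-based probe
#'   selection downstream).
#' @param n_regions regions sampled per donor (one sample each).
#' @param n_genes number of genes.
#' @param probes_per_gene probes measuring each gene (>= 1).
#' @param background_rate fraction of all probes planted below background,
#'   in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return list with `samples` (long `data.frame`: donor, sample, region,
#'   probe, gene, intensity (log2 a.u.), above_background) and `truth`
#'   (`representative` named gene->probe map, `below_background` probe ids,
#'   `profiles` regions x genes true profile matrix, `seed`).
#' @export
gen_probe_samples <- function(n_donors = 2, n_regions = 20, n_genes = 100,
                              probes_per_gene = 3, background_rate = 0.2,
                              seed) {
  check_number(n_donors, "n_donors", lower = 1, integer = TRUE)
  check_number(n_regions, "n_regions", lower = 2, integer = TRUE)
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(probes_per_gene, "probes_per_gene", lower = 1, integer = TRUE)
  check_number(background_rate, "background_rate", lower = 0, upper = 1)

  with_seed(seed, {
    regions <- pad_id("r", seq_len(n_regions), n_regions)
    genes <- pad_id("g", seq_len(n_genes), n_genes)
    donors <- pad_id("d", seq_len(n_donors), n_donors)
    n_probes <- n_genes * probes_per_gene
    probe_gene <- rep(genes, each = probes_per_gene)
    probes <- pad_id("p", seq_len(n_probes), n_probes)

    profiles <- matrix(stats::rnorm(n_regions * n_genes), nrow = n_regions,
                       dimnames = list(regions, genes))
    rep_idx <- (match(genes, probe_gene) - 1L) +
      sample.int(probes_per_gene, n_genes, replace = TRUE)
    representative <- stats::setNames(probes[rep_idx], genes)
    is_rep <- seq_len(n_probes) %in% rep_idx
    probe_offset <- stats::rnorm(n_probes, mean = 8, sd = 1)

    decoys <- probes[!is_rep]
    pool <- if (length(decoys) > 0) decoys else probes
    n_below <- min(round(background_rate * n_probes), length(pool))
    below <- sort(sample(pool, n_below))

    n_samples <- n_donors * n_regions
    rows <- vector("list", n_donors)
    for (di in seq_len(n_donors)) {
      sample_ids <- paste0(donors[di], "_s", regions)
      # intensity matrix: regions x probes for this donor
      sig <- profiles[, probe_gene, drop = FALSE]
      w <- ifelse(is_rep, 1, 0.3)[col(sig)]
      dn_sd <- ifelse(is_rep, 0.2, 1.5)[col(sig)]
      I <- sig * w + matrix(stats::rnorm(length(sig)), nrow = n_regions) * dn_sd
      I <- I + probe_offset[col(I)]
      rows[[di]] <- data.frame(
        donor = donors[di],
        sample = rep(sample_ids, times = n_probes),
        region = rep(regions, times = n_probes),
        probe = rep(probes, each = n_regions),
        gene = rep(probe_gene, each = n_regions),
        intensity = as.numeric(I),
        stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, rows)

    # deterministic above-background counts: 30% of samples for planted-below
    # probes, 95% for the rest (threshold 0.5 separates them exactly)
    ab <- logical(nrow(samples))
    all_sample_ids <- unique(samples$sample)
    for (p in probes) {
      frac <- if (p %in% below) 0.30 else 0.95
      k <- if (p %in% below) floor(frac * n_samples) else ceiling(frac * n_samples)
      chosen <- sample(all_sample_ids, k)
      ab[samples$probe == p & samples$sample %in% chosen] <- TRUE
    }
    samples$above_background <- ab

    truth <- list(representative = representative, below_background = below,
                  profiles = profiles, seed = as.integer(seed))
    list(samples = samples, truth = truth)
  })
}

#' Generate differential-gene-expression betas coupled to a correlate map
#'
#' Emulates meta-analytic postmortem DGE estimates: standardized betas whose
#' signal component is the (z-scaled) transcriptional-correlate truth times a
#' coupling sign, plus heavy-tailed t(3) noise. A `zero_inflation` fraction
#' of genes has its signal component shrunk by `shrink_factor`, piling most
#' betas near zero — the regime in which a bin-based correlation estimator
#' outperforms the direct gene-level correlation.
#'
#' @param correlate_truth named numeric vector (per gene) of true
#'   transcriptional correlates to couple to.
#' @param coupling_sign -1, 0 or 1.
#' @param zero_inflation fraction of genes with shrunk signal, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param disorder label stored in the table (default "MDD").
#' @param shrink_factor multiplier applied to the signal of zero-inflated
#'   genes.
#' @param noise_scale scale of the t(3) noise.
#' @return `data.frame` with columns gene, disorder, beta.
#' @export
gen_dge <- function(correlate_truth, coupling_sign, zero_inflation, seed,
                    disorder = "MDD", shrink_factor = 0.05,
                    noise_scale = 0.15) {
  if (!coupling_sign %in% c(-1, 0, 1)) stop_("coupling_sign must be -1, 0 or 1")
  check_number(zero_inflation, "zero_inflation", lower = 0, upper = 1 - 1e-12)
  stopifnot(is.numeric(correlate_truth), !is.null(names(correlate_truth)))
  with_seed(seed, {
    n <- length(correlate_truth)
    z <- zscale(correlate_truth, allow_constant = TRUE)
    shrink <- rep(1, n)
    n_inflated <- round(zero_inflation * n)
    if (n_inflated > 0) shrink[sample.int(n, n_inflated)] <- shrink_factor
    beta <- coupling_sign * shrink * z + noise_scale * stats::rt(n, df = 3)
    data.frame(gene = names(correlate_truth), disorder = disorder,
               beta = beta, stringsAsFactors = FALSE, row.names = NULL)
  })
}
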