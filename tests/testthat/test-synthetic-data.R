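test_that("generators are pure functions of their parameters and seed", {
  a <- gen_expression(20, 50, 10, 1, 0.5, seed = 7)
  b <- gen_expression(20, 50, 10, 1, 0.5, seed = 7)
  expect_identical(a, b)

  set.seed(123)
  before <- .Random.seed
  invisible(gen_subjects(5, 5, a$truth$gradient, seed = 3))
  expect_identical(.Random.seed, before) # caller's RNG stream untouched

  truth <- setNames(rnorm(50), paste0("g", 1:50))
  expect_identical(gen_dge(truth, -1, 0.5, seed = 11),
                   gen_dge(truth, -1, 0.5, seed = 11))
  expect_identical(gen_probe_samples(2, 5, 10, 2, 0.1, seed = 13),
                   gen_probe_samples(2, 5, 10, 2, 0.1, seed = 13))
})

test_that("expression generator plants a recoverable PC1 gradient", {
  sim <- gen_expression(210, 1000, 300, 1, 0.5, seed = 42)
  pc <- pc1_of_expression(sim$expression)
  rs <- spearman(pc$scores, sim$truth$gradient)$r_s
  expect_gt(abs(rs), 0.9)
  # sign convention recovers the planted orientation (positive loadings)
  expect_gt(rs, 0)

  # near-noiseless rank-1 limit: PC1 explains ~all variance
  r1 <- gen_expression(30, 50, 50, 1, 1e-6, seed = 1)
  expect_gt(pc1_of_expression(r1$expression)$var_explained, 0.999)
})

test_that("expression generator rejects degenerate dimensions", {
  expect_error(gen_expression(2, 10, 5, 1, 0.5, seed = 1), "n_regions")
  expect_error(gen_expression(10, 10, 11, 1, 0.5, seed = 1), "n_causal")
  expect_error(gen_expression(10, 10, 5, 0, 0.5, seed = 1), "gradient_loading_sd")
  expect_error(gen_expression(10, 10, 5, 1, -1, seed = 1), "noise_sd")
})

test_that("subject generator plants couplings, covariates and balance", {
  sim <- gen_expression(210, 100, 30, 1, 0.5, seed = 2)
  subj <- gen_subjects(150, 120, sim$truth$gradient, rho_func = -0.3,
                       rho_gmv = 0.35, seed = 9)
  expect_named(subj$measures, c("GMV", "ALFF", "fALFF", "ReHo"))
  tab <- subj$measures$GMV
  expect_equal(sum(tab$group == "case"), 150)
  expect_equal(sum(tab$group == "control"), 120)

  # realized true-map couplings close to requested (210 regions)
  rs_f <- spearman(subj$truth$delta$ALFF, sim$truth$gradient)$r_s
  rs_g <- spearman(subj$truth$delta$GMV, sim$truth$gradient)$r_s
  expect_lt(abs(rs_g - 0.35), 0.2)
  expect_lt(rs_f, 0.1) # negative coupling diluted by measure noise, not positive

  # group contrast matches the planted d map (large-n check on means)
  big <- gen_subjects(2000, 2000, sim$truth$gradient, seed = 10)
  Y <- as.matrix(big$measures$ALFF[, names(sim$truth$gradient)])
  diff <- colMeans(Y[big$measures$ALFF$group == "case", ]) -
    colMeans(Y[big$measures$ALFF$group == "control", ])
  expect_gt(cor(diff, big$truth$delta$ALFF), 0.8)

  expect_error(gen_subjects(1, 10, sim$truth$gradient, seed = 1), "n_case")
  expect_error(gen_subjects(10, 10, sim$truth$gradient, rho_func = 1.5, seed = 1),
               "rho_func")
})

test_that("probe-sample generator has the promised combinatorial layout", {
  ps <- gen_probe_samples(n_donors = 2, n_regions = 10, n_genes = 100,
                          probes_per_gene = 3, background_rate = 0.2, seed = 4)
  expect_equal(nrow(ps$samples), 2 * 10 * 300)
  # every probe maps to exactly one gene
  map <- unique(ps$samples[, c("probe", "gene")])
  expect_false(any(duplicated(map$probe)))
  # planted-below probes are decoys, never the representative
  expect_length(intersect(ps$truth$below_background, ps$truth$representative), 0)

  none <- gen_probe_samples(2, 10, 20, 3, background_rate = 0, seed = 5)
  flt <- filter_probes(none$samples, 0.5)
  expect_length(flt$dropped_probes, 0)
  expect_error(gen_probe_samples(2, 10, 20, 3, background_rate = 2, seed = 1),
               "background_rate")
})

test_that("DGE generator is deterministic and respects the null", {
  set.seed(1)
  truth <- setNames(rnorm(500), paste0("g", sprintf("%03d", 1:500)))
  d1 <- gen_dge(truth, -1, 0.8, seed = 21)
  d2 <- gen_dge(truth, -1, 0.8, seed = 21)
  expect_identical(d1, d2)

  # coupling_sign = 0: bin correlation centred on zero across seeds
  ct <- data.frame(gene = names(truth), r_s = unname(truth))
  rs <- vapply(1:20, function(s) {
    dge <- gen_dge(truth, 0, 0.8, seed = s)
    bin_correlation(bin_genes(ct, dge, 50))$r_s
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.12)
  expect_error(gen_dge(truth, -2, 0.5, seed = 1), "coupling_sign")
  expect_error(gen_dge(truth, 1, 1, seed = 1), "zero_inflation")
})
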