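test_that("background filter keeps probes by above-background fraction", {
  # p1 above in 3/5 samples (0.6), p2 in 2/5 (0.4), p3 in 5/5
  df <- make_probe_df(
    donor = "d1", sample = rep(paste0("s", 1:5), times = 3),
    region = rep(paste0("r", 1:5), times = 3),
    probe = rep(c("p1", "p2", "p3"), each = 5),
    gene = rep(c("gA", "gA", "gB"), each = 5),
    intensity = rnorm(15),
    above_background = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                         TRUE, TRUE, FALSE, FALSE, FALSE,
                         rep(TRUE, 5)))
  flt <- filter_probes(df, 0.5)
  expect_setequal(flt$kept_probes, c("p1", "p3"))
  expect_equal(flt$dropped_probes, "p2")
  expect_length(flt$dropped_genes, 0)

  # boundary: threshold 1 keeps only always-above probes
  strict <- filter_probes(df, 1)
  expect_equal(strict$kept_probes, "p3")
  expect_equal(strict$dropped_genes, "gA")

  # all probes below background: empty set plus complete drop report
  df$above_background <- FALSE
  none <- filter_probes(df, 0.5)
  expect_equal(nrow(none$samples), 0)
  expect_setequal(none$dropped_probes, c("p1", "p2", "p3"))
  expect_setequal(none$dropped_genes, c("gA", "gB"))

  expect_error(filter_probes(df[0, ], 0.5), "non-empty")
  expect_error(filter_probes(df, 0), "threshold_fraction")
})

test_that("representative-probe selection maximises differential stability", {
  # one probe per gene: identity mapping
  ps <- gen_probe_samples(2, 8, 10, probes_per_gene = 1, background_rate = 0,
                          seed = 3)
  rep1 <- select_representative_probe(ps$samples)
  expect_identical(rep1, ps$truth$representative[names(rep1)])

  # planted high-consistency probe recovered at small scale
  ps2 <- gen_probe_samples(2, 20, 150, probes_per_gene = 3,
                           background_rate = 0, seed = 8)
  rep2 <- select_representative_probe(ps2$samples)
  expect_gte(mean(rep2 == ps2$truth$representative[names(rep2)]), 0.95)

  # identical profiles: smaller probe id wins
  base <- make_probe_df(
    donor = rep(c("d1", "d2"), each = 4),
    sample = paste0(rep(c("d1", "d2"), each = 4), "_s", rep(1:4, 2)),
    region = rep(paste0("r", 1:4), 2),
    probe = "pB", gene = "g1", intensity = rep(c(1, 2, 3, 4), 2))
  tie <- rbind(base, transform(base, probe = "pA"))
  expect_identical(unname(select_representative_probe(tie)), "pA")

  # single donor: highest mean intensity, with a warning
  solo <- base
  solo <- rbind(solo[solo$donor == "d1", ],
                transform(base[base$donor == "d1", ], probe = "pA",
                          intensity = intensity + 5))
  expect_warning(rs <- select_representative_probe(solo), "single donor")
  expect_identical(unname(rs), "pA")
})

test_that("aggregation normalises within donor and averages as promised", {
  # one donor, one sample per region, z-score: output equals z-scored input
  vals <- c(2, 4, 6, 8)
  df <- make_probe_df(donor = "d1", sample = paste0("s", 1:4),
                      region = paste0("r", 1:4), probe = "p1", gene = "g1",
                      intensity = vals)
  X <- aggregate_to_regions(df, c(g1 = "p1"))
  expect_equal(unname(X[, "g1"]), as.numeric(scale(vals)))

  # two donors with identical data: same as single donor
  df2 <- rbind(df, transform(df, donor = "d2", sample = paste0("d2", sample)))
  X2 <- aggregate_to_regions(df2, c(g1 = "p1"))
  expect_equal(X2, X, ignore_attr = TRUE)

  # permutation invariance over row order
  shuf <- df2[sample(nrow(df2)), ]
  expect_equal(aggregate_to_regions(shuf, c(g1 = "p1")), X2,
               ignore_attr = TRUE)

  # unsampled parcellation region excluded with a warning, never imputed
  expect_warning(
    X3 <- aggregate_to_regions(df, c(g1 = "p1"),
                               regions = c(paste0("r", 1:4), "r9")),
    "no sample")
  expect_false("r9" %in% rownames(X3))
  expect_equal(attr(X3, "excluded_regions"), "r9")
})

test_that("full atlas build recovers planted regional profiles", {
  ps <- gen_probe_samples(2, 25, 80, probes_per_gene = 3,
                          background_rate = 0.2, seed = 12)
  X <- build_expression_atlas(ps$samples)
  prof <- ps$truth$profiles[rownames(X), colnames(X)]
  per_gene <- vapply(seq_len(ncol(X)), function(j) cor(X[, j], prof[, j]),
                     numeric(1))
  expect_gt(mean(per_gene), 0.9)
})
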