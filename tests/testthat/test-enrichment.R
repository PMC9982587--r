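test_that("hypergeometric enrichment p matches closed-form and enumeration", {
  bg <- paste0("g", 1:20)
  anno <- bg[1:5]
  row <- fisher_enrich(bg[1:5], anno, bg)
  expect_equal(row$p, 1 / choose(20, 5), tolerance = 1e-12) # single tail term
  expect_equal(row$overlap, 5)

  # overlap at its expectation is unsurprising
  bg2 <- paste0("g", 1:100)
  row2 <- fisher_enrich(bg2[1:10], c(bg2[1], bg2[11:19]), bg2) # overlap 1 = 10*10/100
  expect_gte(row2$p, 0.5)

  # enumeration oracle over all tables with small backgrounds
  for (N in c(5, 8, 11)) {
    bgN <- paste0("g", seq_len(N))
    for (K in 0:N) for (n in 0:N) {
      a_min <- max(0, n + K - N)
      for (a in a_min:min(n, K)) {
        q <- c(bgN[seq_len(K)][seq_len(a)],
               setdiff(bgN, bgN[seq_len(K)])[seq_len(n - a)])
        got <- fisher_enrich(q, bgN[seq_len(K)], bgN)$p
        expect_equal(got, enum_hyper_p(a, n, K, N), tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment validates subsets and flags continuity correction", {
  bg <- paste0("g", 1:30)
  expect_error(fisher_enrich(c(bg[1:3], "alien"), bg[1:5], bg), "alien")
  expect_error(fisher_enrich(bg[1:3], c(bg[1:5], "ghost"), bg), "ghost")

  zero <- fisher_enrich(bg[1:5], bg[6:10], bg) # overlap 0
  expect_true(zero$or_continuity)
  expect_gte(zero$odds_ratio, 0)
  nonzero <- fisher_enrich(bg[1:5], c(bg[1:2], bg[6:8]), bg)
  expect_false(nonzero$or_continuity)
  # odds ratio from the plain 2x2 cells: a=2 b=3 c=3 d=22
  expect_equal(nonzero$odds_ratio, (2 * 22) / (3 * 3))
})

test_that("collection enrichment corrects within query and keeps order", {
  set.seed(6)
  bg <- paste0("g", 1:500)
  queries <- list(q1 = sample(bg, 60), q2 = sample(bg, 40),
                  q3 = sample(bg, 50), q4 = sample(bg, 30))
  collection <- lapply(setNames(1:7, paste0("cell", 1:7)),
                       function(i) sample(bg, 45))
  res <- enrich_collection(queries, collection, bg)
  expect_equal(nrow(res), 4 * 7)
  expect_equal(unique(res$query), names(queries))

  # BH within one query: q monotone nondecreasing in p
  for (qn in names(queries)) {
    sub <- res[res$query == qn, ]
    expect_true(all(diff(sub$q[order(sub$p)]) >= -1e-12))
    expect_equal(sub$q, fdr_bh(sub$p)$q)
  }

  collection$empty <- character(0)
  expect_warning(res2 <- enrich_collection(queries, collection, bg),
                 "empty annotation sets")
  expect_equal(nrow(res2), 4 * 7)
})

test_that("planted causal enrichment is detected end to end", {
  # strong-coupling configuration: the screen recovers causal genes, and the
  # recovered set is enriched in the planted causal annotation
  sim <- gen_expression(210, 600, 150, 1, 0.5, seed = 51)
  subj <- gen_subjects(200, 200, sim$truth$gradient, rho_func = -0.8,
                       rho_gmv = 0.6, seed = 52)
  em <- effect_size_map(subj$measures$ALFF, "ALFF")
  target <- setNames(em$d, em$region)[rownames(sim$expression)]
  tab <- gene_correlates(sim$expression, target, "ALFF-d")
  sel <- select_significant(tab)
  recovered <- c(sel$positive, sel$negative)
  expect_gt(length(recovered), 10)
  row <- fisher_enrich(recovered, sim$truth$causal_genes, tab$gene,
                       "recovered", "planted-causal")
  expect_lt(fdr_bh(row$p)$q, 0.05)
  expect_gt(row$odds_ratio, 1)
})
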