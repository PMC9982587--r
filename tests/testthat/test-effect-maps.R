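test_that("residualization removes covariate signal exactly", {
  set.seed(2)
  n <- 80
  tab <- make_subject_table(rep(c("case", "control"), each = n / 2),
                            list(r1 = rnorm(n), r2 = rnorm(n)),
                            age = runif(n, 18, 65), sex = rbinom(n, 1, 0.5),
                            education = sample(6:22, n, TRUE),
                            motion = rlnorm(n, -2, 0.5))
  tab$r1 <- tab$r1 + 0.05 * tab$age # planted age effect
  res <- residualize(tab)
  for (cv in c("age", "sex", "education", "motion")) {
    expect_lt(abs(cor(res$r1, res[[cv]])), 1e-10)
    expect_lt(abs(cor(res$r2, res[[cv]])), 1e-10)
  }
  # rank-deficient design rejected with the offending column named
  bad <- tab
  bad$motion <- bad$age
  expect_error(residualize(bad), "rank deficient")
})

test_that("pooled two-sample t matches hand and reference computations", {
  tab <- make_subject_table(rep(c("case", "control"), each = 3),
                            list(rA = c(1, 2, 3, 4, 5, 6)))
  tt <- case_control_t(tab)
  # hand computation: pooled sd = 1, se = sqrt(2/3) = 0.8165, df = 4
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)

  # label swap flips the sign exactly
  sw <- tab
  sw$group <- ifelse(sw$group == "case", "control", "case")
  expect_equal(case_control_t(sw)$t, -tt$t)

  # reference: stats::t.test on random data, pooled and Welch
  set.seed(9)
  y <- rnorm(30)
  g <- rep(c("case", "control"), each = 15)
  rt <- make_subject_table(g, list(rX = y))
  ref <- t.test(y[g == "case"], y[g == "control"], var.equal = TRUE)
  expect_equal(case_control_t(rt)$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(case_control_t(rt)$p, ref$p.value, tolerance = 1e-12)
  refw <- t.test(y[g == "case"], y[g == "control"])
  expect_equal(case_control_t(rt, welch = TRUE)$t, unname(refw$statistic),
               tolerance = 1e-12)
  expect_equal(case_control_t(rt, welch = TRUE)$p, refw$p.value,
               tolerance = 1e-12)

  const <- make_subject_table(g, list(rC = rep(1, 30)))
  expect_error(case_control_t(const), "rC")
})

test_that("t to Cohen's d conversion and sign agreement", {
  expect_equal(t_to_d(2, 50, 50), 0.4)
  expect_equal(t_to_d(0, 10, 12), 0)
  set.seed(4)
  t_vec <- rnorm(50)
  expect_true(all(sign(t_to_d(t_vec, 20, 25)) == sign(t_vec)))
})

test_that("BH correction follows the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up oracle computed by hand: compare p_(i) to i/4 * 0.05
  out <- fdr_bh(p)
  expect_true(all(out$significant))
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.04))

  expect_false(any(fdr_bh(rep(1, 6))$significant))

  set.seed(3)
  p2 <- runif(40)
  perm <- sample(40)
  expect_equal(fdr_bh(p2)$q[perm], fdr_bh(p2[perm])$q)
  expect_error(fdr_bh(c(0.5, 0)), "p values")
})

test_that("funcPC1 of stacked effect maps behaves as a first component", {
  set.seed(11)
  m <- rnorm(100)
  ident <- cbind(a = m, b = m, c = m)
  rownames(ident) <- paste0("r", 1:100)
  pc <- pc1_of_effects(ident)
  expect_equal(pc$var_explained, 1)
  expect_equal(unname(pc$scores), as.numeric(scale(m)), tolerance = 1e-12)

  # orthogonal maps: variance explained near isotropy (1/3)
  ortho <- matrix(rnorm(3000), ncol = 3)
  ve <- pc1_of_effects(ortho)$var_explained
  expect_gt(ve, 0.30); expect_lt(ve, 0.45)

  # sign convention: positive correlation with the mean input map
  set.seed(12)
  maps <- matrix(rnorm(300), ncol = 3) + rnorm(100)
  pc2 <- pc1_of_effects(maps)
  expect_gt(cor(pc2$scores, rowMeans(scale(maps))), 0)

  expect_warning(pc1_of_effects(cbind(m, rep(1, 100), m + rnorm(100))),
                 "constant columns") # constant map dropped, not fatal
})

test_that("genePC1 is invariant to duplicating gene columns", {
  sim <- gen_expression(50, 60, 20, 1, 0.5, seed = 6)
  X <- sim$expression
  pc <- pc1_of_expression(X)
  dup <- cbind(X, X)
  colnames(dup) <- make.unique(colnames(dup))
  pc_dup <- pc1_of_expression(dup)
  expect_equal(pc_dup$scores, pc$scores, tolerance = 1e-8)

  Xz <- cbind(X, flat = rep(1, nrow(X)))
  expect_warning(pc1_of_expression(Xz), "constant columns")
})

test_that("effect_size_map chains the stages coherently", {
  sim <- gen_expression(40, 20, 5, 1, 0.5, seed = 3)
  subj <- gen_subjects(60, 60, sim$truth$gradient, seed = 5)
  em <- effect_size_map(subj$measures$ALFF, measure = "ALFF")
  expect_named(em, c("region", "t", "d", "p", "q", "significant", "measure"))
  expect_true(all(sign(em$d) == sign(em$t)))
  expect_true(all(em$p > 0 & em$p <= 1 & em$q <= 1))
})
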