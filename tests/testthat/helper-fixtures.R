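# Small fixtures and independent oracles used across test files.

# subject table with explicit values; measures is a named list of
# per-region numeric vectors (one value per subject)
make_subject_table <- function(group, measures, age = NULL, sex = NULL,
                               education = NULL, motion = NULL) {
  n <- length(group)
  df <- data.frame(
    subject = sprintf("s%02d", seq_len(n)),
    group = group,
    age = age %||% rep(30, n),
    sex = sex %||% rep(0:1, length.out = n),
    education = education %||% rep(12, n),
    motion = motion %||% rep(0.1, n),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(measures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of seq_len(n), rows of a matrix (oracle helper)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact permutation-null two-sided p for Spearman's rho (oracle)
exact_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  perms <- all_perms(n)
  rs <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# hypergeometric upper-tail by direct enumeration with choose() (oracle)
enum_hyper_p <- function(a, n_query, n_anno, n_bg) {
  ks <- seq(a, min(n_query, n_anno))
  if (length(ks) == 0) return(1)
  sum(choose(n_anno, ks) * choose(n_bg - n_anno, n_query - ks)) /
    choose(n_bg, n_query)
}

# tiny probe-sample data.frame built by hand
make_probe_df <- function(donor, sample, region, probe, gene, intensity,
                          above_background = TRUE) {
  data.frame(donor = donor, sample = sample, region = region, probe = probe,
             gene = gene, intensity = intensity,
             above_background = above_background, stringsAsFactors = FALSE)
}
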