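# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_(sprintf("`%s` must be > 0", name))
  if (x < lower || x > upper)
    stop_(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  if (integer && x != round(x))
    stop_(sprintf("`%s` must be an integer", name))
  invisible(x)
}

# z-scale a vector; errors on zero spread unless allow_constant
zscale <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop_("cannot z-scale a constant vector")
  }
  (x - mean(x)) / s
}

# Pearson correlation that reproduces a target Spearman coupling for
# bivariate Gaussian data: rho_s = (6/pi) asin(rho_p / 2).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Column-wise ranks of a matrix (average ranks for ties).
col_ranks <- function(X) {
  matrix(apply(X, 2L, rank, ties.method = "average"),
         nrow = nrow(X), dimnames = dimnames(X))
}

# Draw a vector coupled to `base` (z-scaled) at Spearman-scale `rho_s`
# via the Gaussian closed form; result is z-scaled.
couple_to <- function(base, rho_s) {
  rho_p <- spearman_to_pearson(rho_s)
  raw <- rho_p * base + sqrt(1 - rho_p^2) * stats::rnorm(length(base))
  zscale(raw)
}

# left-pad ids like g0007, r012
pad_id <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), i)
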