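# Internal helpers: deterministic seed substreams and small numerics.

# Deterministic 31-bit substream seed from a master seed and a stream name,
# so trial generation, weight draws, spike draws and each decoder repeat
# consume independent, individually reproducible RNG streams.
substream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% 2147483647
  as.integer(((master %% 2147483647) * 48271 + h + 1) %% 2147483647)
}

with_substream <- function(master, name, expr) {
  set.seed(substream_seed(master, name))
  expr
}

# z-score a vector; zero-variance input maps to all zeros.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Vectorized Pearson correlation of each row of `m` with `y`, with two-sided
# p-values from the t distribution. Zero-variance rows give NA.
row_cor_test <- function(m, y) {
  n <- length(y)
  stopifnot(ncol(m) == n, n >= 3)
  ys <- y - mean(y)
  ssy <- sum(ys^2)
  mc <- m - rowMeans(m)
  ssm <- rowSums(mc^2)
  r <- as.vector(mc %*% ys) / sqrt(ssm * ssy)
  bad <- ssm == 0 | ssy == 0 | !is.finite(r)
  r[bad] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}
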