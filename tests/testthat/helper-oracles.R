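# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force double-sum convolution of two mass-shift distributions.
conv_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# Mass-shift distribution of a partly gluconeogenic fragment by explicit
# enumeration over all 2^n site configurations (no dbinom).
label_dist_enum <- function(p_water, fgng_true, n_sites = 6) {
  shifts <- numeric(n_sites + 1L)
  for (cfg in 0:(2^n_sites - 1L)) {
    bits <- as.integer(intToBits(cfg))[seq_len(n_sites)]
    k <- sum(bits)
    shifts[k + 1L] <- shifts[k + 1L] +
      prod(ifelse(bits == 1L, p_water, 1 - p_water))
  }
  out <- fgng_true * shifts
  out[1] <- out[1] + (1 - fgng_true)
  out
}

# Textbook OLS closed form.
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Balanced two-way ANOVA by direct cell-means decomposition (equal n only).
balanced_anova_oracle <- function(records, response = "fgng") {
  y <- records[[response]]
  fa <- factor(records$feeding); fb <- factor(records$injury)
  g <- mean(y)
  ma <- tapply(y, fa, mean); mb <- tapply(y, fb, mean)
  mc <- tapply(y, interaction(fa, fb), mean)
  n_cell <- unique(table(fa, fb))
  stopifnot(length(n_cell) == 1)
  ss_a <- n_cell * nlevels(fb) * sum((ma - g)^2)
  ss_b <- n_cell * nlevels(fa) * sum((mb - g)^2)
  cell_of <- interaction(fa, fb)
  ss_res <- sum((y - mc[cell_of])^2)
  ss_tot <- sum((y - g)^2)
  c(feeding = ss_a, injury = ss_b,
    interaction = ss_tot - ss_a - ss_b - ss_res, residual = ss_res)
}

# Construct a vector with exactly the requested mean and sd (n >= 2).
exact_moments <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}
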