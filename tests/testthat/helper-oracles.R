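# independent numerical oracles used across the suite

# j1 by direct series summation: j1(x) = sum_{n>=1} (-1)^(n+1) 2n x^(2n-1) / (2n+1)!
# (derived termwise from the sin/cos Taylor series, summed to machine precision)
j1_series <- function(x, n_terms = 25) {
  total <- 0
  for (n in seq_len(n_terms)) {
    total <- total + (-1)^(n + 1) * 2 * n * x^(2 * n - 1) /
      factorial(2 * n + 1)
  }
  total
}

# type-7 (linear interpolation) quantile by explicit sort and index
# arithmetic, independent of stats::quantile
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Pearson r by the definitional sums of products
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# spherical vesicle intensity recomposed term by term (volumes, contrast,
# closed-form j1) without reusing the package's evaluation path
vesicle_oracle <- function(q, phi, r_c, shell, sld_shell, sld_solvent, b) {
  r_t <- r_c + shell
  v_c <- 4 / 3 * pi * r_c^3
  v_t <- 4 / 3 * pi * r_t^3
  v_sh <- v_t - v_c
  j1 <- function(x) (sin(x) - x * cos(x)) / x^2
  term1 <- 3 * v_c * (sld_solvent - sld_shell) * j1(q * r_c) / (q * r_c)
  term2 <- 3 * v_t * (sld_shell - sld_solvent) * j1(q * r_t) / (q * r_t)
  phi / v_sh * (term1 + term2)^2 + b
}
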