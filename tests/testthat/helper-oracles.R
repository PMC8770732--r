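# Independent brute-force oracles: plain accumulation loops, no shared code
# with the package implementations they check.

oracle_mad <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i])
  s / length(x)
}

oracle_see <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / (length(x) - 2))
}

oracle_pcp <- function(x, y, threshold) {
  k <- 0
  for (i in seq_along(x)) if (abs(x[i] - y[i]) <= threshold) k <- k + 1
  100 * k / length(x)
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  (sxy / sqrt(sxx * syy))^2
}

# exhaustive two-sided rank-sum p-value for small samples without ties
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- sum(rank(pooled)[seq_along(a)])
  combos <- utils::combn(n, length(a))
  sums <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- mean(sums)
  min(1, mean(abs(sums - mu) >= abs(obs - mu)))
}

# random paired-age instance
random_pairs <- function(n = sample(3:200, 1)) {
  x <- runif(n, 0, 101)
  list(x = x, y = x + rnorm(n, 0, runif(1, 0.5, 15)))
}

# samples table written to a temp CSV
write_sample_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

noiseless_sites <- function(...) {
  lapply(default_site_models(...), function(s) {
    s$noise_sd <- 0
    s
  })
}
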