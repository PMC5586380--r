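# Independent brute-force oracles used across tests. Each recomputes a
# quantity by the most literal route available, with no shared code paths
# with the implementation.

# per-base average rate over [from, to): expand the map to one value per bp
per_bp_mean_oracle <- function(map, from, to) {
  bp <- from:(to - 1)
  val <- rep(NA_real_, length(bp))
  for (i in seq_along(map$rates)) {
    inside <- bp >= map$positions[i] & bp < map$positions[i + 1]
    val[inside] <- map$rates[i]
  }
  mean(val, na.rm = TRUE)
}

# all-pairs interval overlap scan (half-open)
overlap_count_oracle <- function(a, b) {
  hits <- 0L
  for (j in seq_len(nrow(b))) {
    for (i in seq_len(nrow(a))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# Gini as normalized mean absolute pairwise difference (equal-length bins)
gini_pairwise_oracle <- function(rates) {
  n <- length(rates)
  sum(abs(outer(rates, rates, "-"))) / (2 * n^2 * mean(rates))
}

# exact HWE distribution by direct multinomial coefficients (factorials),
# independent of the implementation's log-space recurrence
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(list(p_value = 1, probs = 1))
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  w <- vapply(hs, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- N - h - hom_minor
    factorial(N) / (factorial(hom_minor) * factorial(h) *
                      factorial(hom_major)) * 2^h
  }, numeric(1))
  probs <- w / sum(w)
  obs <- probs[match(n_Aa, hs)]
  list(p_value = sum(probs[probs <= obs * (1 + 1e-12)]), probs = probs)
}

# O(n^2) tie-corrected Kendall tau
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- choose(n, 2)
  tx <- sum(choose(table(x), 2))
  ty <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# random valid rho map for round-trip / property tests
random_rho_map <- function(n_int = 10, chrom = "chrR") {
  pos <- cumsum(c(sample(1:500, 1), sample(1:200, n_int, replace = TRUE)))
  rho_map(chrom, pos, stats::rgamma(n_int, 2, rate = 200))
}
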