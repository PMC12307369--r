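# independent Kruskal-Wallis H from the textbook rank formula (with tie
# correction), used as the oracle for the packaged test
kw_h_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  rk <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, groups, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

exact_kw_p <- function(values, sizes) {
  # exhaustive permutation distribution of H over all group assignments
  n <- length(values)
  stopifnot(sum(sizes) == n)
  labs <- rep(seq_along(sizes), sizes)
  h_obs <- kw_h_oracle(values, labs)
  idx_all <- seq_len(n)
  count <- 0L; total <- 0L
  for (a in utils::combn(idx_all, sizes[1], simplify = FALSE)) {
    rest <- setdiff(idx_all, a)
    for (b in utils::combn(rest, sizes[2], simplify = FALSE)) {
      cc <- setdiff(rest, b)
      g <- integer(n); g[a] <- 1L; g[b] <- 2L; g[cc] <- 3L
      h <- kw_h_oracle(values, g)
      total <- total + 1L
      if (h >= h_obs - 1e-9) count <- count + 1L
    }
  }
  count / total
}

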