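# Independent oracles shared by the unit and acceptance tests. These are
# deliberately simple (exhaustive or quadratic) re-implementations that never
# share code with the package internals they check.

# all permutations of a small vector (n! lists; keep n <= 8)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Mann-Kendall S by direct pairwise signs
S_oracle <- function(x) {
  n <- length(x)
  sum(sign(outer(x, x, "-"))[lower.tri(matrix(0, n, n))])
}

# exact O(n^2) dynamic program for the penalised-SSE changepoint objective
dp_changepoints <- function(x, beta, min_seglen = 2) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / (j - i + 1)
  F <- c(-beta, rep(Inf, n)); prev <- integer(n + 1)
  for (t in seq_len(n)) {
    for (s in 0:(t - 1)) {
      if (t - s < min_seglen) next
      if (s > 0 && is.infinite(F[s + 1])) next
      v <- F[s + 1] + sse(s + 1, t) + beta
      if (v < F[t + 1]) { F[t + 1] <- v; prev[t + 1] <- s }
    }
  }
  cps <- integer(0); t <- n
  while (t > 0) { s <- prev[t + 1]; if (s > 0) cps <- c(s, cps); t <- s }
  list(cps = cps, cost = F[n + 1])
}
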