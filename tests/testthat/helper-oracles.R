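# Independent oracles: brute-force / enumeration implementations kept
# deliberately separate from the package's code paths.

# direct summation Shannon entropy
entropy_oracle <- function(freq) {
  p <- freq[freq > 0]
  p <- p / sum(p)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

# brute-force pairwise Gini
gini_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings:
# p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|) under the permutation null
mwu_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(xi, yi) sum(outer(xi, yi, ">")) # ties absent by design
  u_obs <- u_of(a, b)
  labelings <- utils::combn(n1 + n2, n1)
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  hits <- 0
  for (k in seq_len(ncol(labelings))) {
    ia <- labelings[, k]
    u <- u_of(pool[ia], pool[-ia])
    if (abs(u - n1 * n2 / 2) >= dev_obs - 1e-12) hits <- hits + 1
  }
  list(u = u_obs, p = hits / ncol(labelings))
}

# full (unbanded) affine-gap Smith-Waterman score, O(mn) dynamic
# programming; gap of length L costs open + (L-1) * extend
sw_full_oracle <- function(query, ref, match = 2, mismatch = -2,
                           gap_open = -5, gap_extend = -2) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  m <- length(q); n <- length(r)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      s <- if (q[i - 1] == r[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# one-sample KS D against the normal fitted by sample mean/sd, computed
# straight from the ECDF-vs-Phi definition
ks_D_oracle <- function(x) {
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  phi <- pnorm(z)
  max(abs(seq_len(n) / n - phi), abs((seq_len(n) - 1) / n - phi))
}

# hash-style public-clonotype counter independent of public_clonotypes():
# counts keys observed in >= 2 distinct samples via an environment
public_count_oracle <- function(sample_ids, keys) {
  env <- new.env(hash = TRUE)
  for (i in seq_along(keys)) {
    seen <- get0(keys[i], envir = env, ifnotfound = character(0))
    assign(keys[i], union(seen, sample_ids[i]), envir = env)
  }
  sum(vapply(ls(env), function(k) length(get(k, envir = env)) >= 2,
             logical(1)))
}
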