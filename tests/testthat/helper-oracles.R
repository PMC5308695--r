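# Independent oracles: deliberately simple re-implementations used only to
# check the package's optimised code paths.

# exhaustive Smith-Waterman score (no traceback), flat indel penalty
sw_oracle_score <- function(read, window, match = 10, mismatch = -8,
                            indel = -9) {
  r <- strsplit(read, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(r); n <- length(w)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (r[i] == w[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + indel,
                             H[i + 1, j] + indel)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# brute-force approximate matcher: all positions of query in ref with at
# most max_mm substitutions
fm_oracle <- function(ref, query, max_mm = 0L) {
  n <- nchar(ref); k <- nchar(query)
  qs <- strsplit(query, "")[[1]]
  hits <- integer(0)
  for (s in 0:(n - k)) {
    mm <- sum(strsplit(substr(ref, s + 1, s + k), "")[[1]] != qs)
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic
# (untied data), enumerating all assignments of the combined sample
mwu_perm_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) {
    r <- rank(pool)
    sum(r[ii]) - m * (m + 1) / 2
  })
  r <- rank(pool)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
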