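# Exact combinatorial oracle for the hypergeometric distribution.
#
# Independent of the package's tail functions: binomial coefficients come
# from an integer Pascal-triangle recursion, which is exact in doubles for
# M <= 30 (the largest value involved, C(30,15) = 155117520, is far below
# 2^53), so pmf and tail sums are exact rational arithmetic up to one final
# division.

oracle_binom_table <- function(M) {
  C <- matrix(0, M + 1L, M + 1L)
  C[, 1L] <- 1
  for (i in seq_len(M) + 1L) {
    for (j in 2:i) C[i, j] <- C[i - 1L, j - 1L] + C[i - 1L, j]
  }
  C  # C[n+1, k+1] == choose(n, k)
}

oracle_choose <- function(C, n, k) {
  if (k < 0 || k > n) return(0)
  C[n + 1L, k + 1L]
}

# full pmf vector over k = 0..min(n, N)
oracle_pmf_vector <- function(M, n, N) {
  C <- oracle_binom_table(M)
  denom <- oracle_choose(C, M, N)
  vapply(0:min(n, N), function(k) {
    oracle_choose(C, n, k) * oracle_choose(C, M - n, N - k) / denom
  }, numeric(1))
}

oracle_pmf <- function(M, n, N, k) {
  v <- oracle_pmf_vector(M, n, N)
  if (k < 0 || k > min(n, N)) 0 else v[k + 1L]
}

# k-inclusive tails
oracle_p_enrich <- function(M, n, N, k) {
  v <- oracle_pmf_vector(M, n, N)
  if (k <= 0) 1 else if (k > min(n, N)) 0 else sum(v[(k + 1L):length(v)])
}

oracle_p_deplete <- function(M, n, N, k) {
  v <- oracle_pmf_vector(M, n, N)
  if (k < 0) 0 else sum(v[seq_len(min(k, min(n, N)) + 1L)])
}
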