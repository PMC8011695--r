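# Independent brute-force oracles used across the test files.

# all compositions of n into k nonnegative parts
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (y in 0:n) {
    sub <- compositions(n - y, k - 1)
    out <- rbind(out, cbind(y, sub))
  }
  unname(out)
}

# neg-crossentropy by full enumeration of the multinomial outcome space
enum_neg_crossentropy <- function(pi_r, pi_s, n) {
  ys <- compositions(n, length(pi_r))
  lp <- function(y, p) {
    if (any(y > 0 & p == 0)) return(-Inf)
    pos <- y > 0
    lgamma(n + 1) - sum(lgamma(y + 1)) + sum(y[pos] * log(p[pos]))
  }
  tot <- 0
  for (i in seq_len(nrow(ys))) {
    y <- ys[i, ]
    pr <- exp(lp(y, pi_r))
    if (pr > 0) tot <- tot + pr * lp(y, pi_s)
  }
  tot
}

# random probability vector
rand_pi <- function(k) {
  x <- stats::rexp(k) + 1e-3
  x / sum(x)
}

# run the full geometry pipeline on a planar Gaussian ensemble
planar_pipeline <- function(ens, mode = "ordinal") {
  tb <- ensemble_entropy_table(ens)
  emb <- nmds(symmetrized_kl_matrix(tb), d = 2, mode = mode)
  proj <- project_generating_process(emb, tb$sgg, tb$sgfi)
  list(table = tb, emb = emb, proj = proj)
}
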