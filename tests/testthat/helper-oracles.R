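# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Upper-tail hypergeometric P(X >= k) by direct summation of binomials.
enum_hyper_upper <- function(k, n_a, n_b, M) {
  if (k > min(n_a, n_b)) return(0)
  xs <- max(k, max(0L, n_a + n_b - M)):min(n_a, n_b)
  sum(exp(lchoose(n_a, xs) + lchoose(M - n_a, n_b - xs) - lchoose(M, n_b)))
}

# Two-tailed Fisher p by enumerating the whole support with fixed margins.
enum_fisher_two_tailed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive sliding-window motif counter over allowed-base sets.
naive_motif_count <- function(seq, position_sets) {
  chars <- strsplit(toupper(seq), "")[[1]]
  k <- length(position_sets)
  n <- length(chars)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(chars[i + j - 1] %in% position_sets[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

rrach_sets <- list(c("A", "G"), c("A", "G"), "A", "C", c("A", "C", "T"))

# Manual BH step-up.
manual_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided rank-sum p by enumerating which ranks the first sample got.
enum_wilcoxon_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  all_w <- apply(combn(nx + ny, nx), 2, function(idx) {
    sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2
  })
  p_lower <- mean(all_w <= w_obs)
  p_upper <- mean(all_w >= w_obs)
  min(1, 2 * min(p_lower, p_upper))
}

random_dna <- function(n, len, p = c(.25, .25, .25, .25)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}
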