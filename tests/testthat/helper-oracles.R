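# Independent oracles: brute-force path enumeration for HMM likelihood and
# best-path score. Deliberately written in plain R, separate from the
# package's scaled recursions.

enum_paths <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# total likelihood by summing over all K^T state paths
brute_force_likelihood <- function(pi, A, B, obs1) {
  T <- length(obs1)
  paths <- enum_paths(length(pi), T)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    w <- pi[s[1]] * B[s[1], obs1[1]]
    if (T > 1) for (t in 2:T) w <- w * A[s[t - 1], s[t]] * B[s[t], obs1[t]]
    total <- total + w
  }
  total
}

# max log path score, accumulating terms left to right exactly as the
# Viterbi recursion does, so a matching implementation agrees bit for bit
brute_force_best_path <- function(pi, A, B, obs1) {
  T <- length(obs1)
  paths <- enum_paths(length(pi), T)
  best <- -Inf
  lpi <- log(pi); lA <- log(A); lB <- log(B)
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    sc <- lpi[s[1]] + lB[s[1], obs1[1]]
    if (T > 1) for (t in 2:T) sc <- sc + lA[s[t - 1], s[t]] + lB[s[t], obs1[t]]
    if (sc > best) best <- sc
  }
  best
}

# log score of one specific 1-based path, same accumulation order
path_log_score <- function(pi, A, B, obs1, s) {
  sc <- log(pi[s[1]]) + log(B[s[1], obs1[1]])
  if (length(obs1) > 1)
    for (t in 2:length(obs1))
      sc <- sc + log(A[s[t - 1], s[t]]) + log(B[s[t], obs1[t]])
  sc
}

# random stochastic HMM via normalised gamma draws
random_hmm <- function(K, V, seed) {
  set.seed(seed)
  norm_rows <- function(m) m / rowSums(m)
  pi <- stats::rgamma(K, 1) + 0.05
  pi <- pi / sum(pi)
  A <- norm_rows(matrix(stats::rgamma(K * K, 1) + 0.05, K, K))
  B <- norm_rows(matrix(stats::rgamma(K * V, 1) + 0.05, K, V))
  hmm_params(pi, A, B)
}

random_obs <- function(V, T, seed) {
  set.seed(seed)
  sample.int(V, T, replace = TRUE) - 1L
}

# stationary distribution of a transition matrix (left eigenvector)
stationary_dist <- function(A) {
  e <- eigen(t(A))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# construct a correlation_profile object directly for onset-rule tests
make_profile <- function(hour, r, n_pairs = rep(10L, length(hour))) {
  out <- data.frame(hour = hour, r = r, n_pairs = n_pairs)
  class(out) <- c("correlation_profile", "data.frame")
  out
}
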