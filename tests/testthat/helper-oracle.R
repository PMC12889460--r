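# Independent brute-force oracle: posterior marginals and log-likelihood
# by exhaustive enumeration of all K^T state paths.  Shares no code with
# the scaled forward-backward implementation.
oracle_fb <- function(model, codes) {
  K <- model$K
  T_ <- nrow(codes)
  B <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (s in seq_len(K)) {
      B[t, s] <- prod(ifelse(codes[t, ] == 2, 1,
                             ifelse(codes[t, ] == 1, model$emission[s, ],
                                    1 - model$emission[s, ])))
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  probs <- apply(paths, 1L, function(s) {
    p <- model$initial[s[1]] * B[1, s[1]]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * model$transition[s[t - 1], s[t]] * B[t, s[t]]
    }
    p
  })
  total <- sum(probs)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) {
      gamma[t, k] <- sum(probs[paths[, t] == k]) / total
    }
  }
  list(gamma = gamma, loglik = log(total))
}

# Random valid model / ternary sequence, drawn from the session RNG.
rand_model <- function(K, M) {
  init <- rgamma(K, 1); init <- init / sum(init)
  A <- matrix(rgamma(K * K, 1), K, K); A <- A / rowSums(A)
  hmm_model(init, A, matrix(runif(K * M, 0.05, 0.95), K, M))
}

rand_codes <- function(T_, M, missing_prob = 0.2) {
  matrix(sample(c(0L, 1L, 2L), T_ * M, replace = TRUE,
                prob = c((1 - missing_prob) / 2, (1 - missing_prob) / 2,
                         missing_prob)),
         T_, M)
}

# Best assignment score by brute-force enumeration of all permutations
# (independent check of the Hungarian matcher).
brute_best_perm <- function(score) {
  n <- nrow(score)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  vals <- apply(perms, 1L, function(p) {
    sum(score[cbind(seq_len(n), p)])
  })
  list(value = max(vals), perm = perms[which.max(vals), ])
}

# Small labeled/gene-structured fixture reused across annotate tests.
small_sim <- function(K = 3, M = 6, n_genes = 12, positions = 25,
                      stickiness = 0.8, seed = 42) {
  model <- simulate_model(K, M, stickiness = stickiness, seed = seed)
  simulate_dataset(model, n_genes = n_genes,
                   positions_per_gene = positions,
                   missing_rate = 0.05, Q = 20, seed = seed + 1)
}
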