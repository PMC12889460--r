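# Self-contained synthetic fixtures with known ground truth: a separable
# ground-truth model, a variant table whose scores binarize back to the
# simulated codes, interval annotations with designed enrichment, and
# labels/DMS measurements with known state effects.

#' Simulate a separable ground-truth model
#'
#' Draws a `varhmm` model whose states are distinguishable from data:
#' the features are randomly partitioned round-robin across states, each
#' state emitting its own features with high probability (uniform on
#' `(0.7, 0.9)`) and the rest with low probability (uniform on
#' `(0.02, 0.08)`), plus occasional extra high features (probability 0.15
#' each).  The partition guarantees every feature has at least one
#' high-emission state and keeps emission rows weakly correlated.
#' Transitions put `stickiness` mass on the diagonal and spread the rest
#' uniformly; `stickiness = 1/K` gives the uniform transition matrix.
#' The initial distribution is uniform.
#'
#' @param K,M numbers of states and score features.
#' @param stickiness diagonal transition mass in `(0, 1)`.
#' @param seed integer seed; the same seed gives the identical model.
#' @return A `varhmm` model.
#' @export
simulate_model <- function(K, M, stickiness = 0.7, seed = 1L) {
  if (stickiness <= 0 || stickiness >= 1) {
    stop("stickiness must lie in (0, 1)")
  }
  with_seed(seed, {
    owner <- (sample.int(M) - 1L) %% K + 1L  # feature -> base state
    # redraw the extra-feature pattern until no two states share an
    # emission profile (pairwise Pearson < 0.8); usually first try
    for (attempt in 1:50) {
      emission <- matrix(0, K, M)
      for (s in seq_len(K)) {
        high <- owner == s
        extra <- !high & runif(M) < 0.15
        emission[s, high | extra] <- runif(sum(high | extra), 0.7, 0.9)
        emission[s, !(high | extra)] <-
          runif(sum(!(high | extra)), 0.02, 0.08)
      }
      if (K == 1L) break
      cc <- suppressWarnings(cor(t(emission)))
      if (max(cc[upper.tri(cc)], na.rm = TRUE) < 0.8) break
    }
    transition <- matrix(if (K > 1L) (1 - stickiness) / (K - 1L) else 1,
                         K, K)
    diag(transition) <- stickiness
    hmm_model(rep(1 / K, K), transition, emission)
  })
}

#' Simulate a scored variant table from a ground-truth model
#'
#' Per gene, a hidden state path is drawn from the Markov chain, one
#' state per genomic position.  Each position hosts `alts_per_position`
#' variant rows sharing the position's state; each row draws its own
#' Bernoulli "present" bits from the state's emission probabilities.
#' Scores are then generated so that [binarize()] at the configured `Q`
#' reproduces the bits exactly: "present" cells share the column maximum
#' (1.0, the saturated top of a rank-scaled score, whose tie-at-max rule
#' the binarizer handles) and "absent" cells are uniform below a band gap
#' at `1 - Q/100`.  Exact reproduction requires each column's realized
#' present count to reach `ceiling(Q/100 * n)`, which holds whenever every
#' feature has a high-emission state and `Q`% is below the feature's
#' marginal present rate; a warning is raised otherwise.  Missing cells
#' (probability `missing_rate`) get an `NA` score and code 2.
#'
#' @param model a `varhmm` ground-truth model (e.g. [simulate_model()]).
#' @param n_genes number of genes.
#' @param positions_per_gene positions per gene: a constant, a vector to
#'   sample from, or a function of one argument (the number of genes).
#' @param alts_per_position alternate alleles per position: a constant or
#'   a vector from `{1, 2, 3}` sampled per position.
#' @param missing_rate per-cell probability of a missing score.
#' @param Q binarization top-percent (kept with the dataset so encoding
#'   and generation agree).
#' @param seed integer seed.
#' @return A list of class `varstates_sim`: `table` (variant table with
#'   score columns `S1..SM`), `codes` (ternary matrix aligned to the
#'   table), `states` (true state per row), `bits` (latent 0/1 presence
#'   matrix before missingness), `model`, `Q`.
#' @export
simulate_dataset <- function(model, n_genes = 300L, positions_per_gene = 80L,
                             alts_per_position = 1:3, missing_rate = 0.1,
                             Q = 10, seed = 1L) {
  validate_hmm(model)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (!all(alts_per_position %in% 1:3)) {
    stop("alts_per_position must be in {1, 2, 3}")
  }
  M <- model$M
  nucs <- c("A", "C", "G", "T")
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  with_seed(seed, {
    npos <- if (is.function(positions_per_gene)) {
      positions_per_gene(n_genes)
    } else if (length(positions_per_gene) == 1L) {
      rep(positions_per_gene, n_genes)
    } else {
      sample(positions_per_gene, n_genes, replace = TRUE)
    }
    genes <- sprintf("G%04d", seq_len(n_genes))
    chroms <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
    tabs <- vector("list", n_genes)
    states_all <- vector("list", n_genes)
    bits_all <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      T_ <- npos[g]
      path <- simulate(model, n_positions = T_, seed = NULL)$states
      offset <- ((g - 1L) %/% 22L) * 1e6
      pos <- offset + sort(sample.int(3L * T_ + 10L, T_)) * 3L
      n_alt <- if (length(alts_per_position) == 1L) {
        rep(alts_per_position, T_)
      } else {
        sample(alts_per_position, T_, replace = TRUE)
      }
      row_pos <- rep(pos, n_alt)
      row_state <- rep(path, n_alt)
      nr <- length(row_pos)
      ref <- rep(sample(nucs, T_, replace = TRUE), n_alt)
      alt <- unlist(lapply(seq_len(T_), function(i) {
        sample(setdiff(nucs, ref[match(pos[i], row_pos)]), n_alt[i])
      }))
      aaref <- rep(sample(aas, T_, replace = TRUE), n_alt)
      aaalt <- vapply(seq_len(nr), function(i) {
        sample_one(setdiff(aas, aaref[i]))
      }, character(1))
      p <- model$emission[row_state, , drop = FALSE]
      bits <- matrix(as.integer(runif(nr * M) < p), nr, M)
      tabs[[g]] <- data.frame(
        chrom = chroms[g], pos = row_pos, ref = ref, alt = alt,
        gene = genes[g], aaref = aaref, aaalt = aaalt,
        stringsAsFactors = FALSE)
      states_all[[g]] <- row_state
      bits_all[[g]] <- bits
    }
    table <- do.call(rbind, tabs)
    states <- unlist(states_all)
    bits <- do.call(rbind, bits_all)
    n <- nrow(table)
    # scores consistent with the binarizer: present cells share the
    # column maximum, absent cells sit below a band gap
    band <- 1 - Q / 100
    scores <- matrix(runif(n * M, 0, band - 0.02), n, M)
    scores[bits == 1L] <- 1
    miss <- matrix(runif(n * M) < missing_rate, n, M)
    scores[miss] <- NA_real_
    codes <- bits
    codes[miss] <- 2L
    colnames(scores) <- paste0("S", seq_len(M))
    colnames(codes) <- colnames(scores)
    present <- colSums(codes == 1L)
    needed <- ceiling(Q / 100 * colSums(codes != 2L))
    if (any(present < needed)) {
      warning("some score columns have fewer present codes than the top-",
              Q, "% cutoff; binarize() will not reproduce them exactly")
    }
    structure(list(table = cbind(table, as.data.frame(scores)),
                   codes = codes, states = states, bits = bits,
                   model = model, Q = Q),
              class = "varstates_sim")
  })
}

#' @export
print.varstates_sim <- function(x, ...) {
  cat("Synthetic variant dataset: ", nrow(x$table), " variants, ",
      length(unique(x$table$gene)), " genes, K = ", x$model$K,
      ", M = ", x$model$M, ", Q = ", x$Q, "\n", sep = "")
  invisible(x)
}

#' Simulate pathogenicity labels and DMS measurements with state effects
#'
#' Attaches a continuous evaluation score `score ~ U(0, 1)` to each
#' variant, then draws a binary label with probability
#' `plogis(a * (score - 0.5) + b_state[state])` and a DMS-style
#' measurement `c * score + d_state[state] + N(0, noise_sd)`.  Equal
#' `b_state` (or `d_state`) entries make the label (measurement)
#' independent of the state given the score — the null configuration for
#' the paired evaluations.
#'
#' @param table a variant table (only the key columns and `gene` are
#'   used; `gene` becomes the `protein`/`measurement` grouping).
#' @param states true state per row.
#' @param b_state,d_state per-state offsets (length `K`).
#' @param a,c_slope score coefficients for the label and measurement.
#' @param noise_sd Gaussian noise on the measurement.
#' @param seed integer seed.
#' @return A list with `labeled` (key columns, `gene`, `score`, `state`,
#'   `label`), `dms` (`protein`, `measurement`, `score`, `state`,
#'   `value`) and `effects` (the generating parameters).
#' @export
simulate_labels_and_dms <- function(table, states, b_state, d_state = b_state,
                                    a = 4, c_slope = 1, noise_sd = 0.5,
                                    seed = 1L) {
  n <- nrow(table)
  with_seed(seed, {
    score <- runif(n)
    label <- rbinom(n, 1L, plogis(a * (score - 0.5) + b_state[states]))
    value <- c_slope * score + d_state[states] + rnorm(n, 0, noise_sd)
    labeled <- data.frame(table[, c(variant_key_cols, "gene")],
                          score = score, state = states, label = label,
                          stringsAsFactors = FALSE)
    dms <- data.frame(protein = table$gene, measurement = table$gene,
                      score = score, state = states, value = value,
                      stringsAsFactors = FALSE)
    list(labeled = labeled, dms = dms,
         effects = list(a = a, b_state = b_state, c_slope = c_slope,
                        d_state = d_state, noise_sd = noise_sd))
  })
}

#' Match estimated states to ground-truth states
#'
#' HMM states are identifiable only up to relabeling, so estimated
#' parameters are compared to the truth after an optimal one-to-one state
#' matching: the permutation maximizing the summed Pearson correlation
#' between emission vectors, found by the Hungarian algorithm.  Reports
#' the mean absolute emission and transition errors under that
#' permutation.
#'
#' @param true_model,est_model `varhmm` models with equal `K` and `M`.
#' @return A list with `permutation` (`permutation[s]` is the estimated
#'   state matched to true state `s`), `emission_mae`, `transition_mae`
#'   and `initial_mae`.
#' @export
match_states <- function(true_model, est_model) {
  validate_hmm(true_model); validate_hmm(est_model)
  if (true_model$K != est_model$K) stop("models must share K")
  if (true_model$M != est_model$M) stop("models must share M")
  C <- suppressWarnings(cor(t(true_model$emission), t(est_model$emission)))
  C[!is.finite(C)] <- 0
  perm <- hungarian_max(C)
  pe <- est_model$emission[perm, , drop = FALSE]
  pa <- est_model$transition[perm, perm, drop = FALSE]
  list(permutation = perm,
       emission_mae = mean(abs(true_model$emission - pe)),
       transition_mae = mean(abs(true_model$transition - pa)),
       initial_mae = mean(abs(true_model$initial -
                              est_model$initial[perm])))
}

# Optimal assignment maximizing sum of scores: Hungarian algorithm
# (shortest augmenting path formulation with potentials, O(n^3)).
# Returns perm with perm[i] = column assigned to row i.
hungarian_max <- function(score) {
  cost <- max(score) - score
  n <- nrow(cost)
  if (n == 1L) return(1L)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) perm[p[j + 1L]] <- j
  }
  perm
}

#' Interval annotations marking the footprint of chosen states
#'
#' Builds a BED-style interval set covering the positions of variants
#' whose true state lies in `states`, optionally widened and with extra
#' noise intervals, giving enrichment tests a known expected fold.
#'
#' @param sim a [simulate_dataset()] result.
#' @param states integer vector of true states whose positions to mark.
#' @param pad bases added on each side of a marked position.
#' @param noise fraction of additional intervals placed at positions of
#'   other states.
#' @param seed integer seed for the noise draw.
#' @return A BED-style data frame (`chrom`, `start`, `end`; 0-based
#'   half-open), per-chromosome sorted.
#' @export
state_footprint_intervals <- function(sim, states, pad = 0L, noise = 0,
                                      seed = 1L) {
  tab <- sim$table
  sel <- sim$states %in% states
  with_seed(seed, {
    if (noise > 0) {
      others <- which(!sel)
      extra <- others[runif(length(others)) < noise]
      sel[extra] <- TRUE
    }
    iv <- data.frame(chrom = tab$chrom[sel],
                     start = tab$pos[sel] - 1L - pad,
                     end = tab$pos[sel] + pad,
                     stringsAsFactors = FALSE)
    iv <- iv[!duplicated(iv), , drop = FALSE]
    iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    iv
  })
}
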