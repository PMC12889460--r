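#' Forward-backward posterior decoding
#'
#' Runs the scaled forward-backward algorithm on one ternary observation
#' sequence and returns the per-position posterior state probabilities and
#' the sequence log-likelihood.  Per-position normalizers (rather than
#' log-space recursions) keep arbitrarily long sequences from underflowing
#' and yield the log-likelihood as the sum of log normalizers.
#'
#' @param model a `varhmm` model.
#' @param codes `T x M` integer matrix with entries in `{0, 1, 2}` (one row
#'   per position).
#' @return A list with `gamma` (`T x K` posterior matrix; rows sum to 1),
#'   `loglik` (total log-likelihood) and `xi` (`K x K` expected transition
#'   counts summed over positions, used by the EM fitter).
#' @examples
#' m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
#'                rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' forward_backward(m, rbind(c(1, 0), c(0, 1)))$gamma
#' @export
forward_backward <- function(model, codes) {
  validate_hmm(model)
  codes <- check_codes(codes)
  if (ncol(codes) != model$M) stop("sequence width must equal M")
  if (nrow(codes) < 1L) stop("sequence must be nonempty")
  B <- emission_likelihood_matrix(model, codes)
  .fb_cpp(model$initial, model$transition, B)
}

#' Total log-likelihood of a set of sequences
#'
#' @param model a `varhmm` model.
#' @param sequences a list of `T x M` ternary code matrices (or the result
#'   of [build_training_sequences()]).
#' @return The sum of per-sequence log-likelihoods.
#' @export
sequence_loglik <- function(model, sequences) {
  sequences <- as_code_list(sequences)
  if (length(sequences) == 0L) stop("no sequences given")
  sum(vapply(sequences, function(s) forward_backward(model, s)$loglik,
             numeric(1)))
}

# Accept a bare list of matrices or a variant_sequences object.
as_code_list <- function(sequences) {
  if (inherits(sequences, "variant_sequences")) {
    sequences <- sequences$codes
  }
  if (is.matrix(sequences)) sequences <- list(sequences)
  sequences
}

#' Fit a variant prioritization state HMM by Baum-Welch
#'
#' Expectation-maximization training of the multivariate Bernoulli HMM on
#' per-gene ternary observation sequences.  Mirrors the chromatin-state
#' segmentation training recipe: optionally subsample genes anew at each
#' iteration, add pseudo-counts to every expected count before
#' normalization, and keep iterating even when the (subsample-estimated)
#' likelihood decreases.
#'
#' Missing codes (2) contribute no evidence to the emission update: they
#' are excluded from both the numerator and denominator of the "present"
#' frequency, consistent with their emission factor of 1 in the
#' likelihood.
#'
#' Initialization is a seeded random draw: emissions uniform on
#' `(0.2, 0.8)`, transition rows and the initial distribution normalized
#' Gamma(1) (i.e. flat Dirichlet) draws.  With `n_restarts > 1` the fit
#' with the best full-data log-likelihood is returned.  The RNG draw order
#' under `seed` is: for each restart, first the initial distribution, then
#' the transition rows, then the emission matrix, then the per-iteration
#' subsample draws.
#'
#' Stopping: with subsampling the likelihood estimate is noisy, so
#' training runs for exactly `max_iterations`.  In full-batch mode it
#' stops early once the improvement drops below `convergence_delta`
#' (or the likelihood decreases and `allow_likelihood_decrease` is
#' `FALSE`).
#'
#' @param sequences list of `T x M` ternary code matrices, one per gene,
#'   or the result of [build_training_sequences()].
#' @param K number of states.
#' @param n_subsample number of genes drawn (uniformly, without
#'   replacement) for each EM iteration, or `"all"` for full-batch
#'   training.  Draws use the seeded RNG.
#' @param pseudocount nonnegative value added to every expected initial,
#'   transition and emission count (both the "present" and "absent"
#'   emission outcomes) before normalization in the M-step.
#' @param max_iterations maximum number of EM iterations.
#' @param convergence_delta full-batch early-stopping threshold on the
#'   log-likelihood improvement.
#' @param allow_likelihood_decrease continue after a likelihood decrease;
#'   defaults to `TRUE` when subsampling, `FALSE` otherwise.
#' @param n_restarts number of random restarts; the best full-data
#'   log-likelihood wins.
#' @param seed integer seed governing initialization and subsampling.
#' @return A fitted model of class `varhmm`; in addition to the parameter
#'   fields it carries `loglik` (full-data log-likelihood), `trace` (the
#'   per-iteration log-likelihood of the data used in that iteration,
#'   evaluated under the entering parameters), `restart_logliks`,
#'   `iterations` and `n_sequences`.
#' @examples
#' sim <- simulate_model(K = 2, M = 4, seed = 1)
#' seqs <- replicate(20, simulate(sim, n_positions = 30, seed = NULL),
#'                   simplify = FALSE)
#' fit <- fit_hmm(lapply(seqs, `[[`, "codes"), K = 2, seed = 1,
#'                max_iterations = 20)
#' fit$loglik
#' @export
fit_hmm <- function(sequences, K, n_subsample = "all", pseudocount = 0,
                    max_iterations = 200L, convergence_delta = 1e-3,
                    allow_likelihood_decrease = NULL, n_restarts = 1L,
                    seed = 1L) {
  sequences <- as_code_list(sequences)
  if (length(sequences) == 0L) stop("no sequences given")
  sequences <- lapply(sequences, check_codes)
  M <- unique(vapply(sequences, ncol, integer(1)))
  if (length(M) != 1L) stop("all sequences must share the same number of features M")
  if (K < 1L) stop("K must be >= 1")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  n_seq <- length(sequences)
  n_obs <- sum(vapply(sequences, nrow, integer(1)))
  if (K > n_obs) {
    warning("K (", K, ") exceeds the total number of observations (", n_obs,
            "); proceeding anyway")
  }
  subsampling <- !identical(n_subsample, "all")
  if (subsampling) {
    n_subsample <- min(as.integer(n_subsample), n_seq)
  }
  if (is.null(allow_likelihood_decrease)) {
    allow_likelihood_decrease <- subsampling
  }

  with_seed(seed, {
    best <- NULL
    restart_logliks <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      initial <- normalize(rgamma(K, 1))
      transition <- t(apply(matrix(rgamma(K * K, 1), K, K), 1L, normalize))
      if (K == 1L) transition <- matrix(1, 1L, 1L)
      emission <- matrix(runif(K * M, 0.2, 0.8), K, M)
      trace <- numeric(0)
      iter_done <- 0L
      for (iter in seq_len(max_iterations)) {
        idx <- if (subsampling) {
          sample.int(n_seq, n_subsample, replace = FALSE)
        } else {
          seq_len(n_seq)
        }
        es <- em_estep(sequences[idx], initial, transition, emission)
        trace <- c(trace, es$loglik)
        iter_done <- iter
        # M-step with pseudo-counts on every expected count
        initial <- normalize(es$init_counts + pseudocount)
        transition <- sweep_normalize(es$trans_counts + pseudocount)
        if (K == 1L) transition <- matrix(1, 1L, 1L)
        new_emis <- (es$emis_num + pseudocount) /
          (es$emis_den + 2 * pseudocount)
        keep <- !is.finite(new_emis)  # state/feature never observed
        new_emis[keep] <- emission[keep]
        emission <- new_emis
        if (!subsampling && iter > 1L) {
          delta <- trace[iter] - trace[iter - 1L]
          if (delta < 0 && !allow_likelihood_decrease) break
          if (abs(delta) < convergence_delta) break
        }
      }
      model <- structure(
        list(K = as.integer(K), M = as.integer(M), initial = initial,
             transition = transition, emission = emission),
        class = "varhmm")
      full_ll <- sequence_loglik(model, sequences)
      restart_logliks[r] <- full_ll
      if (is.null(best) || full_ll > best$loglik) {
        best <- model
        best$loglik <- full_ll
        best$trace <- trace
        best$iterations <- iter_done
      }
    }
    best$restart_logliks <- restart_logliks
    best$n_sequences <- n_seq
    best$call <- match.call()
    validate_hmm(best)
    best
  })
}

# One EM E-step over a list of sequences: accumulated expected counts and
# the total log-likelihood under the entering parameters.
em_estep <- function(sequences, initial, transition, emission) {
  K <- length(initial)
  M <- ncol(emission)
  init_counts <- numeric(K)
  trans_counts <- matrix(0, K, K)
  emis_num <- matrix(0, K, M)
  emis_den <- matrix(0, K, M)
  loglik <- 0
  lp1 <- t(log(pmax(emission, 1e-300)))
  lp0 <- t(log(pmax(1 - emission, 1e-300)))
  for (s in sequences) {
    I1 <- (s == 1L)
    I0 <- (s == 0L)
    B <- exp(I1 %*% lp1 + I0 %*% lp0)
    fb <- .fb_cpp(initial, transition, B)
    loglik <- loglik + fb$loglik
    init_counts <- init_counts + fb$gamma[1L, ]
    trans_counts <- trans_counts + fb$xi
    emis_num <- emis_num + crossprod(fb$gamma, I1)
    emis_den <- emis_den + crossprod(fb$gamma, I1 | I0)
  }
  list(loglik = loglik, init_counts = init_counts,
       trans_counts = trans_counts, emis_num = emis_num,
       emis_den = emis_den)
}

normalize <- function(x) x / sum(x)

sweep_normalize <- function(m) m / rowSums(m)
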