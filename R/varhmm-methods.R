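#' @export
print.varhmm <- function(x, ...) {
  cat("Multivariate Bernoulli HMM (varhmm)\n")
  cat("  states (K):   ", x$K, "\n", sep = "")
  cat("  features (M): ", x$M, "\n", sep = "")
  if (!is.null(x$loglik)) {
    cat("  fitted on ", x$n_sequences, " sequences; log-likelihood ",
        format(x$loglik, digits = 8), " after ", x$iterations,
        " EM iterations\n", sep = "")
  }
  invisible(x)
}

#' Summarize a fitted prioritization-state model
#'
#' Combines the per-state top-score membership counts and grouping from
#' [summarize_states()] with the parameter matrices.
#'
#' @param object a `varhmm` model.
#' @param top_n how many top emission ranks count as membership (default 5).
#' @param ... passed to [summarize_states()].
#' @return An object of class `summary.varhmm`.
#' @export
summary.varhmm <- function(object, top_n = 5L, ...) {
  out <- list(model = object,
              states = summarize_states(object, top_n = top_n, ...))
  class(out) <- "summary.varhmm"
  out
}

#' @export
print.summary.varhmm <- function(x, ...) {
  print(x$model)
  cat("\nState summary (top-score membership counts):\n")
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' @export
coef.varhmm <- function(object, ...) {
  list(initial = object$initial, transition = object$transition,
       emission = object$emission)
}

#' @export
logLik.varhmm <- function(object, ...) {
  if (is.null(object$loglik)) stop("model has not been fitted to data")
  K <- object$K
  structure(object$loglik,
            df = (K - 1) + K * (K - 1) + K * object$M,
            class = "logLik")
}

#' Posterior decoding for new observation sequences
#'
#' Runs forward-backward posterior decoding on one or more ternary code
#' sequences.  For the window-based mode assignment used to annotate a
#' variant table, see [annotate_variants()].
#'
#' @param object a `varhmm` model.
#' @param newdata a `T x M` ternary code matrix or a list of them.
#' @param type `"state"` for per-position maximum-posterior states (ties
#'   broken toward the lowest state index), `"posterior"` for the full
#'   `gamma` matrices.
#' @param ... unused.
#' @return For a single matrix, an integer vector (type `"state"`) or a
#'   `T x K` matrix (type `"posterior"`); for a list, a list of the same.
#' @export
predict.varhmm <- function(object, newdata, type = c("state", "posterior"),
                           ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  seqs <- as_code_list(newdata)
  out <- lapply(seqs, function(s) {
    gamma <- forward_backward(object, s)$gamma
    if (type == "state") max.col(gamma, ties.method = "first") else gamma
  })
  if (single) out[[1L]] else out
}

#' Simulate a state path and ternary codes from the model
#'
#' Draws a hidden state path from the Markov chain and, per position and
#' feature, a Bernoulli "present" indicator from the state's emission
#' probability.  No missing codes are generated here; missingness is
#' injected by [simulate_dataset()].
#'
#' @param object a `varhmm` model.
#' @param nsim number of sequences to draw.
#' @param seed integer seed, or `NULL` to use the session RNG.
#' @param n_positions sequence length (scalar or vector of length `nsim`).
#' @param ... unused.
#' @return For `nsim = 1` a list with `states` (length-`T` integer vector)
#'   and `codes` (`T x M` 0/1 matrix); otherwise a list of such lists.
#' @export
simulate.varhmm <- function(object, nsim = 1, seed = NULL,
                            n_positions = 100L, ...) {
  validate_hmm(object)
  n_positions <- rep_len(n_positions, nsim)
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(i) {
      T_ <- n_positions[i]
      states <- integer(T_)
      states[1L] <- sample.int(object$K, 1L, prob = object$initial)
      for (t in seq_len(T_ - 1L)) {
        states[t + 1L] <- sample.int(object$K, 1L,
                                     prob = object$transition[states[t], ])
      }
      p <- object$emission[states, , drop = FALSE]
      codes <- matrix(as.integer(runif(length(p)) < p), nrow = T_)
      list(states = states, codes = codes)
    })
    if (nsim == 1) out[[1L]] else out
  })
}

#' Emission heatmap of a fitted model
#'
#' Displays the `K x M` emission matrix as a shaded image, states on the
#' rows (state 1 at the top) and score features on the columns.
#'
#' @param x a `varhmm` model.
#' @param feature_names optional column labels.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.varhmm <- function(x, feature_names = NULL, ...) {
  em <- x$emission
  if (is.null(feature_names)) {
    feature_names <- colnames(em)
    if (is.null(feature_names)) feature_names <- paste0("S", seq_len(x$M))
  }
  graphics::image(x = seq_len(x$M), y = seq_len(x$K),
                  z = t(em[rev(seq_len(x$K)), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE,
                  xlab = "score feature", ylab = "state", ...)
  graphics::axis(1, at = seq_len(x$M), labels = feature_names, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(x$K), labels = rev(seq_len(x$K)), las = 1)
  graphics::box()
  invisible(x)
}
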