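#' Construct a multivariate Bernoulli-emission HMM
#'
#' Builds the parameter container used throughout the package: `K` hidden
#' states over `M` binary score features, with an initial distribution, a
#' row-stochastic transition matrix and per-state Bernoulli "present"
#' probabilities.  Observations are ternary codes: 1 (feature present,
#' i.e. score in the top quantile), 0 (absent) or 2 (score missing; the
#' feature contributes no evidence).
#'
#' @param initial numeric vector of length `K`; must sum to 1.
#' @param transition `K x K` matrix; each row must sum to 1.
#' @param emission `K x M` matrix of probabilities in `[0, 1]` that a
#'   feature is "present" in each state.
#' @return An object of class `varhmm` with elements `K`, `M`, `initial`,
#'   `transition` and `emission`.
#' @examples
#' m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
#'                rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' m$K
#' @export
hmm_model <- function(initial, transition, emission) {
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  obj <- structure(
    list(K = length(initial), M = ncol(emission),
         initial = as.numeric(initial), transition = transition,
         emission = emission),
    class = "varhmm")
  validate_hmm(obj)
}

validate_hmm <- function(x, tol = 1e-5) {
  stopifnot(inherits(x, "varhmm"))
  K <- x$K; M <- x$M
  if (K < 1L || M < 1L) stop("K and M must be >= 1")
  if (length(x$initial) != K) stop("initial must have length K")
  if (!all(dim(x$transition) == c(K, K))) stop("transition must be K x K")
  if (nrow(x$emission) != K || ncol(x$emission) != M) {
    stop("emission must be K x M")
  }
  if (abs(sum(x$initial) - 1) > tol) stop("initial must sum to 1")
  if (any(abs(rowSums(x$transition) - 1) > tol)) {
    stop("transition rows must sum to 1")
  }
  if (any(x$emission < 0 | x$emission > 1)) {
    stop("emission probabilities must lie in [0, 1]")
  }
  if (any(x$initial < 0) || any(x$transition < 0)) {
    stop("probabilities must be nonnegative")
  }
  invisible(x)
}

#' Per-state emission likelihood of one ternary observation
#'
#' For each state `s` the likelihood is the product over features `n` of
#' `p[s, n]` when the code is 1, `1 - p[s, n]` when it is 0, and 1 when it
#' is 2 (missing): a missing feature contributes no evidence.
#'
#' @param model a `varhmm` model.
#' @param obs_row integer vector of length `M` with entries in `{0, 1, 2}`.
#' @return Numeric vector of length `K` of likelihoods in `[0, 1]`.
#' @examples
#' m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
#'                rbind(c(0.9, 0.1, 0.5), c(0.2, 0.8, 0.5)))
#' emission_likelihood(m, c(1, 0, 2))  # c(0.81, 0.04)
#' @export
emission_likelihood <- function(model, obs_row) {
  validate_hmm(model)
  obs <- check_codes(matrix(obs_row, nrow = 1L))
  if (ncol(obs) != model$M) stop("observation length must equal M")
  drop(emission_likelihood_matrix(model, obs))
}

# T x K matrix of per-position emission likelihoods for a whole sequence.
# Logs are clamped so that emission probabilities of exactly 0 or 1 yield
# (numerically) zero likelihood instead of NaN.
emission_likelihood_matrix <- function(model, codes) {
  lp1 <- t(log(pmax(model$emission, 1e-300)))      # M x K
  lp0 <- t(log(pmax(1 - model$emission, 1e-300)))
  I1 <- (codes == 1L)
  I0 <- (codes == 0L)
  exp(I1 %*% lp1 + I0 %*% lp0)
}

#' Replace the transition matrix by the uniform one
#'
#' Sets every transition probability to `1/K`, leaving the emission
#' parameters and the initial distribution untouched.  Annotating with the
#' uniformized model isolates the contribution of spatial context: under
#' uniform transitions the posterior at each interior position depends on
#' that position's emission likelihood alone.
#'
#' @param model a `varhmm` model.
#' @return The model with `transition` set to `1/K` everywhere.
#' @export
uniformize_transitions <- function(model) {
  validate_hmm(model)
  model$transition <- matrix(1 / model$K, model$K, model$K)
  model
}

#' Read and write HMM model files
#'
#' Plain-text interchange format: a header line `K M` (tab-separated),
#' then the blocks `initial`, `transition` and `emission`, each a block
#' name on its own line followed by tab-separated decimals written at six
#' significant digits.  Writing then reading recovers the parameters at
#' that precision, and re-writing a read model is byte-identical.
#'
#' @param model a `varhmm` model.
#' @param path file path.
#' @return `read_hmm_model` returns a `varhmm` model; `write_hmm_model`
#'   returns `path` invisibly.
#' @export
write_hmm_model <- function(model, path) {
  validate_hmm(model, tol = 1e-4)  # models read back at 6 digits pass too
  fmt <- function(x) apply(rbind(x), 1L, function(r) {
    paste(sprintf("%.6g", r), collapse = "\t")
  })
  lines <- c(paste(model$K, model$M, sep = "\t"),
             "initial", fmt(model$initial),
             "transition", fmt(model$transition),
             "emission", fmt(model$emission))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  K <- hd[1L]; M <- hd[2L]
  parse_block <- function(at, n) {
    vals <- lapply(lines[seq(at, length.out = n)], function(l) {
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])
    })
    do.call(rbind, vals)
  }
  if (lines[2L] != "initial") stop("malformed model file: expected 'initial'")
  initial <- drop(parse_block(3L, 1L))
  if (lines[4L] != "transition") {
    stop("malformed model file: expected 'transition'")
  }
  transition <- parse_block(5L, K)
  if (lines[5L + K] != "emission") {
    stop("malformed model file: expected 'emission'")
  }
  emission <- parse_block(6L + K, K)
  obj <- structure(
    list(K = K, M = M, initial = initial, transition = transition,
         emission = emission),
    class = "varhmm")
  # six significant digits: row sums deviate from 1 by up to ~K * 5e-7
  validate_hmm(obj, tol = 1e-4)
}
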