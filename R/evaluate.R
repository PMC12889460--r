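# Paired with/without-state predictive evaluation.  Design matrices are
# built by hand (intercept + score + K-1 state indicators) so that a state
# level absent from a training fold yields a zero, not NA, contribution at
# prediction time.

state_design <- function(score, state, levels) {
  X <- cbind(1, score)
  if (length(levels) > 1L) {
    ind <- outer(state, levels[-1L], `==`) * 1
    colnames(ind) <- paste0("state", levels[-1L])
    X <- cbind(X, ind)
  }
  colnames(X)[1:2] <- c("(Intercept)", "score")
  X
}

fit_predict <- function(X, y, train, test, family = NULL) {
  Xt <- X[train, , drop = FALSE]
  keep <- c(TRUE, apply(Xt[, -1L, drop = FALSE], 2L, function(col) {
    length(unique(col)) > 1L
  }))
  fit <- if (is.null(family)) {
    stats::lm.fit(Xt[, keep, drop = FALSE], y[train])
  } else {
    suppressWarnings(
      stats::glm.fit(Xt[, keep, drop = FALSE], y[train], family = family))
  }
  beta <- rep(0, ncol(X))
  beta[keep] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  eta <- drop(X[test, , drop = FALSE] %*% beta)
  if (is.null(family)) eta else plogis(eta)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) {
      stop("too few observations in a class for ", n_folds, "-fold ",
           "stratified cross-validation")
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

auroc <- function(labels, pred) {
  as.numeric(pROC::auc(response = labels, predictor = pred,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Build a balanced labeled variant set
#'
#' Removes from the negative set any variant whose key appears among the
#' positives, then down-samples the negatives without replacement to the
#' number of positives, producing a balanced classification set.
#'
#' @param positives,negatives data frames with variant key columns
#'   (`chrom`, `pos`, `ref`, `alt`) plus score/state columns.
#' @param seed integer seed for the down-sampling draw.
#' @return The row-bound balanced set with a binary `label` column
#'   (1 = positive).
#' @export
prepare_classification_set <- function(positives, negatives, seed = 1L) {
  kp <- variant_key(positives)
  negatives <- negatives[!(variant_key(negatives) %in% kp), , drop = FALSE]
  if (nrow(negatives) < nrow(positives)) {
    stop("fewer negatives than positives after exclusion")
  }
  with_seed(seed, {
    keep <- sample.int(nrow(negatives), nrow(positives))
    negatives <- negatives[keep, , drop = FALSE]
  })
  positives$label <- 1L
  negatives$label <- 0L
  common <- intersect(names(positives), names(negatives))
  out <- rbind(positives[, common, drop = FALSE],
               negatives[, common, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Paired classification evaluation of a score with and without states
#'
#' Cross-validated comparison of two logistic regression classifiers of a
#' binary pathogenicity label: one using the score as its only feature,
#' one using the score plus one-hot state indicators (K-1 indicators with
#' an intercept).  Folds are stratified by label; out-of-fold predicted
#' probabilities are pooled and a single overall AUROC computed per
#' feature set.  Rows with a missing score are dropped (and counted).
#'
#' @param set a labeled set (e.g. from [prepare_classification_set()])
#'   with `label` and `state` columns.
#' @param score_name name of the score column to evaluate.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return A one-row data frame: `score`, `auroc_score_only`,
#'   `auroc_with_states`, `percent_improvement`
#'   (`100 * (with - without) / without`), `n_used`, `n_dropped`.
#' @export
paired_classification_eval <- function(set, score_name, n_folds = 5L,
                                       seed = 1L) {
  if (!score_name %in% names(set)) stop("no such score column: ", score_name)
  ok <- !is.na(set[[score_name]])
  n_dropped <- sum(!ok)
  set <- set[ok, , drop = FALSE]
  y <- set$label
  if (length(unique(y)) < 2L) stop("both classes must be nonempty")
  levels <- sort(unique(set$state))
  X <- state_design(set[[score_name]], set$state, levels)
  with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    pred1 <- pred2 <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      test <- fold == f
      train <- !test
      pred1[test] <- fit_predict(X[, 1:2, drop = FALSE], y, train, test,
                                 family = binomial())
      pred2[test] <- fit_predict(X, y, train, test, family = binomial())
    }
    a1 <- auroc(y, pred1)
    a2 <- auroc(y, pred2)
    data.frame(score = score_name, auroc_score_only = a1,
               auroc_with_states = a2,
               percent_improvement = 100 * (a2 - a1) / a1,
               n_used = length(y), n_dropped = n_dropped,
               stringsAsFactors = FALSE)
  })
}

#' Paired regression evaluation against DMS-style measurements
#'
#' For each measurement, cross-validated comparison of two linear
#' regressions of the measurement value: score only versus score plus
#' one-hot state indicators.  Out-of-fold predictions are pooled and
#' scored by Spearman correlation with the truth.  Measurements with a
#' constant value (undefined Spearman) or fewer than `2 * n_folds`
#' variants are skipped with a message.
#'
#' @param measurements data frame with columns `measurement` (identifier),
#'   `value` (the measured effect), `state` and the score column.
#' @param score_name name of the score column.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return Data frame with one row per evaluated measurement: `score`,
#'   `measurement`, `spearman_score_only`, `spearman_with_states`,
#'   `percent_improvement`, `n`.
#' @export
paired_regression_eval <- function(measurements, score_name, n_folds = 5L,
                                   seed = 1L) {
  if (!score_name %in% names(measurements)) {
    stop("no such score column: ", score_name)
  }
  ok <- !is.na(measurements[[score_name]]) & !is.na(measurements$value)
  measurements <- measurements[ok, , drop = FALSE]
  with_seed(seed, {
    out <- lapply(split(measurements, measurements$measurement),
                  function(d) {
      if (nrow(d) < 2L * n_folds) {
        message("measurement ", d$measurement[1L],
                " has too few variants; skipped")
        return(NULL)
      }
      if (length(unique(d$value)) < 2L) {
        message("measurement ", d$measurement[1L],
                " is constant; skipped")
        return(NULL)
      }
      y <- d$value
      levels <- sort(unique(d$state))
      X <- state_design(d[[score_name]], d$state, levels)
      fold <- sample(rep_len(seq_len(n_folds), length(y)))
      pred1 <- pred2 <- numeric(length(y))
      for (f in seq_len(n_folds)) {
        test <- fold == f
        pred1[test] <- fit_predict(X[, 1:2, drop = FALSE], y, !test, test)
        pred2[test] <- fit_predict(X, y, !test, test)
      }
      s1 <- cor(pred1, y, method = "spearman")
      s2 <- cor(pred2, y, method = "spearman")
      data.frame(score = score_name, measurement = d$measurement[1L],
                 spearman_score_only = s1, spearman_with_states = s2,
                 percent_improvement = 100 * (s2 - s1) / abs(s1),
                 n = length(y), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Conditional positive probability above a score threshold, per state
#'
#' Among variants with score above `threshold`, the fraction labeled
#' positive, computed separately within each state.  Quantifies how much
#' the pathogenic fraction of highly ranked variants varies with the
#' state.  States with no qualifying variants are reported `NA`.
#'
#' @param set a labeled set with `label`, `state` and the score column.
#' @param score_name name of the score column.
#' @param threshold score cutoff (qualifying variants have
#'   `score > threshold`).
#' @return A list with `per_state` (data frame: `state`, `n`,
#'   `probability`), `mean` and `sd` across non-missing states.
#' @export
conditional_positive_probability <- function(set, score_name, threshold) {
  x <- set[[score_name]]
  qual <- !is.na(x) & x > threshold
  states <- sort(unique(set$state))
  per_state <- do.call(rbind, lapply(states, function(s) {
    sel <- qual & set$state == s
    data.frame(state = s, n = sum(sel),
               probability = if (sum(sel) == 0L) NA_real_
                             else mean(set$label[sel] == 1L))
  }))
  list(per_state = per_state,
       mean = mean(per_state$probability, na.rm = TRUE),
       sd = sd(per_state$probability, na.rm = TRUE))
}

#' Per-state average scaled ranks of predictors and DMS measurements
#'
#' Converts a DMS measurement to within-protein ranks scaled to `[0, 1]`
#' (1 = most pathogenic) and each predictor's scores to across-protein
#' ranks with the same orientation, then averages the scaled ranks over
#' the variants in each state.  Also reports, per state, the Spearman
#' correlation between the predictors' average ranks in the state and a
#' leaderboard ordering (supplied, or computed as the per-protein average
#' Spearman of each predictor with the DMS ranks); and, per predictor,
#' the Spearman correlation between its per-state rank profile and the
#' DMS per-state rank profile.
#'
#' @param x data frame with columns `state`, `protein`, `dms` (the
#'   measurement) and the predictor columns.
#' @param predictors character vector of predictor column names.
#' @param leaderboard optional numeric vector (named by predictor) of
#'   leaderboard positions in ascending order (1 = best); computed from
#'   the data when `NULL`.
#' @param low_is_damaging orientation of raw values: when `TRUE` (the
#'   common DMS convention) the lowest measurement/score ranks as most
#'   pathogenic (scaled rank 1).
#' @return A list with `state_dms_rank` (per-state average DMS rank),
#'   `state_predictor_rank` (states x predictors matrix of average
#'   ranks), `leaderboard`, `state_leaderboard_cor` and
#'   `predictor_dms_cor`.
#' @export
rank_by_state <- function(x, predictors, leaderboard = NULL,
                          low_is_damaging = TRUE) {
  stopifnot(all(c("state", "protein", "dms") %in% names(x)),
            all(predictors %in% names(x)))
  orient <- function(r) if (low_is_damaging) 1 - r else r
  # DMS ranks within protein
  keep <- rep(TRUE, nrow(x))
  dms_rank <- rep(NA_real_, nrow(x))
  for (pr in unique(x$protein)) {
    sel <- x$protein == pr
    if (sum(sel) < 2L) {
      message("protein ", pr, " has fewer than 2 variants; excluded")
      keep[sel] <- FALSE
      next
    }
    dms_rank[sel] <- orient(rank_scale(x$dms[sel]))
  }
  x <- x[keep, , drop = FALSE]
  dms_rank <- dms_rank[keep]
  # predictor ranks across proteins
  pred_rank <- vapply(predictors, function(p) orient(rank_scale(x[[p]])),
                      numeric(nrow(x)))
  states <- sort(unique(x$state))
  state_dms <- vapply(states, function(s) mean(dms_rank[x$state == s]),
                      numeric(1))
  names(state_dms) <- states
  pred_rank <- matrix(pred_rank, nrow = nrow(x),
                      dimnames = list(NULL, predictors))
  state_pred <- do.call(rbind, lapply(states, function(s) {
    colMeans(pred_rank[x$state == s, , drop = FALSE])
  }))
  rownames(state_pred) <- states
  if (is.null(leaderboard)) {
    per_protein <- lapply(split(seq_len(nrow(x)), x$protein), function(idx) {
      vapply(predictors, function(p) {
        cor(pred_rank[idx, p], dms_rank[idx], method = "spearman")
      }, numeric(1))
    })
    avg_spearman <- colMeans(do.call(rbind, per_protein), na.rm = TRUE)
    leaderboard <- rank(-avg_spearman, ties.method = "min")
  }
  # negated positions so that a positive correlation means predictors
  # ranking the state's variants high sit higher on the leaderboard
  state_leaderboard_cor <- apply(state_pred, 1L, function(r) {
    suppressWarnings(cor(r, -leaderboard[predictors], method = "spearman"))
  })
  predictor_dms_cor <- apply(state_pred, 2L, function(col) {
    suppressWarnings(cor(col, state_dms, method = "spearman"))
  })
  list(state_dms_rank = state_dms, state_predictor_rank = state_pred,
       leaderboard = leaderboard,
       state_leaderboard_cor = state_leaderboard_cor,
       predictor_dms_cor = predictor_dms_cor)
}
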