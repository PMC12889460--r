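#' Rank states by emission membership and group them
#'
#' For each score feature, states are ranked by emission probability in
#' descending order (ties share the minimum rank).  A state's `top_count`
#' is the number of scores for which it ranks within the top `top_n`
#' states.  States are then ordered by descending `top_count` (ties toward
#' the lower state index) and cut into four groups: states prioritized by
#' most scores, by an intermediate band of scores, by only a few, and by
#' none.
#'
#' @param model a `varhmm` model.
#' @param top_n emission rank cutoff counting as membership (default 5).
#' @param group_thresholds integer vector `c(lo, hi)`: group 2 covers
#'   `top_count` in `[lo, hi]`, group 1 above `hi`, group 3 in
#'   `[1, lo - 1]` and group 4 exactly 0.  Default
#'   `c(ceiling(0.15 * M), floor(0.45 * M))`.
#' @return Data frame with `state`, `top_count`, `display_order` (a
#'   permutation of `1:K`) and `group`.
#' @export
summarize_states <- function(model, top_n = 5L, group_thresholds = NULL) {
  validate_hmm(model)
  K <- model$K; M <- model$M
  if (is.null(group_thresholds)) {
    group_thresholds <- c(ceiling(0.15 * M), floor(0.45 * M))
  }
  lo <- group_thresholds[1L]; hi <- group_thresholds[2L]
  # rank of each state within each score, descending emission, min ties
  ranks <- apply(model$emission, 2L, function(p) {
    rank(-p, ties.method = "min")
  })
  ranks <- matrix(ranks, nrow = K)  # K x M
  top_count <- rowSums(ranks <= top_n)
  ord <- order(-top_count, seq_len(K))
  display_order <- integer(K)
  display_order[ord] <- seq_len(K)
  group <- ifelse(top_count == 0L, 4L,
           ifelse(top_count < lo, 3L,
           ifelse(top_count <= hi, 2L, 1L)))
  data.frame(state = seq_len(K), top_count = as.integer(top_count),
             display_order = display_order, group = as.integer(group))
}

# Point-in-interval overlap.  Variant positions are 1-based; intervals are
# 0-based half-open, so position p overlaps [start, end) iff
# start <= p - 1 < end.  Centralized here as the package's only coordinate
# conversion.
overlaps_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Fold enrichment of states for interval annotations
#'
#' For each state `s` and annotation `a`, the fold enrichment is
#' `(B_sa / B_s) / (B_a / B_total)`: the state-conditional annotation
#' frequency over the background frequency, where `B_sa` counts variants
#' in state `s` overlapping `a`, `B_s` the variants in state `s`, `B_a`
#' the background variants overlapping `a` and `B_total` all background
#' variants.  A variant overlaps an annotation when its (1-based)
#' position falls inside one of the (0-based half-open) intervals; strand
#' is ignored.
#'
#' @param assignments an assignment data frame or [annotate_variants()]
#'   result.
#' @param intervals a BED-style interval data frame (from [read_bed()])
#'   or a named list of them (one enrichment column set per annotation).
#' @param background assignment table used as background; defaults to
#'   `assignments` (all annotated variants).
#' @param unique_positions count unique (chrom, pos) positions instead of
#'   variant rows.
#' @return Data frame with one row per (state, annotation):
#'   `state`, `annotation`, `B_sa`, `B_s`, `B_a`, `B_total` and `fold`
#'   (`NA` when `B_s` or `B_a` is 0).
#' @export
fold_enrichment <- function(assignments, intervals,
                            background = assignments,
                            unique_positions = FALSE) {
  assignments <- as_assignments(assignments)
  background <- as_assignments(background)
  if (is.data.frame(intervals)) intervals <- list(annotation = intervals)
  for (iv in intervals) {
    if (any(iv$start >= iv$end)) {
      stop("malformed intervals: start must be < end")
    }
  }
  if (unique_positions) {
    assignments <- assignments[!duplicated(assignments[, c("chrom", "pos")]),
                               , drop = FALSE]
    background <- background[!duplicated(background[, c("chrom", "pos")]),
                             , drop = FALSE]
  }
  states <- sort(unique(assignments$state))
  B_total <- nrow(background)
  out <- lapply(names(intervals), function(nm) {
    iv <- intervals[[nm]]
    in_a <- overlaps_intervals(assignments$chrom, assignments$pos, iv)
    in_bg <- overlaps_intervals(background$chrom, background$pos, iv)
    B_a <- sum(in_bg)
    do.call(rbind, lapply(states, function(s) {
      sel <- assignments$state == s
      B_s <- sum(sel)
      B_sa <- sum(sel & in_a)
      fold <- if (B_s == 0L || B_a == 0L) {
        NA_real_
      } else {
        (B_sa / B_s) / (B_a / B_total)
      }
      data.frame(state = s, annotation = nm, B_sa = B_sa, B_s = B_s,
                 B_a = B_a, B_total = B_total, fold = fold,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Amino-acid substitution preferences per state
#'
#' Counts each ordered amino-acid substitution (e.g. `"P->L"`) among the
#' variants assigned to each state and compares the within-state
#' proportion to the overall proportion across all states: `delta` is the
#' difference of proportions (per state the deltas sum to 0) and `fold`
#' their ratio.  Rows with a missing reference or alternate amino acid are
#' excluded; the number excluded is attached as attribute `n_excluded`.
#'
#' @param assignments an assignment data frame or [annotate_variants()]
#'   result.
#' @param table the variant table with `aaref`/`aaalt` columns, aligned
#'   by variant key.
#' @return Data frame with `state`, `substitution`, `count`, `delta`,
#'   `fold`.
#' @export
substitution_preferences <- function(assignments, table) {
  assignments <- as_assignments(assignments)
  if (!all(c("aaref", "aaalt") %in% names(table))) {
    stop("table must have aaref and aaalt columns")
  }
  m <- match(variant_key(assignments), variant_key(table))
  if (anyNA(m)) stop("assignments contain variants absent from table")
  aaref <- table$aaref[m]; aaalt <- table$aaalt[m]
  ok <- !is.na(aaref) & !is.na(aaalt) & aaref != "" & aaalt != ""
  n_excluded <- sum(!ok)
  sub <- paste(aaref[ok], aaalt[ok], sep = "->")
  st <- assignments$state[ok]
  subs <- sort(unique(sub))
  overall <- as.numeric(table(factor(sub, levels = subs)))
  overall_prop <- overall / sum(overall)
  out <- do.call(rbind, lapply(sort(unique(st)), function(s) {
    cnt <- as.numeric(table(factor(sub[st == s], levels = subs)))
    prop <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, length(subs))
    data.frame(state = s, substitution = subs, count = cnt,
               delta = prop - overall_prop,
               fold = prop / overall_prop,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Match states across two models by emission correlation
#'
#' For each state of model `a`, the Pearson correlation between its
#' emission vector (length `M`) and every state of model `b`, reporting
#' the best-matching state of `b` and the maximum correlation.  Used to
#' compare models of different sizes trained on the same features.  A
#' zero-variance emission vector has undefined correlation and is
#' reported as `NA`.
#'
#' @param model_a,model_b `varhmm` models sharing the same `M`.
#' @return Data frame with `state`, `best_match`, `correlation`.
#' @export
compare_models <- function(model_a, model_b) {
  validate_hmm(model_a); validate_hmm(model_b)
  if (model_a$M != model_b$M) {
    stop("models must share the same number of features M")
  }
  C <- suppressWarnings(cor(t(model_a$emission), t(model_b$emission)))
  C <- matrix(C, nrow = model_a$K)
  best <- apply(C, 1L, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  corr <- vapply(seq_len(model_a$K), function(i) {
    if (is.na(best[i])) NA_real_ else C[i, best[i]]
  }, numeric(1))
  data.frame(state = seq_len(model_a$K), best_match = as.integer(best),
             correlation = corr)
}
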