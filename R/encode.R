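#' Rank-scale a score vector to [0, 1]
#'
#' Replaces non-missing values by `(rank - 1) / (n - 1)` over the
#' non-missing entries, ascending, so that the largest (most damaging)
#' value maps to 1 and the smallest to 0.  Ties share the mean rank;
#' missing values stay missing.  A single non-missing value maps to 0.5.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @return Numeric vector of the same length in `[0, 1]` with `NA`s
#'   preserved.
#' @examples
#' rank_scale(c(3, NA, 7, 1))  # 0.5, NA, 1.0, 0.0
#' @export
rank_scale <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0L) stop("all values are missing")
  if (n == 1L) {
    x[!is.na(x)] <- 0.5
    return(x)
  }
  r <- rank(x, ties.method = "average", na.last = "keep")
  (r - 1) / (n - 1)
}

#' Score quality-control filter
#'
#' Drops score columns that are unusable for top-quantile binarization:
#' those with a missing fraction above `missing_rate_max` or with more
#' than `top_tie_rate_max` of their non-missing values tied at the
#' maximum (a saturated score carries almost no top-quantile signal).
#'
#' @param table a variant table (see [read_variant_table()]); all columns
#'   other than `chrom`, `pos`, `ref`, `alt`, `gene`, `aaref`, `aaalt` are
#'   treated as scores.
#' @param missing_rate_max,top_tie_rate_max drop thresholds (fractions).
#' @return A list with `table` (the filtered table) and `report`, a data
#'   frame with one row per score giving `missing_rate`, `top_tie_rate`,
#'   `dropped` and the offending `reason` (e.g. `"missing_rate 0.80"`).
#' @export
qc_filter_scores <- function(table, missing_rate_max = 0.5,
                             top_tie_rate_max = 0.5) {
  check_variant_table(table)
  scores <- score_columns(table)
  if (length(scores) == 0L) stop("variant table has no score columns")
  report <- do.call(rbind, lapply(scores, function(sc) {
    x <- table[[sc]]
    mr <- mean(is.na(x))
    nx <- x[!is.na(x)]
    tr <- if (length(nx) == 0L) 1 else mean(nx == max(nx))
    dropped <- mr > missing_rate_max || tr > top_tie_rate_max
    reason <- if (mr > missing_rate_max) {
      sprintf("missing_rate %.2f", mr)
    } else if (tr > top_tie_rate_max) {
      sprintf("top_tie_rate %.2f", tr)
    } else {
      ""
    }
    data.frame(score = sc, missing_rate = mr, top_tie_rate = tr,
               dropped = dropped, reason = reason,
               stringsAsFactors = FALSE)
  }))
  kept <- report$score[!report$dropped]
  if (length(kept) == 0L) stop("all score columns were dropped by QC")
  keep_cols <- c(intersect(names(table),
                           c(variant_key_cols, "gene", "aaref", "aaalt")),
                 kept)
  list(table = table[, keep_cols, drop = FALSE], report = report)
}

#' Binarize scores into ternary presence codes
#'
#' Per score column, code 1 marks values in the top `Q`% of non-missing
#' values across all variants: the cutoff is the `ceiling(Q/100 * n)`-th
#' largest value and every value `>=` the cutoff is coded 1.  With
#' distinct values exactly `ceiling(Q/100 * n)` variants are coded 1;
#' ties at the cutoff (in particular, a mass of values tied at the
#' maximum larger than `Q`%) are all coded 1.  Remaining non-missing
#' values are coded 0 and missing values 2.
#'
#' @param x a variant table (score columns are binarized) or a numeric
#'   matrix of scores.
#' @param Q top-percent threshold in `(0, 100)`.
#' @return Integer matrix of codes in `{0, 1, 2}`, one row per variant,
#'   one column per score.
#' @examples
#' binarize(matrix(1:100, ncol = 1), Q = 10)  # exactly 10 ones
#' @export
binarize <- function(x, Q = 10) {
  if (Q <= 0 || Q >= 100) stop("Q must lie in (0, 100)")
  scores <- if (is.data.frame(x)) {
    as.matrix(x[, score_columns(x), drop = FALSE])
  } else {
    as.matrix(x)
  }
  storage.mode(scores) <- "double"
  codes <- matrix(2L, nrow(scores), ncol(scores),
                  dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    ok <- !is.na(v)
    n <- sum(ok)
    if (n == 0L) next
    q <- ceiling(Q / 100 * n)
    cutoff <- sort(v[ok], decreasing = TRUE)[q]
    codes[ok, j] <- ifelse(v[ok] >= cutoff, 1L, 0L)
  }
  codes
}

#' Build per-gene training sequences
#'
#' For each gene, orders its unique genomic positions ascending and picks
#' exactly one variant row per position uniformly at random (a position
#' can host up to three alternate alleles).  The chosen rows' ternary
#' codes, concatenated in position order, form the gene's training
#' sequence.
#'
#' @param table a variant table.
#' @param codes ternary code matrix aligned to `table` rows (from
#'   [binarize()]).
#' @param seed integer seed for the per-position draws.
#' @return An object of class `variant_sequences`: a list with `codes`
#'   (named list of per-gene `T x M` matrices, genes in sorted order) and
#'   `manifest` (data frame mapping `gene`, `pos` to the chosen `row` of
#'   `table`).
#' @export
build_training_sequences <- function(table, codes, seed = 1L) {
  check_variant_table(table)
  codes <- check_codes(codes)
  if (nrow(codes) != nrow(table)) {
    stop("codes must have one row per variant table row")
  }
  genes <- sort(unique(table$gene))
  with_seed(seed, {
    rows_by_gene <- split(seq_len(nrow(table)), table$gene)
    seq_list <- vector("list", length(genes))
    names(seq_list) <- genes
    manifest <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      g <- genes[i]
      rows <- rows_by_gene[[g]]
      if (length(rows) == 0L) {
        message("gene ", g, " has no variants; skipped")
        next
      }
      pos_split <- split(rows, table$pos[rows])
      pos_order <- order(as.numeric(names(pos_split)))
      chosen <- vapply(pos_split[pos_order], sample_one, numeric(1))
      chosen <- as.integer(chosen)
      seq_list[[i]] <- codes[chosen, , drop = FALSE]
      manifest[[i]] <- data.frame(gene = g, pos = table$pos[chosen],
                                  row = chosen, stringsAsFactors = FALSE)
    }
    keep <- !vapply(seq_list, is.null, logical(1))
    structure(list(codes = seq_list[keep],
                   manifest = do.call(rbind, manifest[keep])),
              class = "variant_sequences")
  })
}

#' @export
print.variant_sequences <- function(x, ...) {
  lens <- vapply(x$codes, nrow, integer(1))
  cat("Per-gene training sequences: ", length(x$codes), " genes, ",
      sum(lens), " positions (M = ", ncol(x$codes[[1L]]), ")\n", sep = "")
  invisible(x)
}
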