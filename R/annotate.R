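# Window-based mode assignment: for each target variant, N "local
# combinations" are sampled (one random variant per flanking position, the
# target row fixed), forward-backward is run on each window as a standalone
# chain starting from the model's initial distribution, and the mode of the
# per-combination maximum-posterior states at the target becomes the call.

# Per-gene index structures reused across targets: ordered unique
# positions and the table row indices hosted at each.
gene_index <- function(table) {
  idx <- split(seq_len(nrow(table)), table$gene)
  lapply(idx, function(rows) {
    by_pos <- split(rows, table$pos[rows])
    ord <- order(as.numeric(names(by_pos)))
    list(positions = as.numeric(names(by_pos))[ord],
         rows = by_pos[ord])
  })
}

as_assignments <- function(x) {
  if (inherits(x, "varstates_annotation")) x$assignments else x
}

resolve_target <- function(table, target) {
  if (is.numeric(target)) {
    if (target < 1L || target > nrow(table)) stop("target row out of range")
    return(as.integer(target))
  }
  hit <- which(variant_key(table) == target)
  if (length(hit) == 0L) stop("target variant not found in table")
  hit[1L]
}

#' Sample local combinations around a target variant
#'
#' Builds `N` observation sequences covering up to `k` positions upstream
#' and `k` downstream of the target within its gene (truncated at gene
#' ends).  The target's own row is fixed in every combination; each
#' flanking position contributes one of its variant rows, drawn uniformly
#' at random.
#'
#' @param table a variant table.
#' @param codes ternary code matrix aligned to `table`.
#' @param target row index into `table`, or a `"chrom:pos:ref:alt"` key.
#' @param k flanking positions per side (`k >= 0`).
#' @param N number of combinations.
#' @param seed integer seed, or `NULL` to use the session RNG.
#' @return A list of `N` elements, each with `codes` (the window's code
#'   matrix), `rows` (the chosen table rows) and `center` (the target's
#'   index within the window).
#' @export
local_combinations <- function(table, codes, target, k = 3L, N = 9L,
                               seed = NULL) {
  check_variant_table(table)
  codes <- check_codes(codes)
  if (k < 0L) stop("k must be >= 0")
  if (N < 1L) stop("N must be >= 1")
  target <- resolve_target(table, target)
  gidx <- gene_index(table)[[table$gene[target]]]
  with_seed(seed, {
    draw_combinations(gidx, target, table$pos[target], codes, k, N)
  })
}

draw_combinations <- function(gidx, target_row, target_pos, codes, k, N) {
  i <- match(target_pos, gidx$positions)
  lo <- max(1L, i - k)
  hi <- min(length(gidx$positions), i + k)
  window <- lo:hi
  center <- i - lo + 1L
  lapply(seq_len(N), function(c_) {
    rows <- vapply(window, function(j) {
      if (j == i) target_row else sample_one(gidx$rows[[j]])
    }, numeric(1))
    rows <- as.integer(rows)
    list(codes = codes[rows, , drop = FALSE], rows = rows, center = center)
  })
}

#' Assign a state to one variant by the mode over local combinations
#'
#' For each of `N` local combinations the forward-backward posterior at
#' the target position is computed and its maximum-posterior state taken
#' (ties toward the lowest state index).  The final call is the mode of
#' the `N` per-combination states; mode ties are broken uniformly at
#' random.
#'
#' @inheritParams local_combinations
#' @param model a `varhmm` model with `M` matching `codes`.
#' @return A one-row data frame with `state`, `n_mode_votes`,
#'   `tie_broken` and `max_posterior` (mean over combinations of the
#'   center-position maximum posterior).
#' @export
assign_state <- function(model, table, codes, target, k = 3L, N = 9L,
                         seed = NULL) {
  validate_hmm(model)
  codes <- check_codes(codes)
  if (ncol(codes) != model$M) stop("codes width must equal the model's M")
  target <- resolve_target(table, target)
  gidx <- gene_index(table)[[table$gene[target]]]
  LB <- emission_likelihood_matrix(model, codes)
  with_seed(seed, {
    as.data.frame(vote_state(model, gidx, target, table$pos[target],
                             codes, LB, k, N))
  })
}

# Core voting routine; assumes the RNG is already seeded by the caller.
vote_state <- function(model, gidx, target_row, target_pos, codes, LB,
                       k, N) {
  combos <- draw_combinations(gidx, target_row, target_pos, codes, k, N)
  votes <- integer(model$K)
  maxpost <- 0
  for (cb in combos) {
    fb <- .fb_cpp(model$initial, model$transition,
                  LB[cb$rows, , drop = FALSE])
    g <- fb$gamma[cb$center, ]
    s <- which.max(g)  # ties toward the lowest state index
    votes[s] <- votes[s] + 1L
    maxpost <- maxpost + g[s]
  }
  top <- which(votes == max(votes))
  tie <- length(top) > 1L
  state <- if (tie) sample_one(top) else top
  list(state = as.integer(state), n_mode_votes = max(votes),
       tie_broken = tie, max_posterior = maxpost / N)
}

#' Annotate every variant in a table with a state
#'
#' Applies the window-based mode assignment of [assign_state()] to every
#' variant row (all alternate alleles, not one per position) and computes
#' the run-length segmentation of the assignments within each gene.
#'
#' @inheritParams assign_state
#' @param seed integer seed; a fixed seed makes the full annotation
#'   reproducible.
#' @return A list of class `varstates_annotation` with `assignments` (a
#'   data frame: `chrom`, `pos`, `ref`, `alt`, `gene`, `state`,
#'   `n_mode_votes`, `tie_broken`, `max_posterior`, aligned to `table`
#'   rows) and `segments` (see [segment_states()]).
#' @export
annotate_variants <- function(model, table, codes, k = 3L, N = 9L,
                              seed = 1L) {
  validate_hmm(model)
  check_variant_table(table)
  codes <- check_codes(codes)
  if (ncol(codes) != model$M) stop("codes width must equal the model's M")
  if (nrow(codes) != nrow(table)) {
    stop("codes must have one row per variant table row")
  }
  if (k < 0L) stop("k must be >= 0")
  if (N < 1L) stop("N must be >= 1")
  gidx_all <- gene_index(table)
  LB <- emission_likelihood_matrix(model, codes)
  n <- nrow(table)
  state <- integer(n); nvotes <- integer(n)
  tie <- logical(n); mp <- numeric(n)
  with_seed(seed, {
    for (v in seq_len(n)) {
      res <- vote_state(model, gidx_all[[table$gene[v]]], v, table$pos[v],
                        codes, LB, k, N)
      state[v] <- res$state
      nvotes[v] <- res$n_mode_votes
      tie[v] <- res$tie_broken
      mp[v] <- res$max_posterior
    }
  })
  assignments <- data.frame(
    chrom = table$chrom, pos = table$pos, ref = table$ref,
    alt = table$alt, gene = table$gene, state = state,
    n_mode_votes = nvotes, tie_broken = tie, max_posterior = mp,
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 segments = segment_states(assignments)),
            class = "varstates_annotation")
}

#' @export
print.varstates_annotation <- function(x, ...) {
  cat("State annotation of ", nrow(x$assignments), " variants in ",
      length(unique(x$assignments$gene)), " genes\n", sep = "")
  cat("  segments: ", nrow(x$segments), ", mean length ",
      format(mean(x$segments$length), digits = 4), " variants\n", sep = "")
  invisible(x)
}

#' Run-length segmentation of state assignments
#'
#' Maximal runs of consecutive variants assigned the same state within a
#' gene, over the assignment table ordered by `(gene, pos, ref, alt)`.
#' Runs tile each gene's variants without gaps or overlaps, so the
#' segmentation is a lossless run-length encoding of the assignments.
#'
#' @param assignments an assignment data frame (from
#'   [annotate_variants()]`$assignments`).
#' @param unique_positions if `TRUE`, keep only the first alternate allele
#'   at each (gene, position) before computing runs, so runs are over
#'   positions rather than over all variant rows.
#' @return Data frame with `gene`, `start` and `end` (indices into the
#'   gene's ordered variants), `state` and `length`.
#' @export
segment_states <- function(assignments, unique_positions = FALSE) {
  assignments <- as_assignments(assignments)
  ord <- order(assignments$gene, assignments$pos, assignments$ref,
               assignments$alt)
  a <- assignments[ord, , drop = FALSE]
  if (unique_positions) {
    a <- a[!duplicated(a[, c("gene", "pos")]), , drop = FALSE]
  }
  out <- lapply(split(a$state, a$gene), function(s) {
    r <- rle(s)
    ends <- cumsum(r$lengths)
    data.frame(start = ends - r$lengths + 1L, end = ends,
               state = r$values, length = r$lengths)
  })
  res <- do.call(rbind, Map(function(g, d) cbind(gene = g, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Compare two state assignments of the same variants
#'
#' Reports, for each state of assignment `a`, the fraction of its
#' variants assigned a different state in `b` (plus the mean over states
#' and over variants), segment counts and mean segment lengths for both
#' segmentations, and a one-sided Mann-Whitney U test of whether `a`'s
#' segment lengths are stochastically larger than `b`'s.  When the two
#' assignments are identical the switch fractions are 0 and the one-sided
#' test is at its null boundary (p = 0.5 up to ties).
#'
#' @param a,b assignment data frames covering the same variant keys.
#' @param unique_positions passed to [segment_states()].
#' @return A list with `per_state` (data frame: `state`, `n`,
#'   `switch_fraction`), `mean_switch_fraction` (over states),
#'   `variant_switch_fraction` (over variants), `segments_a`/`segments_b`
#'   (count and mean length), and `segment_length_p` (Mann-Whitney U,
#'   alternative: `a` longer).
#' @export
compare_assignments <- function(a, b, unique_positions = FALSE) {
  a <- as_assignments(a)
  b <- as_assignments(b)
  ka <- variant_key(a); kb <- variant_key(b)
  m <- match(ka, kb)
  if (anyNA(m) || length(ka) != length(kb)) {
    stop("assignments a and b must cover the same variant keys")
  }
  sa <- a$state
  sb <- b$state[m]
  per_state <- do.call(rbind, lapply(sort(unique(sa)), function(s) {
    sel <- sa == s
    data.frame(state = s, n = sum(sel),
               switch_fraction = mean(sb[sel] != s))
  }))
  seg_a <- segment_states(a, unique_positions)
  seg_b <- segment_states(b, unique_positions)
  p <- suppressWarnings(
    wilcox.test(seg_a$length, seg_b$length,
                alternative = "greater")$p.value)
  list(per_state = per_state,
       mean_switch_fraction = mean(per_state$switch_fraction),
       variant_switch_fraction = mean(sa != sb),
       segments_a = list(n = nrow(seg_a), mean_length = mean(seg_a$length)),
       segments_b = list(n = nrow(seg_b), mean_length = mean(seg_b$length)),
       segment_length_p = p)
}
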