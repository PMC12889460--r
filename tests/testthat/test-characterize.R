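test_that("state summaries count top-rank memberships and group states", {
  # K <= 5: every state is within the top 5 for every score
  m <- hmm_model(c(0.5, 0.5), matrix(0.5, 2, 2),
                 rbind(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3)))
  s <- summarize_states(m)
  expect_equal(s$top_count, c(3L, 3L))

  # one state ranked 6th everywhere: no memberships, group 4
  em <- rbind(matrix(0.9, 5, 10) + matrix(runif(50), 5, 10) * 0.05,
              rep(0.1, 10))
  m6 <- hmm_model(rep(1 / 6, 6), matrix(1 / 6, 6, 6), em)
  s6 <- summarize_states(m6)
  expect_equal(s6$top_count[6], 0L)
  expect_equal(s6$group[6], 4L)
  expect_equal(s6$display_order[6], 6L)

  # identical emission rows share every membership through min-rank ties
  m_tie <- hmm_model(rep(1 / 6, 6), matrix(1 / 6, 6, 6),
                     matrix(0.4, 6, 8))
  expect_equal(summarize_states(m_tie)$top_count, rep(8L, 6))

  # display order is a permutation, descending in top_count
  expect_setequal(s6$display_order, 1:6)
  expect_true(all(diff(s6$top_count[order(s6$display_order)]) <= 0))
})

test_that("state grouping follows the configured thresholds", {
  em <- rbind(rep(0.9, 20), rep(0.5, 20), rep(0.1, 20))
  m <- hmm_model(rep(1 / 3, 3), matrix(1 / 3, 3, 3), em)
  # distinct rows, K=3 <= 5: all states have 20 memberships -> group 1
  s <- summarize_states(m, group_thresholds = c(5, 15))
  expect_equal(s$group, rep(1L, 3))
  s2 <- summarize_states(m, group_thresholds = c(21, 25))
  expect_equal(s2$group, rep(3L, 3))
})

make_assignment <- function(n, states, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_len(n) * 10L, ref = "A", alt = "C",
             gene = "G1", state = states, stringsAsFactors = FALSE)
}

test_that("fold enrichment follows the count formula and identities", {
  # state 1's variants all inside the annotation, which covers half of all
  a <- make_assignment(8, rep(c(1L, 2L), each = 4))
  iv <- data.frame(chrom = "chr1", start = 0L, end = 45L)  # pos 10..40
  enr <- fold_enrichment(a, iv)
  expect_equal(enr$fold[enr$state == 1], 2.0)
  expect_equal(enr$fold[enr$state == 2], 0.0)
  expect_equal(sum(enr$B_sa), unique(enr$B_a))
  expect_equal(sum(enr$B_s), unique(enr$B_total))

  # annotation covering everything: every fold exactly 1
  iv_all <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  enr_all <- fold_enrichment(a, iv_all)
  expect_equal(enr_all$fold, c(1, 1))

  # empty state never occurs; zero-overlap annotation gives B_a = 0 -> NA
  iv_none <- data.frame(chrom = "chr2", start = 0L, end = 10L)
  enr_none <- fold_enrichment(a, iv_none)
  expect_true(all(is.na(enr_none$fold)))

  expect_error(fold_enrichment(a, data.frame(chrom = "chr1", start = 5L,
                                             end = 5L)),
               "malformed intervals")
})

test_that("half-open interval edges follow BED conventions", {
  a <- make_assignment(3, c(1L, 1L, 2L))  # positions 10, 20, 30
  # interval [9, 10) covers 1-based position 10 only
  enr <- fold_enrichment(a, data.frame(chrom = "chr1", start = 9L,
                                       end = 10L))
  expect_equal(enr$B_sa[enr$state == 1], 1L)
  # interval [10, 11) covers position 11, not 10
  enr2 <- fold_enrichment(a, data.frame(chrom = "chr1", start = 10L,
                                        end = 11L))
  expect_equal(sum(enr2$B_sa), 0L)
})

test_that("null enrichment hovers around 1", {
  set.seed(91)
  n <- 10000
  a <- data.frame(chrom = "chr1", pos = sample.int(1e6, n), ref = "A",
                  alt = "C", gene = "G1",
                  state = sample(1:4, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  # random annotation covering ~ half the coordinate space
  starts <- seq(0L, 999000L, by = 2000L)
  iv <- data.frame(chrom = "chr1", start = starts, end = starts + 1000L)
  enr <- fold_enrichment(a, iv)
  expect_true(all(enr$B_s >= 500))
  expect_true(all(abs(enr$fold - 1) < 0.1))
})

test_that("enrichment counts respect the designed state footprint", {
  sim <- small_sim()
  iv <- state_footprint_intervals(sim, states = 1L)
  truth <- data.frame(chrom = sim$table$chrom, pos = sim$table$pos,
                      ref = sim$table$ref, alt = sim$table$alt,
                      gene = sim$table$gene, state = sim$states,
                      stringsAsFactors = FALSE)
  enr <- fold_enrichment(truth, iv)
  f1 <- enr$fold[enr$state == 1]
  expect_equal(enr$B_sa[enr$state == 1], enr$B_s[enr$state == 1])
  expect_gt(f1, 1)  # = B_total / B_a by construction
  expect_equal(f1, enr$B_total[1] / enr$B_a[1])
})

test_that("substitution preferences are zero-sum deltas per state", {
  tab <- data.frame(chrom = "chr1", pos = 1:8, ref = "A", alt = "C",
                    gene = "G1",
                    aaref = c("P", "P", "P", "P", "A", "A", "G", "G"),
                    aaalt = c("L", "L", "L", "L", "V", "V", "S", "S"),
                    stringsAsFactors = FALSE)
  # state 1 holds all P->L rows; states split the rest evenly
  a <- cbind(tab[, c("chrom", "pos", "ref", "alt", "gene")],
             state = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L))
  sp <- substitution_preferences(a, tab)
  s1 <- sp[sp$state == 1, ]
  # hand computation: state 1 has 6 rows (4 P->L, 1 A->V, 1 G->S)
  expect_equal(s1$delta[s1$substitution == "P->L"], 4 / 6 - 4 / 8)
  expect_equal(s1$fold[s1$substitution == "P->L"], (4 / 6) / (4 / 8))
  for (s in unique(sp$state)) {
    expect_equal(sum(sp$delta[sp$state == s]), 0, tolerance = 1e-12)
  }

  # single state: state proportions equal the background, all deltas 0
  a1 <- cbind(tab[, c("chrom", "pos", "ref", "alt", "gene")],
              state = rep(1L, 8))
  sp1 <- substitution_preferences(a1, tab)
  expect_equal(sp1$delta, rep(0, nrow(sp1)))
  expect_equal(sp1$fold, rep(1, nrow(sp1)))

  # missing amino acids are excluded and counted
  tab$aaref[1] <- NA
  sp2 <- substitution_preferences(a, tab)
  expect_equal(attr(sp2, "n_excluded"), 1L)
})

test_that("model comparison is exact on self- and permuted copies", {
  set.seed(101)
  m <- rand_model(K = 5, M = 12)
  self <- compare_models(m, m)
  expect_equal(self$correlation, rep(1, 5))
  expect_equal(self$best_match, 1:5)

  perm <- c(3L, 1L, 5L, 2L, 4L)
  mp <- m
  mp$emission <- m$emission[perm, ]
  # state i of m sits at position which(perm == i) in mp
  res <- compare_models(m, mp)
  expect_equal(res$correlation, rep(1, 5))
  expect_equal(res$best_match, match(1:5, perm))

  # flipping one state's emissions breaks its match
  mf <- m
  mf$emission[2, ] <- 1 - mf$emission[2, ]
  res2 <- compare_models(m, mf)
  expect_lt(res2$correlation[2], 1)
  expect_equal(res2$correlation[2],
               max(cor(m$emission[2, ], t(mf$emission))))

  m2 <- rand_model(K = 2, M = 5)
  expect_error(compare_models(m, m2), "same number of features")
})
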