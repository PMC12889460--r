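# Shared synthetic evaluation fixture: a moderate dataset with known
# per-state effects on labels and DMS values.
eval_fixture <- function(b_state, d_state = b_state, n_genes = 60,
                         noise_sd = 0.3, seed = 7) {
  model <- simulate_model(K = 4, M = 8, stickiness = 0.6, seed = seed)
  sim <- simulate_dataset(model, n_genes = n_genes,
                          positions_per_gene = 40, alts_per_position = 1,
                          missing_rate = 0, Q = 10, seed = seed + 1)
  lab <- simulate_labels_and_dms(sim$table, sim$states, b_state = b_state,
                                 d_state = d_state, noise_sd = noise_sd,
                                 seed = seed + 2)
  lab
}

test_that("classification sets are balanced, disjoint and seeded", {
  set.seed(3)
  pos <- data.frame(chrom = "chr1", pos = 1:100, ref = "A", alt = "C",
                    score = runif(100), state = sample(1:3, 100, TRUE),
                    stringsAsFactors = FALSE)
  neg <- data.frame(chrom = "chr1", pos = c(1:50, 1001:11000), ref = "A",
                    alt = "C", score = runif(10050),
                    state = sample(1:3, 10050, TRUE),
                    stringsAsFactors = FALSE)
  set <- prepare_classification_set(pos, neg, seed = 1)
  expect_equal(sum(set$label == 1), 100L)
  expect_equal(sum(set$label == 0), 100L)
  # overlapping keys (pos 1..50) were excluded before sampling
  negk <- paste(set$chrom, set$pos, sep = ":")[set$label == 0]
  expect_false(any(negk %in% paste("chr1", 1:100, sep = ":")))
  set2 <- prepare_classification_set(pos, neg, seed = 1)
  expect_identical(set, set2)
  expect_error(prepare_classification_set(pos, neg[1:80, ], "fewer"))
})

test_that("a perfectly separating score leaves no room for improvement", {
  set.seed(5)
  n <- 400
  set <- data.frame(label = rep(0:1, each = n / 2),
                    s = rep(0:1, each = n / 2) + rnorm(n, 0, 1e-6),
                    state = sample(1:3, n, TRUE))
  res <- paired_classification_eval(set, "s", seed = 1)
  expect_equal(res$auroc_score_only, 1.0)
  expect_equal(res$auroc_with_states, 1.0)
  expect_equal(res$percent_improvement, 0.0)
})

test_that("state-independent labels given score yield ~ zero improvement", {
  lab <- eval_fixture(b_state = rep(0, 4))$labeled
  imp <- vapply(1:8, function(s) {
    paired_classification_eval(lab, "score", seed = s)$percent_improvement
  }, numeric(1))
  expect_lt(abs(mean(imp)), 2)
})

test_that("strong state main effects lift the AUROC", {
  lab <- eval_fixture(b_state = c(-2, -0.7, 0.7, 2))$labeled
  res <- paired_classification_eval(lab, "score", seed = 1)
  expect_gt(res$percent_improvement, 5)
  expect_gt(res$auroc_with_states, res$auroc_score_only)
})

test_that("missing scores are dropped and counted", {
  lab <- eval_fixture(b_state = rep(0, 4))$labeled
  lab$score[1:50] <- NA
  res <- paired_classification_eval(lab, "score", seed = 1)
  expect_equal(res$n_dropped, 50L)
  expect_equal(res$n_used, nrow(lab) - 50L)
  expect_error(paired_classification_eval(lab, "nope"), "no such score")
})

test_that("an affine measurement is predicted perfectly either way", {
  set.seed(11)
  d <- data.frame(measurement = "m1", value = NA, score = runif(200),
                  state = sample(1:3, 200, TRUE))
  d$value <- 2 * d$score + 1
  res <- paired_regression_eval(d, "score", seed = 1)
  expect_equal(res$spearman_score_only, 1.0, tolerance = 1e-8)
  expect_equal(res$spearman_with_states, 1.0, tolerance = 1e-8)
})

test_that("state offsets in the measurement reward the state features", {
  dms <- eval_fixture(b_state = rep(0, 4), d_state = c(-1, 0, 0.5, 1.5),
                      noise_sd = 0.3)$dms
  dms$measurement <- "all"  # one pooled measurement, n = 2400
  res <- paired_regression_eval(dms, "score", seed = 1)
  expect_gt(res$spearman_with_states, res$spearman_score_only)
  expect_gt(res$percent_improvement, 5)
})

test_that("shuffled measurements give near-zero correlation both ways", {
  set.seed(13)
  d <- data.frame(measurement = "m1", value = rnorm(5000),
                  score = runif(5000), state = sample(1:4, 5000, TRUE))
  res <- paired_regression_eval(d, "score", seed = 1)
  expect_lt(abs(res$spearman_score_only), 0.05)
  expect_lt(abs(res$spearman_with_states), 0.05)
})

test_that("degenerate measurements are skipped with a message", {
  d <- data.frame(measurement = rep(c("const", "tiny"), c(40, 4)),
                  value = c(rep(1, 40), rnorm(4)),
                  score = runif(44), state = 1L)
  expect_message(res <- paired_regression_eval(d, "score", seed = 1),
                 "skipped")
  expect_null(res)
})

test_that("per-state conditional positive rates are recovered", {
  set.seed(17)
  rates <- c(0.9, 0.5, 0.1)
  n_per <- 1000
  set <- data.frame(state = rep(1:3, each = 2 * n_per),
                    score = rep(c(0.95, 0.5), times = 3 * n_per))
  set$label <- ifelse(set$score > 0.9,
                      rbinom(nrow(set), 1, rates[set$state]), 0L)
  res <- conditional_positive_probability(set, "score", threshold = 0.9)
  expect_equal(res$per_state$probability, rates, tolerance = 0.03)
  expect_equal(res$per_state$n, rep(n_per, 3))
  expect_equal(res$mean, mean(res$per_state$probability))

  # a state with nothing above the threshold is reported missing
  set$score[set$state == 2] <- 0.5
  res2 <- conditional_positive_probability(set, "score", threshold = 0.9)
  expect_true(is.na(res2$per_state$probability[2]))

  # weighted recombination recovers the overall positive rate
  qual <- set$score > 0.9
  overall <- mean(set$label[qual] == 1)
  w <- res2$per_state$n / sum(res2$per_state$n)
  expect_equal(sum(w * res2$per_state$probability, na.rm = TRUE), overall)
})

test_that("rank profiles align predictors with DMS by state", {
  set.seed(19)
  n <- 300
  x <- data.frame(protein = "P1", state = sample(1:3, n, TRUE),
                  dms = runif(n))
  x$good <- x$dms                      # identical to the measurement
  x$bad <- -x$dms                      # reversed
  res <- rank_by_state(x, c("good", "bad"))
  expect_equal(unname(res$predictor_dms_cor["good"]), 1.0)
  expect_equal(unname(res$predictor_dms_cor["bad"]), -1.0)
  expect_true(all(res$state_dms_rank >= 0 & res$state_dms_rank <= 1))
  expect_true(all(res$state_predictor_rank >= 0 &
                  res$state_predictor_rank <= 1))
  # the aligned predictor tops the leaderboard
  expect_equal(unname(res$leaderboard["good"]), 1)
  expect_equal(unname(res$leaderboard["bad"]), 2)
})

test_that("per-state average ranks match a hand-computed toy table", {
  # 3 states, 2 predictors, 6 variants in one protein; low value = damaging
  x <- data.frame(protein = "P1",
                  state = c(1, 1, 2, 2, 3, 3),
                  dms = c(1, 2, 3, 4, 5, 6),
                  p1 = c(1, 2, 3, 4, 5, 6),
                  p2 = c(6, 5, 4, 3, 2, 1))
  res <- rank_by_state(x, c("p1", "p2"))
  # scaled DMS ranks: 1, .8, .6, .4, .2, 0 -> state means .9, .5, .1
  expect_equal(unname(res$state_dms_rank), c(0.9, 0.5, 0.1))
  expect_equal(unname(res$state_predictor_rank[, "p1"]), c(0.9, 0.5, 0.1))
  expect_equal(unname(res$state_predictor_rank[, "p2"]), c(0.1, 0.5, 0.9))
  expect_equal(unname(res$predictor_dms_cor), c(1, -1))

  # proteins with a single variant are excluded with a message
  x2 <- rbind(x, data.frame(protein = "P2", state = 1, dms = 1,
                            p1 = 1, p2 = 1))
  expect_message(res2 <- rank_by_state(x2, c("p1", "p2")), "excluded")
  expect_equal(unname(res2$state_dms_rank), c(0.9, 0.5, 0.1))
})
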