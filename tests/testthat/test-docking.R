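# exhaustive brute-force F1 sweep over all cut positions
f1_oracle <- function(actives, inactives) {
  cuts <- sort(unique(c(actives, inactives)))
  cuts <- sort(unique(c(cuts, cuts - 1e-9, cuts + 1e-9,
                        min(cuts) - 1, max(cuts) + 1)))
  best <- 0
  for (t in cuts) {
    tp <- sum(actives <= t); fp <- sum(inactives <= t)
    fn <- length(actives) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    if (f1 > best) best <- f1
  }
  best
}

test_that("perfect separation calibrates to F1 = 1 between the classes", {
  cal <- best_f1_threshold(c(-9, -8), c(-5, -4))
  expect_equal(cal$best_f1, 1)
  expect_gt(cal$threshold, -8)
  expect_lt(cal$threshold, -5)
  expect_equal(cal$threshold, -6.5)    # midpoint, permissive tie rule
  expect_equal(cal$precision_at_best, 1)
  expect_equal(cal$recall_at_best, 1)
})

test_that("overlapping classes: known best F1 and threshold region", {
  cal <- best_f1_threshold(c(-9, -6, -5), c(-7, -4, -3))
  expect_equal(cal$best_f1, 6 / 7, tolerance = 1e-12)
  # the chosen threshold classifies exactly as t = -5 does
  expect_gte(cal$threshold, -5)
  expect_lt(cal$threshold, -4)
  expect_equal(cal$precision_at_best, 3 / 4)
  expect_equal(cal$recall_at_best, 1)
})

test_that("F1 at the chosen threshold dominates the whole sweep", {
  set.seed(21)
  cal <- best_f1_threshold(rnorm(30, -7), rnorm(60, -5.5))
  expect_equal(cal$best_f1, max(cal$sweep_table$f1))
  expect_true(all(cal$best_f1 >= cal$sweep_table$f1))
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(cal$best_f1,
               2 * cal$precision_at_best * cal$recall_at_best /
                 (cal$precision_at_best + cal$recall_at_best))
})

test_that("calibration equals the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:50) {
    na <- sample(3:15, 1); ni <- sample(3:15, 1)
    act <- round(rnorm(na, -7, 1.2), 2)
    ina <- round(rnorm(ni, -5.5, 1.2), 2)
    cal <- best_f1_threshold(act, ina)
    expect_equal(cal$best_f1, f1_oracle(act, ina), tolerance = 1e-12,
                 info = paste("instance", i))
  }
})

test_that("degenerate calibrations are flagged", {
  cal <- best_f1_threshold(rep(-5, 3), rep(-5, 4))
  expect_true(cal$degenerate)
  expect_error(best_f1_threshold(numeric(0), -5), "nonempty")
})

test_that("separation diagnostics: extremes, identity, and U oracle", {
  d <- separation_diagnostics(c(-9, -8), c(-5, -4))
  expect_true(d$U %in% c(0, 4))       # complete separation is extremal
  x <- c(1, 2, 3, 4)
  expect_equal(separation_diagnostics(x, x)$p, 1)
  # U equals the pairwise-comparison counting oracle
  set.seed(41)
  for (i in 1:100) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    d <- separation_diagnostics(a, b)
    u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(d$U, u_oracle, info = paste("instance", i))
  }
})

test_that("gating is the conjunction of prediction and all thresholds", {
  scores <- rbind(
    data.frame(compound_id = c("a", "b", "c"), target_id = "T1",
               score = c(-8, -8, -5)),
    data.frame(compound_id = c("a", "b", "c"), target_id = "T2",
               score = c(-9, -6, -9)))
  cal <- list(T1 = -6, T2 = -7)
  out <- gate_candidates(scores, cal, c("a", "b"))
  expect_equal(out$survivors, "a")   # b fails T2, c not predicted
  # boundary: score equal to threshold passes (<= convention)
  scores$score[1] <- -6
  out2 <- gate_candidates(scores, cal, c("a", "b"))
  expect_equal(out2$survivors, "a")
})

test_that("funnel fractions recover a planted cascade", {
  ids <- sprintf("c%02d", 1:40)
  # 50% pass T1; of those, 50% pass T2
  s1 <- ifelse(seq_along(ids) <= 20, -8, -4)
  s2 <- ifelse(seq_along(ids) %% 2 == 1, -8, -4)
  scores <- rbind(
    data.frame(compound_id = ids, target_id = "T1", score = s1),
    data.frame(compound_id = ids, target_id = "T2", score = s2))
  out <- gate_candidates(scores, list(T1 = -6, T2 = -6), ids)
  expect_equal(out$funnel$fraction[out$funnel$stage == "dock_T1"], 0.5)
  expect_equal(out$funnel$fraction[out$funnel$stage == "dock_T2"], 0.5)
  expect_equal(length(out$survivors), 10)
})

test_that("missing scores drop candidates with a warning", {
  scores <- data.frame(compound_id = "a", target_id = "T1", score = -9)
  expect_warning(
    out <- gate_candidates(scores, list(T1 = -6), c("a", "zzz")),
    "lack a T1 score")
  expect_equal(out$survivors, "a")
})

test_that("synthetic scores honour medians, seed, and input checks", {
  sc <- synth_scores(n_active = 2000, n_inactive = 2000,
                     median_active = -6.93, median_inactive = -5.64,
                     spread = 1, seed = 5)
  act <- sc$score[sc$label == "active"]
  ina <- sc$score[sc$label == "inactive"]
  expect_lt(abs(median(act) - (-6.93)), 3 / sqrt(2000))
  expect_lt(abs(median(ina) - (-5.64)), 3 / sqrt(2000))
  expect_identical(synth_scores(seed = 8), synth_scores(seed = 8))
  expect_error(synth_scores(n_active = 0), "at least one")
  expect_error(synth_scores(spread = 0), "spread")
})
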