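# Brute-force Bernoulli NB posterior by explicit joint probabilities,
# kept deliberately independent of the package's log-space implementation.
nb_oracle <- function(active_fp, inactive_fp, alpha, query) {
  n_bits <- ncol(active_fp)
  lik <- function(fps, q) {
    p <- (colSums(fps) + alpha) / (nrow(fps) + 2 * alpha)
    prod(ifelse(q == 1, p, 1 - p))
  }
  pa <- nrow(active_fp) / (nrow(active_fp) + nrow(inactive_fp))
  ja <- lik(active_fp, query) * pa
  ji <- lik(inactive_fp, query) * (1 - pa)
  ja / (ja + ji)
}

test_that("posterior matches the hand-computed two-bit case", {
  # 1 active with bit 1, 1 inactive with bit 2, alpha = 1, query {1}:
  # p(b1|act) = 2/3, p(b2|act) = 1/3, p(b1|ina) = 1/3, p(b2|ina) = 2/3
  # P(act|q) = (2/3)(2/3) / ((2/3)(2/3) + (1/3)(1/3)) = 4/5
  act <- matrix(c(1, 0), nrow = 1)
  ina <- matrix(c(0, 1), nrow = 1)
  m <- nb_train(act, ina, alpha = 1, threshold_mode = "fixed")
  expect_equal(nb_posterior(m, c(1, 0)), 0.8, tolerance = 1e-12)
})

test_that("symmetric classes with equal priors give posterior 0.5", {
  act <- matrix(c(1, 0), nrow = 1)
  ina <- matrix(c(0, 1), nrow = 1)
  m <- nb_train(act, ina, alpha = 1, threshold_mode = "fixed")
  expect_equal(nb_posterior(m, c(1, 1)), 0.5, tolerance = 1e-12)
  expect_equal(nb_posterior(m, c(0, 0)), 0.5, tolerance = 1e-12)
})

test_that("training is deterministic and validates inputs", {
  set.seed(1)
  act <- matrix(rbinom(40, 1, 0.6), nrow = 5)
  ina <- matrix(rbinom(40, 1, 0.2), nrow = 5)
  m1 <- nb_train(act, ina)
  m2 <- nb_train(act, ina)
  expect_identical(m1, m2)
  expect_error(nb_train(act[0, , drop = FALSE], ina), "nonempty")
  expect_error(nb_train(act, ina[, 1:4]), "widths differ")
  expect_error(nb_posterior(m1, rep(1, 5)), "does not match")
})

test_that("posterior equals the exhaustive oracle on 8-bit toys", {
  set.seed(7)
  for (rep in 1:5) {
    act <- matrix(rbinom(5 * 8, 1, runif(1, 0.3, 0.8)), nrow = 5)
    ina <- matrix(rbinom(7 * 8, 1, runif(1, 0.1, 0.5)), nrow = 7)
    m <- nb_train(act, ina, alpha = 1, threshold_mode = "fixed")
    queries <- as.matrix(expand.grid(rep(list(0:1), 8)))
    post <- nb_posterior(m, queries)
    oracle <- apply(queries, 1, function(q) nb_oracle(act, ina, 1, q))
    expect_equal(post, unname(oracle), tolerance = 1e-10)
  }
})

test_that("boundary convention: posterior equal to threshold is active", {
  act <- matrix(c(1, 0), nrow = 1)
  ina <- matrix(c(0, 1), nrow = 1)
  m <- nb_train(act, ina, alpha = 1, threshold_mode = "fixed",
                fixed_threshold = 0.5)
  pred <- nb_predict(m, matrix(c(1, 1), nrow = 1))
  expect_equal(pred$posterior, 0.5)
  expect_true(pred$call)
})

test_that("recall calibration retains at least 99% of training actives", {
  fps <- fixture_fps()
  for (tn in names(fps$actives)) {
    m <- nb_train(fps$actives[[tn]], fps$inactives, target_id = tn)
    pred <- nb_predict(m, fps$actives[[tn]])
    expect_gte(mean(pred$call), 0.99)
  }
})

test_that("chi-square with Yates correction: closed-form cases", {
  res <- chi_square_yates(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # [[30,70],[10,90]]: n=200, |ad-bc|=2000, correction 100 ->
  # 200*1900^2 / (100*100*40*160) = 11.28125
  res2 <- chi_square_yates(matrix(c(30, 10, 70, 90), 2, 2))
  expect_equal(res2$statistic, 11.28125, tolerance = 1e-10)
  # symmetry under simultaneous row and column swap
  tab <- matrix(c(12, 5, 33, 50), 2, 2)
  sw <- tab[2:1, 2:1]
  expect_equal(chi_square_yates(tab)$statistic,
               chi_square_yates(sw)$statistic)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(11)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    mine <- chi_square_yates(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("estimation score: extreme and deterministic cases", {
  lib <- rep(TRUE, 20)
  bg <- rep(FALSE, 100)
  rep1 <- enrichment_report(lib, bg, n_resamples = 200, seed = 3)
  expect_equal(rep1$estimation_score, 0)
  expect_equal(rep1$library_hit_rate, 1)
  rep2 <- enrichment_report(lib, bg, n_resamples = 200, seed = 3)
  expect_identical(unclass(rep1), unclass(rep2))
  # zero-rate library: +Inf sentinel, never enriched, no division by zero
  rep3 <- enrichment_report(rep(FALSE, 20), rep(TRUE, 100),
                            n_resamples = 100, seed = 1)
  expect_identical(rep3$average_ratio, Inf)
  expect_false(rep3$enriched)
  expect_error(enrichment_report(rep(TRUE, 50), rep(TRUE, 30)),
               "larger than the library")
})

test_that("enrichment flag fires for the planted library, not background", {
  fx <- the_fixtures()
  fps <- fixture_fps()
  m <- nb_train(fps$actives$PDE10A, fps$inactives, target_id = "PDE10A")
  bg_calls <- nb_predict(m, fps$background)$call
  # enriched library: held-out-style decorated-core molecules
  lib_calls <- nb_predict(m, fps$actives$A1R)$call
  rep_lib <- enrichment_report(lib_calls, bg_calls, seed = 5)
  expect_true(rep_lib$enriched)
  # library drawn from the background itself: not enriched
  set.seed(6)
  idx <- sample(length(bg_calls), 40)
  rep_null <- enrichment_report(bg_calls[idx], bg_calls, seed = 7)
  expect_false(rep_null$enriched)
})

test_that("multi-target call is the conjunction over targets", {
  fps <- fixture_fps()
  models <- lapply(names(fps$actives), function(tn) {
    nb_train(fps$actives[[tn]], fps$inactives, target_id = tn)
  })
  names(models) <- names(fps$actives)
  fp <- rbind(fps$actives$A1R[1:5, ], fps$inactives[1:5, ])
  calls <- multi_target_calls(models, fp)
  per_target <- as.matrix(
    calls[, grep("^call_", names(calls)), drop = FALSE])
  expect_equal(calls$multi_target, unname(rowSums(per_target) == 3))
})
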