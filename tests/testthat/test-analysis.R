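test_that("min-max normalization maps extremes to 0 and 1 and preserves
           order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(3, 1, 7, 5)
  nx <- minmax_normalize(x)
  expect_equal(nx[which.min(x)], 0)
  expect_equal(nx[which.max(x)], 1)
  expect_identical(order(nx), order(x))
  expect_error(minmax_normalize(rep(2, 5)), "distinct")
})

test_that("z-scoring within groups gives per-group mean 0 and sd 1", {
  z <- zscore_within(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # two identical groups transform identically; matches the formula oracle
  x <- c(5, 9, 13, 5, 9, 13)
  g <- rep(c("a", "b"), each = 3)
  z2 <- zscore_within(x, g)
  expect_equal(z2[1:3], z2[4:6])
  expect_equal(z2[1:3], (x[1:3] - mean(x[1:3])) / sd(x[1:3]))
  expect_error(zscore_within(c(1, 2, 3, 4), c("a", "a", "a", "b")),
               "fewer than 2")
  expect_error(zscore_within(c(1, 1), c("a", "a")), "zero standard")
})

test_that("pearson correlation matches the covariance formula and flags
           degenerate input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  set.seed(3)
  x <- rnorm(50); y <- rnorm(50)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:3), "equal length")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("peak uncertainty equals the maximum of the stored trace", {
  p <- model_parameters()
  tr <- simulate_trial(stimulus_protocol(0.032, "left", 4), p,
                       store_traces = TRUE)
  expect_equal(peak_uncertainty(tr), max(tr$trace$y_HU))
  expect_equal(peak_uncertainty(tr$trace), max(tr$trace$y_HU))
  expect_error(peak_uncertainty(data.frame(a = 1)), "y_HU")
})

test_that("psychometric accuracy split by change-of-mind matches a hand
           tally", {
  toy <- toy_experiment()
  ps <- psychometric_by_com(toy)
  # hand tally: coherence 0, non-CoM trials 1,3,5 -> correct T,F,F
  row <- ps[ps$coherence == 0 & !ps$is_com, ]
  expect_equal(row$mean, 1 / 3)
  expect_equal(row$n, 3L)
  # coherence 0, CoM trials 2,4,6 -> all errors
  row2 <- ps[ps$coherence == 0 & ps$is_com, ]
  expect_equal(row2$mean, 0)
  # coherence 0.256 has no CoM rows: group absent, not an error
  expect_equal(nrow(ps[ps$coherence == 0.256 & ps$is_com, ]), 0)
  expect_equal(sum(ps$n), nrow(toy))
  expect_equal(ps$se, sqrt(ps$mean * (1 - ps$mean) * ps$n / (ps$n - 1)) /
                 sqrt(ps$n), tolerance = 1e-12)
})

test_that("all-correct tables give accuracy one everywhere", {
  toy <- toy_experiment()
  toy$correct <- TRUE
  ps <- psychometric_by_com(toy)
  expect_true(all(ps$mean == 1))
})

test_that("CoM probability by coherence reproduces direct per-coherence
           fractions", {
  toy <- toy_experiment()
  pc <- com_probability_by(toy, "coherence")
  expect_equal(pc$mean[pc$coherence == 0], 0.5)
  expect_equal(pc$mean[pc$coherence == 0.256], 0)
  expect_equal(sum(pc$n), nrow(toy))
})

test_that("tertile boundaries sit at the empirical 1/3 and 2/3 quantiles",
{
  # 9 trials at one coherence with known RT order
  toy <- toy_experiment()[1:6, ]
  toy <- dplyr::bind_rows(toy, dplyr::mutate(toy[1:3, ],
                                             trial = 13:15,
                                             response_time = c(1, 2, 3),
                                             is_com = FALSE,
                                             n_reversals = 0L))
  toy$coherence <- 0
  pc <- com_probability_by(toy, "rt_tertile")
  expect_equal(sort(unique(pc$tertile)), 1:3)
  expect_equal(sum(pc$n), 9)
  expect_true(all(tapply(pc$n, pc$tertile, sum) == 3))
  # oracle: the 3 largest RTs are 250, 300, 400 (all CoM trials)
  expect_equal(pc$mean[pc$tertile == 3], 1)
  expect_equal(pc$mean[pc$tertile == 1], 0)
})

test_that("within-coherence RT tertiles give hand-checkable CoM
           fractions", {
  toy <- toy_experiment()
  pc <- com_probability_by(toy, "rt_tertile")
  # coherence 0 RTs: 10,40 | 70,250 | 300,400 with CoM at 250,300,400
  z <- pc[pc$coherence == 0, ]
  expect_equal(z$mean[z$tertile == 1], 0)
  expect_equal(z$mean[z$tertile == 2], 0.5)
  expect_equal(z$mean[z$tertile == 3], 1)
  expect_error(com_probability_by(toy[1:2, ], "rt_tertile"), "tertile")
})

test_that("uncertainty tertiles are computed on normalized values across
           the run", {
  toy <- toy_experiment()
  pc <- com_probability_by(toy, "uncertainty_tertile")
  # the four highest uncertainties (40, 45, 50 at coherence 0 and 15)
  # contain all CoM trials
  top <- pc[pc$tertile == 3, ]
  expect_equal(sum(top$mean * top$n), 3)
  expect_equal(sum(pc$n), nrow(toy))
})

test_that("uncertainty-by-outcome means match hand-computed group means",
{
  toy <- toy_experiment()
  uc <- uncertainty_by_coherence_outcome(toy, normalize = "none")
  expect_equal(uc$mean[uc$coherence == 0 & uc$correct], 5)
  expect_equal(uc$mean[uc$coherence == 0 & !uc$correct],
               mean(c(40, 10, 45, 15, 50)))
  ucn <- uncertainty_by_coherence_outcome(toy)
  u <- minmax_normalize(toy$peak_uncertainty)
  expect_equal(ucn$mean[ucn$coherence == 0 & ucn$correct],
               mean(u[toy$coherence == 0 & toy$correct]))
})

test_that("summary-curve groups always account for every analysed trial",
{
  ex <- cached_experiment(seed = 1, n_trials = 200)
  analysed <- sum(ex$decided & !ex$com_excluded)
  for (curve in list(psychometric_by_com(ex),
                     com_probability_by(ex, "coherence"),
                     com_probability_by(ex, "rt_tertile"),
                     uncertainty_by_coherence_outcome(ex))) {
    expect_equal(sum(curve$n), analysed)
    expect_true(all(is.finite(curve$mean)))
  }
})

test_that("experiment glance and tidy report consistent run-level rates", {
  ex <- cached_experiment(seed = 1, n_trials = 200)
  g <- glance(ex)
  expect_equal(g$n_trials, nrow(ex))
  expect_equal(g$non_decision_rate, mean(!ex$decided))
  td <- tidy(ex)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$n), nrow(ex))
})
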