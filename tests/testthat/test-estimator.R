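test_that("transition counts follow the daily grid conventions", {
  # 10 subjects all staying in state 1 at day 0
  p <- panel_from_paths(replicate(10, c(1, 1, 7), simplify = FALSE),
                        horizon = 5L)
  n0 <- count_transitions(p, 0)
  expect_equal(n0[1, 1], 10L)
  expect_equal(sum(n0), 10L)

  # absorbed subjects contribute to the absorbing self-count
  n3 <- count_transitions(p, 3)
  expect_equal(n3[7, 7], 10L)

  expect_error(count_transitions(p, 5), "horizon")

  # counts summed over all days = total grid transitions:
  # each subject contributes one transition per day it remains observed
  p2 <- panel_from_paths(list(c(1, 2, 1, 7), c(1, 1, 8), c(1, 5, 6, 6)),
                         horizon = 3L)
  total <- sum(vapply(0:2, function(d) sum(count_transitions(p2, d)),
                      numeric(1)))
  g <- nhsmcea:::state_grid(p2)
  expect_equal(total, sum(!is.na(g[, -1, drop = FALSE])))
})

test_that("single-path and unobserved-state estimation are exact", {
  p <- panel_from_paths(list(c(1, 1, 7)), horizon = 2L)
  fit <- fit_multistate(p, min_at_risk = 1L)
  expect_equal(fit$P[1, 1, 1], 1)
  expect_equal(fit$P[2, 1, 7], 1)
  # nobody enters state 6: its row stays identity at every day
  expect_true(all(fit$P[, 6, 6] == 1))
  # all rows stochastic, absorbing rows unit self-vectors
  expect_true(all(abs(apply(fit$P, c(1, 2), sum) - 1) < 1e-12))
  expect_true(all(fit$P[, 7, 7] == 1) && all(fit$P[, 8, 8] == 1))
})

test_that("sparse rows borrow from adjacent days up to min_at_risk", {
  # 6 subjects exit at day 1 with prob 0.5 overall but only 3 remain at
  # day 1; with min_at_risk = 5 the day-1 row pools days 0-2
  paths <- list(c(1, 7), c(1, 7), c(1, 7), c(1, 1, 7), c(1, 1, 1, 7),
                c(1, 1, 1, 1))
  p <- panel_from_paths(paths, horizon = 3L)
  fit <- fit_multistate(p, min_at_risk = 5L)
  # day 1 raw: 3 at risk (1 exits). borrowed: day0 (6, 3 exit) + day2
  # (2, 1 exits) -> 11 at risk, 5 exits
  expect_equal(fit$P[2, 1, 7], 5 / 11)
  expect_equal(fit$at_risk[2, 1], 3)
})

test_that("occupancy curves match closed forms and conserve mass", {
  ident <- transition_schedule(diag(8), horizon = 10L)
  init <- c(0.4, 0.1, 0, 0, 0.2, 0.1, 0.1, 0.1)
  cv <- occupancy_curve(ident, init)
  expect_true(all(abs(sweep(cv, 2, init)) < 1e-15))

  sch <- toy_exit_schedule(0.5, 10L)
  cv2 <- occupancy_curve(sch)
  expect_equal(as.numeric(cv2[, 1]), 0.5^(0:10))
  expect_true(all(abs(rowSums(cv2) - 1) < 1e-12))
  # absorbing occupancy is monotone non-decreasing
  expect_true(all(diff(cv2[, 7]) >= -1e-15))

  expect_error(occupancy_curve(sch, init = c(1, 1)), "distribution")
})

test_that("observed prevalence is consistent with the model curve", {
  p <- panel_from_paths(list(c(1, 1, 7), c(1, 7), c(1, 2, 7), c(1, 7)),
                        horizon = 12L)
  obs <- observed_prevalence(p)
  expect_equal(obs[13, 7], 1)           # everyone discharged by day 12
  expect_true(all(abs(rowSums(obs) - 1) < 1e-12))

  # simulated panels converge to the generating occupancy curve
  sch <- toy_exit_schedule(0.1, 20L)
  pan <- simulate_cohort(sch, n = 20000, seed = 5)
  obs2 <- observed_prevalence(pan)
  mod2 <- occupancy_curve(sch)
  se <- sqrt(mod2[, 1] * (1 - mod2[, 1]) / 20000)
  expect_true(all(abs(obs2[, 1] - mod2[, 1]) < 4 * se + 1e-12))
})

test_that("expected total LOS credits one day per occupied day", {
  # all mass absorbed into state 7 from day 1 onwards
  sch <- toy_exit_schedule(1, 100L)
  cv <- occupancy_curve(sch)
  expect_equal(expected_total_los(cv, 7), 100)
  # conservation: per-state stays sum to the horizon
  sch2 <- toy_exit_schedule(0.03, 100L)
  cv2 <- occupancy_curve(sch2)
  expect_equal(sum(vapply(1:8, function(s) expected_total_los(cv2, s),
                          numeric(1))), 100)
  # life-expectancy identity: horizon - LOS(death)
  expect_equal(100 - expected_total_los(cv2, 8), 100)  # no deaths in toy
})

test_that("expected visits match brute-force path enumeration", {
  # 2-state toy with return: 1 <-> 2 with symmetric switching, horizon 3
  P <- diag(8)
  P[1, 1] <- 0.6; P[1, 2] <- 0.4
  P[2, 2] <- 0.7; P[2, 1] <- 0.3
  sch <- transition_schedule(P, horizon = 3L)
  for (s in 1:2) {
    expect_equal(expected_visits(sch, s), oracle_expected_visits(sch, s),
                 tolerance = 1e-12)
  }

  # absorbing state entered at most once; equals terminal occupancy
  sch2 <- toy_exit_schedule(0.2, 15L)
  cv <- occupancy_curve(sch2)
  expect_equal(expected_visits(sch2, 7), cv[16, 7])
  expect_lte(expected_visits(sch2, 7), 1)
})

test_that("first passage matches the geometric closed form and the oracle", {
  # constant daily CRBSI hazard 0.001 for 60 days, no other exits
  P <- diag(8)
  P[1, 1] <- 0.999; P[1, 3] <- 0.001
  Parr <- array(0, c(100, 8, 8))
  for (t in 1:100) Parr[t, , ] <- if (t <= 60) P else diag(8)
  sch <- transition_schedule(Parr)
  expect_equal(first_passage_per_1000(sch), 1000 * (1 - 0.999^60),
               tolerance = 1e-12)

  # zero hazard into targets
  expect_equal(first_passage_per_1000(toy_exit_schedule(0.2, 30L)), 0)

  # brute-force oracle on a chain with CRBSI recovery and return
  P2 <- diag(8)
  P2[1, 1] <- 0.7; P2[1, 3] <- 0.2; P2[1, 7] <- 0.1
  P2[3, 1] <- 0.8; P2[3, 3] <- 0; P2[3, 7] <- 0.2
  sch2 <- transition_schedule(P2, horizon = 4L)
  expect_equal(first_passage_per_1000(sch2),
               1000 * oracle_first_passage(sch2, c(3, 4)),
               tolerance = 1e-12)
  # visits to a revisitable state dominate first passage
  expect_gte(expected_visits(sch2, 3),
             first_passage_per_1000(sch2) / 1000)

  expect_error(first_passage_per_1000(sch2, targets = 7), "transient")
})

test_that("estimation recovers the generating matrices (small scale)", {
  cfg <- small_arm_config(n = 4000L, seed = 9L)
  sch <- calibrate_profile(cfg[[1]], horizon = attr(cfg, "horizon"))
  pan <- simulate_cohort(sch, n = 4000, seed = 13)
  # pool sparse days to >= 1000 transitions per row: the generating rows
  # are constant in time (up to the CRBSI cut-off), so borrowing adds no
  # bias and the comparison is a clean variance bound
  fit <- fit_multistate(pan, min_at_risk = 1000L)
  ok <- fit$at_risk >= 500
  err <- 0
  for (t in seq_len(fit$horizon)) {
    for (i in which(ok[t, ])) {
      err <- max(err, max(abs(fit$P[t, i, ] - sch$P[t, i, ])))
    }
  }
  expect_lt(err, 0.05)  # O(1/sqrt(at-risk)) at >= 500 at risk
})

test_that("agreement between panel statistic and model first passage", {
  cfg <- small_arm_config(n = 150L)
  sch <- calibrate_profile(cfg[[1]], horizon = attr(cfg, "horizon"))
  pan <- simulate_cohort(sch, n = 30000, seed = 21)
  fp <- first_passage_per_1000(sch)
  emp <- ever_in_states_per_1000(pan)
  se <- 1000 * sqrt((fp / 1000) * (1 - fp / 1000) / 30000)
  expect_lt(abs(emp - fp), 4 * se)
})
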