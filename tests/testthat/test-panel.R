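test_that("panels validate well-formed data and round-trip through CSV", {
  p <- panel_from_paths(list(c(1, 1, 7)), horizon = 100L)
  expect_s3_class(p, "trajectory_panel")
  expect_equal(n_subjects(p), 1L)
  expect_equal(p$state[nrow(p)], 7L)

  # validation is idempotent
  expect_identical(validate_panel(p), p)

  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  write_panel(p, f)
  expect_equal(as.data.frame(read_panel(f)), as.data.frame(p))
})

test_that("panel validation rejects malformed trajectories", {
  bad_abs <- data.frame(subject = "s", arm = "CHG-T1",
                        day = c(0, 5, 6), state = c(1, 8, 1))
  expect_error(trajectory_panel(bad_abs), "absorbing")

  bad_state <- data.frame(subject = "s", arm = "CHG-T1",
                          day = 0, state = 9)
  expect_error(trajectory_panel(bad_state), "unknown state")

  bad_days <- data.frame(subject = "s", arm = "CHG-T1",
                         day = c(0, 3, 3), state = c(1, 1, 2))
  expect_error(trajectory_panel(bad_days), "duplicate")

  late_start <- data.frame(subject = "s", arm = "CHG-T1",
                           day = c(1, 2), state = c(1, 7))
  expect_error(trajectory_panel(late_start), "day 0")
})

test_that("censoring rules recode post-discharge CRBSI and truncate", {
  # discharged day 10, CRBSI flagged day 12 -> CRBSI occupies day 10,
  # discharge moves to day 11
  raw <- trajectory_panel(
    data.frame(subject = "s1", arm = "PVI-T1",
               day = c(0, 10, 12), state = c(1, 7, 3)),
    horizon = 100L, validate = FALSE)
  cen <- apply_censoring_rules(raw)
  s1 <- as.data.frame(cen)
  expect_equal(s1$state[s1$day == 10], 3L)
  expect_equal(s1$state[s1$day == 11], 7L)
  expect_equal(max(s1$day), 11L)

  # beyond the window: not reassigned, trajectory kept to discharge
  far <- trajectory_panel(
    data.frame(subject = "s2", arm = "PVI-T1",
               day = c(0, 10, 15), state = c(1, 7, 3)),
    horizon = 100L, validate = FALSE)
  expect_warning(cen2 <- apply_censoring_rules(far), "untouched")
  expect_equal(as.data.frame(cen2)$state, c(1L, 7L))

  # within-horizon panel is a no-op
  ok <- panel_from_paths(list(c(1, 2, 7)), horizon = 100L)
  expect_equal(as.data.frame(apply_censoring_rules(ok)),
               as.data.frame(ok))

  # records beyond day 100 are dropped; still-transient subjects censored
  long <- trajectory_panel(
    data.frame(subject = "s3", arm = "PVI-T1",
               day = c(0, 120, 140), state = c(1, 1, 7)),
    horizon = 200L, validate = FALSE)
  cen3 <- apply_censoring_rules(long, horizon = 100L)
  expect_equal(max(cen3$day), 0L)  # only day-0 record survives
  expect_equal(attr(cen3, "horizon"), 100L)

  # never increases subjects, never changes arms
  expect_equal(n_subjects(cen), 1L)
  expect_equal(unique(cen$arm), "PVI-T1")
})

test_that("ever_in_states_per_1000 matches counting and is order invariant", {
  paths <- c(replicate(2, c(1, 3, 7), simplify = FALSE),
             replicate(571, c(1, 1, 7), simplify = FALSE))
  p <- panel_from_paths(paths, horizon = 10L)
  expect_equal(ever_in_states_per_1000(p), 1000 * 2 / 573)
  expect_equal(round(ever_in_states_per_1000(p), 2), 3.49)

  # shuffling record order does not change the statistic
  df <- as.data.frame(p)
  shuffled <- trajectory_panel(df[sample.int(nrow(df)), ], horizon = 10L)
  expect_equal(ever_in_states_per_1000(shuffled),
               ever_in_states_per_1000(p))

  none <- panel_from_paths(list(c(1, 1, 7), c(1, 2, 8)), horizon = 10L)
  expect_equal(ever_in_states_per_1000(none), 0)
  all_hit <- panel_from_paths(list(c(1, 3, 7), c(1, 4, 8)), horizon = 10L)
  expect_equal(ever_in_states_per_1000(all_hit), 1000)
  empty <- trajectory_panel(data.frame(subject = character(),
                                       arm = character(),
                                       day = integer(),
                                       state = integer()))
  expect_error(ever_in_states_per_1000(empty), "empty")
})

test_that("the daily grid applies LOCF and carries absorbing states", {
  p <- trajectory_panel(data.frame(subject = c("a", "a", "a"),
                                   arm = "CHG-T1", day = c(0, 3, 5),
                                   state = c(1, 2, 7)),
                        horizon = 8L)
  g <- nhsmcea:::state_grid(p)
  expect_equal(as.integer(g["a", ]), c(1, 1, 1, 2, 2, 7, 7, 7, 7))

  # censored transient subject leaves the grid after its last record
  q <- trajectory_panel(data.frame(subject = "b", arm = "CHG-T1",
                                   day = c(0, 2), state = c(1, 1)),
                        horizon = 5L)
  gq <- nhsmcea:::state_grid(q)
  expect_equal(as.integer(gq["b", ]), c(1, 1, 1, NA, NA, NA))
})
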