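# cohort summaries built from the published per-arm means, used to
# exercise the comparison arithmetic
published_summaries <- function(variant, costs, effs) {
  arms <- c("PVI-T1", "PVI-T4", "CHG-T1", "CHG-T4")
  stats::setNames(lapply(seq_along(arms), function(i)
    cohort_summary(arms[i], variant, 100L, costs[i], effs[i])), arms)
}

test_that("ICER and dominance reproduce the trade-off arithmetic", {
  s <- published_summaries("simulated_global",
                           costs = c(24874, 24201, 23798, 21822),
                           effs = c(22.37, 22.91, 2.59, 4.86))
  r_pvi4 <- compare_strategies(s[["PVI-T1"]], s[["PVI-T4"]])
  expect_equal(r_pvi4$delta_cost, -673)
  expect_equal(r_pvi4$delta_effectiveness, 0.54, tolerance = 1e-9)
  expect_equal(r_pvi4$dominance, "icer_tradeoff")
  expect_equal(r_pvi4$quadrant, "less costly, less effective")
  expect_equal(round(r_pvi4$icer), 1246)

  r_chg1 <- compare_strategies(s[["PVI-T1"]], s[["CHG-T1"]])
  expect_equal(r_chg1$delta_cost, -1076)
  expect_equal(r_chg1$delta_effectiveness, -19.78)
  expect_equal(r_chg1$dominance, "dominant")
  expect_true(is.na(r_chg1$icer))

  # reflexivity
  same <- compare_strategies(s[["PVI-T1"]], s[["PVI-T1"]])
  expect_equal(same$dominance, "comparable")
  expect_equal(same$delta_cost, 0)

  expect_error(compare_strategies(
    s[["PVI-T1"]],
    cohort_summary("X", "simulated_alive", 100L, 1, 1)), "variant")
})

test_that("comparison is antisymmetric and the ICER scale invariant", {
  grid <- expand.grid(dc = c(-500, 0, 500), de = c(-5, 0, 5))
  for (k in seq_len(nrow(grid))) {
    a <- cohort_summary("A", "observed_global", 100L, 20000, 20)
    b <- cohort_summary("B", "observed_global", 100L,
                        20000 + grid$dc[k], 20 + grid$de[k])
    ab <- compare_strategies(a, b)
    ba <- compare_strategies(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_effectiveness, -ba$delta_effectiveness)
    # dominance partitions the plane deterministically
    expect_true(ab$dominance %in% c("dominant", "dominated",
                                    "icer_tradeoff", "comparable"))
    if (ab$dominance == "dominant") expect_equal(ba$dominance, "dominated")
    if (ab$dominance == "comparable") expect_equal(ba$dominance,
                                                   "comparable")
    if (ab$dominance == "icer_tradeoff" && !ab$icer_undefined) {
      # scaling both deltas leaves the ICER unchanged
      b2 <- cohort_summary("B", "observed_global", 100L,
                           20000 + 3 * grid$dc[k], 20 + 3 * grid$de[k])
      a2 <- cohort_summary("A", "observed_global", 100L, 20000, 20)
      expect_equal(compare_strategies(a2, b2)$icer, ab$icer)
    }
  }
})

test_that("zero effectiveness difference in a trade-off is flagged, not divided", {
  a <- cohort_summary("A", "observed_global", 100L, 20000, 20)
  b <- cohort_summary("B", "observed_global", 100L, 19000, 20)
  r <- compare_strategies(a, b)  # cheaper, equally effective -> dominant
  expect_equal(r$dominance, "dominant")
  expect_false(r$icer_undefined)
})

test_that("significance flags follow the CI-overlap convention", {
  ref <- cohort_summary("PVI-T1", "observed_global", 100L, 23795, 26.04,
                        cost_ci = c(16457, 30662),
                        effectiveness_ci = c(14.64, 42.58))
  alt <- cohort_summary("CHG-T1", "observed_global", 100L, 21927, 3.49,
                        cost_ci = c(14963, 28458),
                        effectiveness_ci = c(0.42, 12.57))
  r <- classify_significance(compare_strategies(ref, alt), ref, alt)
  expect_true(r$ci_overlap_cost)         # costs overlap: not significant
  expect_false(r$ci_overlap_effect)      # effectiveness CIs do not
  expect_match(r$significance, "effectiveness statistically significant",
               fixed = FALSE)

  # identical intervals overlap
  r2 <- classify_significance(compare_strategies(ref, ref), ref, ref)
  expect_true(r2$ci_overlap_cost && r2$ci_overlap_effect)

  # missing CI leaves the flag unset
  noci <- cohort_summary("CHG-T4", "observed_global", 100L, 20612, 6.82)
  expect_message(r3 <- classify_significance(compare_strategies(ref, noci),
                                             ref, noci), "missing")
  expect_true(is.na(r3$ci_overlap_cost))
})

test_that("the horizon contrast subtracts short- from long-horizon cost", {
  mk <- function(arm, cost, horizon)
    cohort_summary(arm, "simulated_global", horizon, cost, 5)
  published <- rbind(
    c(23798, 20772, -3026),   # CHG-T1
    c(21822, 19581, -2241),   # CHG-T4
    c(24874, 21875, -2999),   # PVI-T1
    c(24201, 21246, -2955))   # PVI-T4
  arms <- c("CHG-T1", "CHG-T4", "PVI-T1", "PVI-T4")
  for (i in 1:4) {
    expect_equal(horizon_contrast(mk(arms[i], published[i, 1], 100L),
                                  mk(arms[i], published[i, 2], 30L)),
                 published[i, 3])
  }
  expect_error(horizon_contrast(mk("CHG-T1", 1, 100L),
                                mk("CHG-T4", 1, 30L)), "same arm")
  expect_error(horizon_contrast(mk("CHG-T1", 1, 100L),
                                mk("CHG-T1", 1, 100L)), "shorter")
})
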