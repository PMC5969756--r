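# Shared fixtures and independent oracles, all built in code.

# simple 2-state-in-8 toy: state 1 transient with constant exit prob p to
# state 7, rest stays in 1
toy_exit_schedule <- function(p, horizon) {
  P <- diag(8)
  P[1, 1] <- 1 - p
  P[1, 7] <- p
  transition_schedule(P, arm = "toy", horizon = horizon)
}

# hand-written panel: one subject per row of `paths`, daily states
panel_from_paths <- function(paths, arm = "CHG-T1", horizon = NULL) {
  if (is.null(horizon)) horizon <- max(lengths(paths)) - 1L
  recs <- do.call(rbind, lapply(seq_along(paths), function(i) {
    s <- paths[[i]]
    data.frame(subject = sprintf("p%03d", i), arm = arm,
               day = seq_along(s) - 1L, state = s)
  }))
  trajectory_panel(recs, horizon = horizon)
}

# brute-force path enumeration oracle: expected number of entries into
# `state` and first-passage probability into `targets`, by summing the
# probability of every possible state sequence of a (small) schedule.
enumerate_paths <- function(schedule, init = c(1, rep(0, 7))) {
  H <- schedule$horizon
  paths <- list()
  probs <- numeric(0)
  walk <- function(seq_states, pr, t) {
    if (pr == 0) return()
    if (t == H) {
      paths[[length(paths) + 1L]] <<- seq_states
      probs[length(probs) + 1L] <<- pr
      return()
    }
    s <- seq_states[length(seq_states)]
    for (j in 1:8)
      walk(c(seq_states, j), pr * schedule$P[t + 1L, s, j], t + 1L)
  }
  for (s0 in which(init > 0)) walk(s0, init[s0], 0L)
  list(paths = paths, probs = probs)
}

oracle_expected_visits <- function(schedule, state,
                                   init = c(1, rep(0, 7))) {
  en <- enumerate_paths(schedule, init)
  v <- vapply(en$paths, function(p) {
    sum(p == state & c(TRUE, p[-length(p)] != state))
  }, numeric(1))
  sum(v * en$probs)
}

oracle_first_passage <- function(schedule, targets,
                                 init = c(1, rep(0, 7))) {
  en <- enumerate_paths(schedule, init)
  hit <- vapply(en$paths, function(p) any(p %in% targets), numeric(1))
  sum(hit * en$probs)
}

# small calibrated synthetic arm, shared across tests (cheap: n small)
small_arm_config <- function(n = 150L, seed = 11L) {
  generator_config(
    list("CHG-T1" = arm_profile("CHG-T1", n, 0.29, 0.70, 1, 2.2)),
    horizon = 60L, seed = seed)
}
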