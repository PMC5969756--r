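#' State-occupancy (prevalence) curve implied by a fitted model
#'
#' Propagates an initial distribution through the daily transition
#' matrices: \eqn{\pi_{t+1} = \pi_t P_t}. The resulting curve gives, for
#' every day of the horizon, the probability of occupying each of the
#' eight health states.
#'
#' @param schedule a \code{transition_schedule}.
#' @param init distribution over the 8 states at day 0 (sums to 1);
#'   default: all mass in state 1 (first catheter inserted, no event).
#' @return An object of class \code{prevalence_curve}: a
#'   \code{(horizon + 1) x 8} matrix, row t+1 is the distribution at day
#'   t, with attributes \code{arm} and \code{source = "model"}.
#' @export
occupancy_curve <- function(schedule, init = NULL) {
  if (is.null(init)) init <- c(1, rep(0, 7))
  if (length(init) != 8L || abs(sum(init) - 1) > 1e-9)
    stop("init must be a distribution over the 8 states", call. = FALSE)
  H <- schedule$horizon
  pi_t <- matrix(0, H + 1L, 8L, dimnames = list(0:H, 1:8))
  pi_t[1L, ] <- init
  for (t in seq_len(H))
    pi_t[t + 1L, ] <- as.numeric(pi_t[t, ] %*% schedule$P[t, , ])
  structure(pi_t, arm = schedule$arm, source = "model",
            class = c("prevalence_curve", "matrix"))
}

#' Observed prevalence curve of a panel
#'
#' Empirical state distribution by day: the fraction of subjects in each
#' state at each day of the horizon, on the LOCF-filled daily grid.
#' Absorbed subjects remain counted in their absorbing state; subjects
#' administratively censored while transient leave the denominator after
#' their last observation.
#'
#' @param panel a non-empty validated \code{trajectory_panel}.
#' @return A \code{prevalence_curve} with \code{source = "observed"}.
#' @export
observed_prevalence <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  g <- state_grid(panel)
  H <- attr(panel, "horizon")
  pi_t <- matrix(0, H + 1L, 8L, dimnames = list(0:H, 1:8))
  for (d in seq_len(H + 1L)) {
    s <- g[, d]
    s <- s[!is.na(s)]
    pi_t[d, ] <- tabulate(s, nbins = 8L) / length(s)
  }
  arm <- unique(attr(g, "arm"))
  structure(pi_t, arm = if (length(arm) == 1L) arm else "pooled",
            source = "observed", class = c("prevalence_curve", "matrix"))
}

#' Expected total length of stay in a state
#'
#' Expected number of days spent in \code{state} over the horizon, one
#' day credited per day occupied: \eqn{\sum_{t=1}^{H} \pi_t[s]}. Day 0 is
#' the initial observation and is not credited, so the per-state stays
#' sum exactly to the horizon. For the absorbing states this is the
#' expected time spent discharged (resp. dead) within the window, whence
#' e.g. ICU life expectancy = horizon - LOS(death).
#'
#' @param curve a \code{prevalence_curve} over the full horizon.
#' @param state state code 1..8.
#' @return Expected days.
#' @export
expected_total_los <- function(curve, state) {
  sum(curve[-1L, state])
}

#' Expected number of visits to a state
#'
#' Expected number of distinct entries into \code{state} over the
#' horizon: \eqn{init[s] + \sum_t \sum_{i \neq s} \pi_t[i] P_t[i, s]}.
#' For an absorbing state this is its first-passage probability.
#'
#' @param schedule a \code{transition_schedule}.
#' @param state state code 1..8.
#' @param init initial distribution (default: mass in state 1).
#' @return Expected entries (dimensionless count).
#' @export
expected_visits <- function(schedule, state, init = NULL) {
  if (is.null(init)) init <- c(1, rep(0, 7))
  H <- schedule$horizon
  pi_t <- init
  visits <- init[state]
  for (t in seq_len(H)) {
    P <- schedule$P[t, , ]
    visits <- visits + sum(pi_t[-state] * P[-state, state])
    pi_t <- as.numeric(pi_t %*% P)
  }
  visits
}

#' First-passage probability into target states, per 1000 patients
#'
#' Probability that the chain ever occupies one of the \code{targets}
#' (default: the CRBSI states 3--4) by the horizon, scaled per 1000
#' patients: the model-based analogue of the trial's effectiveness
#' statistic. Computed on an augmented chain in which the target states
#' are shadow-absorbing, so re-entries are not double counted.
#'
#' @param schedule a \code{transition_schedule}.
#' @param targets transient state codes (default \code{c(3, 4)}).
#' @param init initial distribution (default: mass in state 1).
#' @return Rate per 1000 patients, in \code{[0, 1000]}.
#' @export
first_passage_per_1000 <- function(schedule, targets = c(3L, 4L),
                                   init = NULL) {
  ss <- state_space()
  if (any(targets %in% ss$absorbing))
    stop("targets must be transient states", call. = FALSE)
  if (is.null(init)) init <- c(1, rep(0, 7))
  H <- schedule$horizon
  pi_t <- init
  for (t in seq_len(H)) {
    P <- schedule$P[t, , ]
    P[targets, ] <- 0                       # shadow-absorb the targets
    P[cbind(targets, targets)] <- 1
    pi_t <- as.numeric(pi_t %*% P)
  }
  1000 * sum(pi_t[targets])
}

#' @export
print.prevalence_curve <- function(x, ...) {
  H <- nrow(x) - 1L
  cat(sprintf("prevalence curve (%s), arm %s, days 0..%d\n",
              attr(x, "source"), attr(x, "arm"), H))
  show <- unique(pmin(H, c(0L, 1L, 10L, 30L, 60L, H)))
  print(round(x[as.character(show), , drop = FALSE], 4))
  invisible(x)
}

#' Plot a prevalence curve
#'
#' Stacked display of state occupancy over the horizon (base graphics):
#' one line per health state.
#'
#' @param x a \code{prevalence_curve}.
#' @param states which states to draw (default all 8).
#' @param ... passed to \code{matplot}.
#' @export
plot.prevalence_curve <- function(x, states = 1:8, ...) {
  ss <- state_space()
  days <- as.integer(rownames(x))
  graphics::matplot(days, x[, states, drop = FALSE], type = "l", lty = 1,
                    col = seq_along(states), xlab = "ICU day",
                    ylab = "occupancy probability",
                    main = sprintf("State occupancy, arm %s (%s)",
                                   attr(x, "arm"), attr(x, "source")), ...)
  graphics::legend("right", legend = ss$labels[states], lty = 1,
                   col = seq_along(states), cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
predict.transition_schedule <- function(object, init = NULL, ...) {
  occupancy_curve(object, init = init)
}
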