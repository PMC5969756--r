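#' Daily transition counts
#'
#' Counts observed one-day transitions at a given day: entry \code{[i, j]}
#' is the number of subjects in state i at \code{day} and state j at
#' \code{day + 1} on the LOCF-filled daily grid. Absorbed subjects
#' contribute to their absorbing self-count; administratively censored
#' subjects drop out of the risk set after their last observation.
#'
#' @param panel a validated \code{trajectory_panel}.
#' @param day integer day, \code{0 <= day < horizon}.
#' @return 8 x 8 integer matrix; row sums are the at-risk counts.
#' @export
count_transitions <- function(panel, day) {
  horizon <- attr(panel, "horizon")
  if (day < 0L || day >= horizon)
    stop("day must lie in [0, horizon)", call. = FALSE)
  g <- state_grid(panel)
  .count_day(g, day + 1L)
}

# internal: counts from grid column d to d+1 (1-based columns)
.count_day <- function(g, d) {
  from <- g[, d]; to <- g[, d + 1L]
  ok <- !is.na(from) & !is.na(to)
  m <- matrix(0L, 8L, 8L, dimnames = list(1:8, 1:8))
  if (any(ok)) {
    tb <- table(factor(from[ok], levels = 1:8),
                factor(to[ok], levels = 1:8))
    m[] <- as.integer(tb)
  }
  m
}

#' Fit the non-homogeneous multi-state model
#'
#' Estimates, for one trial arm, the sequence of daily 8 x 8 transition
#' probability matrices P_t (t = 0 .. horizon-1) by nonparametric counting
#' on the daily grid: row i of P_t is the row-normalized count of observed
#' i -> j transitions from day t to day t+1. Time-inhomogeneity is indexed
#' by calendar ICU day (day 0 = inclusion).
#'
#' Sparse rows are stabilized: transitions are first pooled over
#' consecutive bins of \code{bin_width} days; a state-bin whose at-risk
#' count is below \code{min_at_risk} borrows counts from the nearest
#' adjacent bins (symmetrically widening) until the threshold is met.
#' Rows never observed default to the identity row, so the chain is always
#' well defined. Entries outside the allowed-transition mask are zeroed
#' and rows renormalized.
#'
#' @param panel a validated \code{trajectory_panel}.
#' @param arm arm label to fit; may be omitted when the panel holds a
#'   single arm.
#' @param min_at_risk minimum at-risk count per state-day row (default 5).
#' @param bin_width days pooled per bin (default 1, i.e. daily matrices).
#' @return An object of class \code{transition_schedule}: list with
#'   \code{arm}, \code{horizon}, \code{P} (array \code{horizon x 8 x 8},
#'   \code{P[t, i, j]} = P(state j at day t | state i at day t-1)),
#'   \code{at_risk} (matrix \code{horizon x 8} of raw per-day at-risk
#'   counts) and \code{n} (subjects used).
#' @seealso [occupancy_curve()], [simulate.transition_schedule()],
#'   [expected_total_los()], [first_passage_per_1000()]
#' @examples
#' cfg <- default_arm_profiles(seed = 1)
#' pan <- generate_panel(cfg["CHG-T1"])
#' fit <- fit_multistate(pan)
#' fit
#' @export
fit_multistate <- function(panel, arm = NULL, min_at_risk = 5L,
                           bin_width = 1L) {
  horizon <- attr(panel, "horizon")
  arms <- unique(panel$arm)
  if (is.null(arm)) {
    if (length(arms) > 1L)
      stop("panel holds arms ", paste(arms, collapse = ", "),
           "; pass `arm`", call. = FALSE)
    arm <- arms
  } else {
    df <- as.data.frame(panel)
    panel <- trajectory_panel(df[df$arm == arm, , drop = FALSE],
                              horizon = horizon, validate = FALSE)
    if (nrow(panel) == 0L) stop("no records for arm ", arm, call. = FALSE)
  }
  g <- state_grid(panel)
  counts <- array(0L, c(horizon, 8L, 8L))
  for (t in seq_len(horizon)) counts[t, , ] <- .count_day(g, t)

  # pool into bins of bin_width days
  bin_of <- ((seq_len(horizon) - 1L) %/% bin_width) + 1L
  nb <- max(bin_of)
  bc <- array(0L, c(nb, 8L, 8L))
  for (t in seq_len(horizon)) bc[bin_of[t], , ] <- bc[bin_of[t], , ] + counts[t, , ]

  ss <- state_space()
  P <- array(0, c(horizon, 8L, 8L),
             dimnames = list(NULL, 1:8, 1:8))
  Pbin <- array(0, c(nb, 8L, 8L))
  for (b in seq_len(nb)) {
    for (i in 1:8) {
      if (i %in% ss$absorbing) {
        Pbin[b, i, i] <- 1
        next
      }
      row <- bc[b, i, ]
      w <- 0L
      while (sum(row) < min_at_risk && w < nb) {  # borrow from neighbours
        w <- w + 1L
        if (b - w >= 1L) row <- row + bc[b - w, i, ]
        if (b + w <= nb) row <- row + bc[b + w, i, ]
      }
      row[!ss$allowed[i, ]] <- 0
      tot <- sum(row)
      if (tot == 0) Pbin[b, i, i] <- 1 else Pbin[b, i, ] <- row / tot
    }
  }
  for (t in seq_len(horizon)) P[t, , ] <- Pbin[bin_of[t], , ]
  at_risk <- t(vapply(seq_len(horizon),
                      function(t) rowSums(counts[t, , , drop = TRUE]),
                      numeric(8)))
  structure(list(arm = arm, horizon = horizon, P = P,
                 at_risk = at_risk, n = nrow(g)),
            class = "transition_schedule")
}

#' Construct a transition schedule from explicit matrices
#'
#' Low-level constructor used by the synthetic generator and in tests:
#' wraps an array of daily row-stochastic matrices as a
#' \code{transition_schedule}, checking stochasticity, the absorbing rows
#' and (optionally) the allowed-transition mask.
#'
#' @param P array \code{horizon x 8 x 8} of daily transition matrices, or
#'   a single 8 x 8 matrix recycled over the horizon.
#' @param arm arm label.
#' @param horizon required when \code{P} is a single matrix.
#' @param check_mask verify entries outside the allowed mask are zero.
#' @return A \code{transition_schedule}.
#' @export
transition_schedule <- function(P, arm = "arm", horizon = NULL,
                                check_mask = TRUE) {
  if (is.matrix(P)) {
    if (is.null(horizon)) stop("horizon required with a single matrix",
                               call. = FALSE)
    P <- aperm(array(P, c(8L, 8L, horizon)), c(3L, 1L, 2L))
  }
  horizon <- dim(P)[1L]
  rs <- apply(P, c(1L, 2L), sum)
  if (any(abs(rs - 1) > 1e-12))
    stop("non-stochastic row(s) in transition matrices", call. = FALSE)
  if (any(P < 0)) stop("negative transition probability", call. = FALSE)
  ss <- state_space()
  for (a in ss$absorbing)
    if (any(P[, a, -a] != 0) || any(P[, a, a] != 1))
      stop("absorbing state ", a, " row must be a unit self-vector",
           call. = FALSE)
  if (check_mask &&
      any(as.vector(P)[rep(as.vector(!ss$allowed), each = horizon)] != 0))
    stop("nonzero probability outside the allowed-transition mask",
         call. = FALSE)
  dimnames(P) <- list(NULL, 1:8, 1:8)
  structure(list(arm = arm, horizon = horizon, P = P,
                 at_risk = NULL, n = NA_integer_),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("non-homogeneous multi-state transition schedule, arm %s\n",
              x$arm))
  cat(sprintf("  horizon %d days, daily 8x8 matrices", x$horizon))
  if (!is.na(x$n)) cat(sprintf(", fitted on %d subjects", x$n))
  cat("\n")
  pi100 <- occupancy_curve(x)
  cat(sprintf("  implied day-%d: discharged %.1f%%, died %.1f%%\n",
              x$horizon, 100 * pi100[x$horizon + 1L, 7L],
              100 * pi100[x$horizon + 1L, 8L]))
  invisible(x)
}

#' @export
summary.transition_schedule <- function(object, init = NULL, ...) {
  curve <- occupancy_curve(object, init)
  los <- vapply(1:8, function(s) expected_total_los(curve, s), numeric(1))
  visits <- vapply(1:8, function(s) expected_visits(object, s, init),
                   numeric(1))
  out <- list(arm = object$arm, horizon = object$horizon, n = object$n,
              los_by_state = stats::setNames(los, state_space()$labels),
              visits_by_state = stats::setNames(visits, state_space()$labels),
              crbsi_per_1000 = first_passage_per_1000(object, init = init))
  class(out) <- "summary.transition_schedule"
  out
}

#' @export
print.summary.transition_schedule <- function(x, ...) {
  cat(sprintf("multi-state model summary, arm %s (horizon %d days)\n",
              x$arm, x$horizon))
  tab <- cbind(`E[days]` = round(x$los_by_state, 2),
               `E[visits]` = round(x$visits_by_state, 3))
  print(tab)
  cat(sprintf("patients ever with CRBSI per 1000: %.2f\n",
              x$crbsi_per_1000))
  invisible(x)
}
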