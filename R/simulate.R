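# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a patient cohort from a fitted schedule
#'
#' Draws \code{n} independent daily-step trajectories from the daily
#' transition matrices of a \code{transition_schedule} (the
#' non-homogeneous semi-Markov chain simulation). Every patient starts at
#' day 0 from \code{init} and is followed until absorption (discharge or
#' death) or administrative censoring at the horizon.
#'
#' @param schedule a \code{transition_schedule}.
#' @param n number of patients (> 0).
#' @param seed integer seed; the draw is bit-reproducible given
#'   \code{(schedule, n, seed)}.
#' @param init initial distribution over states (default: mass in
#'   state 1).
#' @param subject_prefix prefix for generated subject ids.
#' @return A validated \code{trajectory_panel} (records are run-length
#'   compressed: day 0, every state change, and the final day).
#' @export
simulate_cohort <- function(schedule, n, seed = 1L, init = NULL,
                            subject_prefix = NULL) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (is.null(init)) init <- c(1, rep(0, 7))
  H <- schedule$horizon
  g <- with_seed(seed, {
    cur <- sample.int(8L, n, replace = TRUE, prob = init)
    g <- matrix(NA_integer_, n, H + 1L)
    g[, 1L] <- cur
    for (t in seq_len(H)) {
      cumP <- t(apply(schedule$P[t, , ], 1L, cumsum))
      cumP[, 8L] <- 1
      u <- stats::runif(n)
      cur <- rowSums(cumP[cur, , drop = FALSE] < u) + 1L
      g[, t + 1L] <- cur
    }
    g
  })
  grid_to_panel(g, arm = schedule$arm, horizon = H,
                subject_prefix = subject_prefix)
}

# internal: run-length compress an n x (H+1) daily state grid (NA =
# administratively censored tail) to a panel. `arm` may be one label or
# one per row; `ids` defaults to generated per-arm labels.
grid_to_panel <- function(g, arm, horizon, subject_prefix = NULL,
                          ids = NULL) {
  n <- nrow(g)
  if (is.null(ids)) {
    if (is.null(subject_prefix)) subject_prefix <- paste0(arm[1L], "_s")
    ids <- sprintf("%s%06d", subject_prefix, seq_len(n))
  }
  arm <- rep_len(arm, n)
  keep <- matrix(FALSE, n, horizon + 1L)
  keep[, 1L] <- TRUE
  if (horizon > 0L) {
    cur <- g[, -1L, drop = FALSE]
    prev <- g[, -(horizon + 1L), drop = FALSE]
    keep[, -1L] <- !is.na(cur) & cur != prev
  }
  last_col <- rowSums(!is.na(g))           # observed cells are contiguous
  term <- g[cbind(seq_len(n), last_col)]
  cens <- !(term %in% c(7L, 8L))           # censored: keep final day
  keep[cbind(seq_len(n), last_col)] <- keep[cbind(seq_len(n), last_col)] |
    cens
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(subject = ids[idx[, 1L]], arm = arm[idx[, 1L]],
                   day = idx[, 2L] - 1L,
                   state = g[idx])
  trajectory_panel(df, horizon = horizon, validate = FALSE)
}

#' @rdname simulate_cohort
#' @param object a \code{transition_schedule}.
#' @param nsim number of patients.
#' @param ... unused.
#' @export
simulate.transition_schedule <- function(object, nsim = 1L, seed = 1L,
                                         ...) {
  simulate_cohort(object, n = nsim, seed = seed)
}

#' @rdname simulate_cohort
#' @export
generate_from_schedule <- function(schedule, n, seed = 1L, init = NULL) {
  simulate_cohort(schedule, n = n, seed = seed, init = init)
}

#' Restrict a panel to patients who did not die
#'
#' The "alive patient" analysis: subjects whose terminal state is death
#' (state 8) are removed and the remaining panel is re-validated.
#' Downstream re-estimation on the result has, by construction, zero
#' hazard into state 8.
#'
#' @param panel a validated \code{trajectory_panel}.
#' @return A \code{trajectory_panel} without the deceased subjects.
#' @export
alive_variant <- function(panel) {
  term <- tapply(panel$state, panel$subject, function(s) s[length(s)])
  keep <- names(term)[term != 8L]
  if (length(keep) == 0L)
    stop("all patients died; alive-patient panel is empty", call. = FALSE)
  horizon <- attr(panel, "horizon")
  df <- as.data.frame(panel)
  trajectory_panel(df[df$subject %in% keep, , drop = FALSE],
                   horizon = horizon, validate = FALSE)
}

#' Cohort summary: the row block of a cost-effectiveness table
#'
#' Builds the per-arm summary every comparison is made from: prevalence
#' curve, expected length of stay and expected visits per state, the
#' CRBSI effectiveness statistic (patients with CRBSI per 1000) and the
#' mean cost per patient.
#'
#' \code{summarize_cohort} computes the summary from either a fitted
#' \code{transition_schedule} (model-based: matrix-product occupancy,
#' first-passage effectiveness) or a \code{trajectory_panel} (empirical:
#' observed prevalence, ever-in-state effectiveness).
#' \code{cohort_summary} assembles one directly from known numbers (e.g.
#' published table rows).
#'
#' @param x a \code{transition_schedule} or \code{trajectory_panel}.
#' @param cost_table a \code{cost_table}; \code{NULL} skips costing.
#' @param variant analysis label, one of \code{"simulated_global"},
#'   \code{"simulated_alive"}, \code{"observed_global"}.
#' @param init initial distribution (schedule input only).
#' @param targets effectiveness target states (default CRBSI, 3--4).
#' @return An object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(x, cost_table = NULL,
                             variant = c("simulated_global",
                                         "simulated_alive",
                                         "observed_global"),
                             init = NULL, targets = c(3L, 4L)) {
  variant <- match.arg(variant)
  if (inherits(x, "transition_schedule")) {
    arm <- x$arm
    curve <- occupancy_curve(x, init = init)
    visits <- vapply(1:8, function(s) expected_visits(x, s, init),
                     numeric(1))
    eff <- first_passage_per_1000(x, targets = targets, init = init)
  } else if (inherits(x, "trajectory_panel")) {
    arm <- unique(x$arm)
    if (length(arm) != 1L)
      stop("panel holds several arms; subset first", call. = FALSE)
    curve <- observed_prevalence(x)
    visits <- empirical_visits(x)
    eff <- ever_in_states_per_1000(x, targets = targets)
  } else stop("x must be a transition_schedule or trajectory_panel",
              call. = FALSE)
  los <- vapply(1:8, function(s) expected_total_los(curve, s), numeric(1))
  cost <- if (is.null(cost_table)) NA_real_ else
    mean_cost_per_patient(curve, cost_table, arm = arm,
                          visits = visits)
  cohort_summary(arm = arm, variant = variant,
                 horizon = nrow(curve) - 1L,
                 mean_cost = cost, effectiveness = eff,
                 prevalence = curve,
                 los_by_state = los, visits_by_state = visits)
}

#' @rdname summarize_cohort
#' @param arm arm label.
#' @param horizon horizon in days.
#' @param mean_cost mean cost per patient (Euro 2016).
#' @param effectiveness patients with CRBSI per 1000 patients.
#' @param cost_ci,effectiveness_ci optional 95\% intervals,
#'   \code{c(low, high)}.
#' @param prevalence,los_by_state,visits_by_state optional detail fields.
#' @export
cohort_summary <- function(arm, variant, horizon, mean_cost,
                           effectiveness, cost_ci = NULL,
                           effectiveness_ci = NULL, prevalence = NULL,
                           los_by_state = NULL, visits_by_state = NULL) {
  if (!is.na(effectiveness) &&
      (effectiveness < 0 || effectiveness > 1000))
    stop("effectiveness per 1000 must lie in [0, 1000]", call. = FALSE)
  if (!is.na(mean_cost) && mean_cost < 0)
    stop("mean cost must be non-negative", call. = FALSE)
  if (!is.null(los_by_state) &&
      abs(sum(los_by_state) - horizon) > 1e-9)
    stop("per-state stays must sum to the horizon", call. = FALSE)
  structure(list(arm = arm, variant = variant, horizon = horizon,
                 mean_cost_per_patient = mean_cost,
                 effectiveness_per_1000 = effectiveness,
                 cost_ci = cost_ci, effectiveness_ci = effectiveness_ci,
                 prevalence = prevalence, los_by_state = los_by_state,
                 visits_by_state = visits_by_state),
            class = "cohort_summary")
}

# internal: empirical expected entries per state from a panel
empirical_visits <- function(panel) {
  g <- state_grid(panel)
  n <- nrow(g)
  H <- ncol(g) - 1L
  entries <- tabulate(g[, 1L], nbins = 8L)
  for (d in seq_len(H)) {
    from <- g[, d]; to <- g[, d + 1L]
    ok <- !is.na(from) & !is.na(to) & from != to
    if (any(ok)) entries <- entries + tabulate(to[ok], nbins = 8L)
  }
  entries / n
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_ci <- function(ci, digits = 0) {
    if (is.null(ci)) "" else
      sprintf(" (%s; %s)", formatC(ci[1], format = "f", digits = digits),
              formatC(ci[2], format = "f", digits = digits))
  }
  cat(sprintf("cohort summary, arm %s [%s], horizon %d days\n",
              x$arm, x$variant, x$horizon))
  cat(sprintf("  mean cost per patient: EUR %.0f%s\n",
              x$mean_cost_per_patient, fmt_ci(x$cost_ci)))
  cat(sprintf("  patients with CRBSI per 1000: %.2f%s\n",
              x$effectiveness_per_1000, fmt_ci(x$effectiveness_ci, 2)))
  if (!is.null(x$los_by_state)) {
    cat(sprintf("  E[days] discharge %.1f, death %.1f\n",
                x$los_by_state[7L], x$los_by_state[8L]))
  }
  invisible(x)
}
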