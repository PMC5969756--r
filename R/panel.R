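#' Construct and validate a trajectory panel
#'
#' A trajectory panel is the empirical object everything is estimated from:
#' one row per observation of a subject's health state on an ICU day
#' (long format). Observations are daily but need not be complete; missing
#' intermediate days are filled by last observation carried forward when
#' the panel is expanded to the daily grid (see Details).
#'
#' Validation enforces: states are codes 1..8; within a subject, days are
#' strictly increasing with at most one record per day; each subject starts
#' at day 0 in a transient state; once a subject is observed in an
#' absorbing state (discharge, death) no later record differs; no record
#' lies beyond the horizon. Validation is idempotent.
#'
#' @param records data.frame with columns \code{subject}, \code{arm},
#'   \code{day}, \code{state}.
#' @param horizon follow-up window in days (default 100).
#' @param validate run validation (default \code{TRUE}).
#' @return An object of class \code{trajectory_panel}: the records
#'   data.frame (sorted by subject, day) with attribute \code{horizon}.
#' @examples
#' p <- trajectory_panel(data.frame(
#'   subject = "a", arm = "CHG-T1", day = 0:2, state = c(1, 1, 7)))
#' n_subjects(p)
#' @export
trajectory_panel <- function(records, horizon = 100L, validate = TRUE) {
  need <- c("subject", "arm", "day", "state")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[, need]
  records$subject <- as.character(records$subject)
  records$arm <- as.character(records$arm)
  records$day <- as.integer(records$day)
  st <- suppressWarnings(as.integer(records$state))
  if (anyNA(st) && !anyNA(records$state))
    stop("state column is not coercible to integer codes", call. = FALSE)
  records$state <- st
  records <- records[order(records$subject, records$day), , drop = FALSE]
  rownames(records) <- NULL
  out <- structure(records, horizon = as.integer(horizon),
                   class = c("trajectory_panel", "data.frame"))
  if (validate) validate_panel(out) else out
}

#' @rdname trajectory_panel
#' @param panel a \code{trajectory_panel}.
#' @export
validate_panel <- function(panel) {
  horizon <- attr(panel, "horizon")
  check_states(panel$state)
  if (any(panel$day < 0L))
    stop("negative observation day", call. = FALSE)
  if (any(panel$day > horizon))
    stop("record beyond horizon (", horizon, " days); apply ",
         "apply_censoring_rules() first", call. = FALSE)
  ss <- state_space()
  sp <- split(seq_len(nrow(panel)), panel$subject)
  for (id in names(sp)) {
    i <- sp[[id]]
    d <- panel$day[i]; s <- panel$state[i]
    if (anyDuplicated(d))
      stop("subject ", id, ": duplicate observation day", call. = FALSE)
    if (is.unsorted(d, strictly = TRUE))
      stop("subject ", id, ": non-monotone days", call. = FALSE)
    if (d[1L] != 0L)
      stop("subject ", id, ": first record must be at day 0", call. = FALSE)
    if (s[1L] %in% ss$absorbing)
      stop("subject ", id, ": first record in an absorbing state",
           call. = FALSE)
    abs_at <- which(s %in% ss$absorbing)
    if (length(abs_at)) {
      k <- abs_at[1L]
      if (any(s[k:length(s)] != s[k]))
        stop("subject ", id, ": state changes after absorbing state ",
             s[k], call. = FALSE)
    }
    if (length(unique(panel$arm[i])) != 1L)
      stop("subject ", id, ": inconsistent arm label", call. = FALSE)
  }
  panel
}

#' @rdname trajectory_panel
#' @export
n_subjects <- function(panel) length(unique(panel$subject))

#' Read / write trajectory panels as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' \code{subject,arm,day,state}. Reading validates the panel.
#'
#' @param source path to a CSV file.
#' @param horizon follow-up window in days.
#' @return \code{read_panel}: a validated \code{trajectory_panel}.
#' @export
read_panel <- function(source, horizon = 100L) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  trajectory_panel(df, horizon = horizon)
}

#' @rdname read_panel
#' @param panel a \code{trajectory_panel}.
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, c("subject", "arm", "day", "state")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the trial's censoring and recoding rules
#'
#' Two rules are applied to a raw panel before estimation:
#' \enumerate{
#'   \item records beyond the horizon are dropped (subjects still present
#'     at the horizon are administratively censored there);
#'   \item a CRBSI (state 3 or 4) recorded within
#'     \code{post_discharge_window} days \emph{after} an ICU discharge
#'     record is attributed to the ICU stay: the subject's last transient
#'     day is recoded to the CRBSI state and discharge follows one day
#'     later. A CRBSI recorded later than the window is left untouched
#'     with a warning.
#' }
#'
#' @param panel a \code{trajectory_panel} (may be raw, i.e. violating the
#'   absorbing invariant through a post-discharge CRBSI record).
#' @param horizon censoring horizon in days (default 100).
#' @param post_discharge_window days after discharge within which a CRBSI
#'   is attributed to the stay (default 2).
#' @return A validated \code{trajectory_panel}.
#' @export
apply_censoring_rules <- function(panel, horizon = 100L,
                                  post_discharge_window = 2L) {
  df <- as.data.frame(panel)
  check_states(df$state)
  ss <- state_space()
  out <- vector("list", length(unique(df$subject)))
  sp <- split(df, df$subject)
  k <- 0L
  for (id in names(sp)) {
    sub <- sp[[id]]
    sub <- sub[order(sub$day), , drop = FALSE]
    disc <- which(sub$state == 7L)
    if (length(disc)) {
      d0 <- sub$day[disc[1L]]
      late <- which(sub$day > d0 & sub$state %in% ss$crbsi)
      if (length(late)) {
        gap <- sub$day[late[1L]] - d0
        if (gap <= post_discharge_window) {
          crbsi_state <- sub$state[late[1L]]
          sub <- sub[sub$day < d0, , drop = FALSE]
          sub <- rbind(sub, data.frame(subject = id, arm = sub$arm[1L],
                                       day = c(d0, d0 + 1L),
                                       state = c(crbsi_state, 7L)))
        } else {
          warning("subject ", id, ": CRBSI ", gap,
                  " days after discharge left untouched", call. = FALSE)
          sub <- sub[seq_len(disc[1L]), , drop = FALSE]
        }
      }
    }
    sub <- sub[sub$day <= horizon, , drop = FALSE]
    k <- k + 1L
    out[[k]] <- sub
  }
  trajectory_panel(do.call(rbind, out), horizon = horizon)
}

#' Patients ever observed in a set of states, per 1000
#'
#' The trial's effectiveness statistic on observed data: the number of
#' patients with at least one record in \code{targets} (by default the
#' CRBSI states 3--4) per 1000 patients.
#'
#' @param panel a non-empty \code{trajectory_panel}.
#' @param targets integer state codes (default \code{c(3, 4)}).
#' @return Rate per 1000 patients.
#' @examples
#' # 2 of 573 patients with CRBSI -> 3.49 per 1000
#' @export
ever_in_states_per_1000 <- function(panel, targets = c(3L, 4L)) {
  if (nrow(panel) == 0L)
    stop("effectiveness undefined on an empty panel", call. = FALSE)
  hit <- tapply(panel$state %in% targets, panel$subject, any)
  1000 * sum(hit) / length(hit)
}

#' @export
print.trajectory_panel <- function(x, ...) {
  ss <- state_space()
  term <- tapply(x$state, x$subject, function(s) s[length(s)])
  cat(sprintf("trajectory panel: %d subjects, %d records, horizon %d days\n",
              n_subjects(x), nrow(x), attr(x, "horizon")))
  arms <- table(tapply(x$arm, x$subject, `[`, 1L))
  cat("  arms: ", paste(sprintf("%s (n=%d)", names(arms), as.integer(arms)),
                        collapse = ", "), "\n", sep = "")
  cat(sprintf("  discharged %.1f%%, died %.1f%%, censored %.1f%%\n",
              100 * mean(term == 7L), 100 * mean(term == 8L),
              100 * mean(!(term %in% ss$absorbing))))
  invisible(x)
}

# internal: expand a panel to the daily state grid, one row per subject,
# columns day 0..horizon. Missing intermediate days are LOCF-filled;
# absorbing states are carried to the horizon; cells after a transient
# subject's last observation are NA (administrative censoring).
state_grid <- function(panel) {
  horizon <- attr(panel, "horizon")
  ids <- unique(panel$subject)
  n <- length(ids)
  g <- matrix(NA_integer_, n, horizon + 1L,
              dimnames = list(ids, 0:horizon))
  g[cbind(match(panel$subject, ids), panel$day + 1L)] <- panel$state
  last_day <- tapply(panel$day, panel$subject, max)[ids]
  term <- tapply(panel$state, panel$subject,
                 function(s) s[length(s)])[ids]
  for (d in seq_len(horizon) + 1L) {            # LOCF column sweep
    fill <- is.na(g[, d])
    g[fill, d] <- g[fill, d - 1L]
  }
  # blank out beyond last observation for censored (transient) subjects
  cens <- !(term %in% c(7L, 8L))
  if (any(cens)) {
    for (i in which(cens)) {
      if (last_day[i] < horizon)
        g[i, (last_day[i] + 2L):(horizon + 1L)] <- NA_integer_
    }
  }
  attr(g, "arm") <- tapply(panel$arm, panel$subject, `[`, 1L)[ids]
  g
}
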