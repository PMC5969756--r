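#' Euro-2016 unit-cost ledger
#'
#' The base-case unit costs of the analysis (all Euro 2016, ICU
#' perspective): per-day antiseptic solution cost per arm, dressing and
#' catheter handling costs, the direct cost of treating one CRBSI
#' episode, the cost of one ICU patient-day, and the additional ICU
#' length of stay attributable to a CRBSI.
#'
#' @param antiseptic_per_day named per-arm solution cost per patient-day.
#' @param transparent_dressing cost of one semipermeable transparent
#'   dressing.
#' @param catheter_removal,catheter_insertion,catheter_change catheter
#'   handling costs (change assumes 50\% venous + 50\% arterial).
#' @param four_standard_dressings cost of four standard dressings.
#' @param crbsi_direct direct cost of treating one CRBSI episode.
#' @param icu_day cost of one ICU patient-day.
#' @param added_los_days additional ICU length of stay due to CRBSI, days.
#' @return An object of class \code{unit_cost_ledger}.
#' @export
unit_cost_ledger <- function(antiseptic_per_day = c("CHG-T1" = 3.45,
                                                    "CHG-T4" = 4.85,
                                                    "PVI-T1" = 1.98,
                                                    "PVI-T4" = 3.53),
                             transparent_dressing = 0.12,
                             catheter_removal = 29.11,
                             four_standard_dressings = 27.68,
                             catheter_insertion = 116.90,
                             catheter_change = 117.02,
                             crbsi_direct = 715.01,
                             icu_day = 1125.41,
                             added_los_days = 11.77) {
  vals <- c(antiseptic_per_day, transparent_dressing, catheter_removal,
            four_standard_dressings, catheter_insertion, catheter_change,
            crbsi_direct, icu_day, added_los_days)
  if (any(vals < 0)) stop("unit costs must be non-negative", call. = FALSE)
  structure(list(antiseptic_per_day = antiseptic_per_day,
                 transparent_dressing = transparent_dressing,
                 catheter_removal = catheter_removal,
                 four_standard_dressings = four_standard_dressings,
                 catheter_insertion = catheter_insertion,
                 catheter_change = catheter_change,
                 crbsi_direct = crbsi_direct,
                 icu_day = icu_day,
                 added_los_days = added_los_days,
                 currency = "EUR", year = 2016L),
            class = "unit_cost_ledger")
}

#' Composite CRBSI costs derived from the ledger
#'
#' \code{added_los_cost} = additional ICU days due to CRBSI x cost per
#' ICU day; \code{overall_crbsi_cost} = direct treatment cost of one
#' episode + \code{added_los_cost}. Full precision is kept; rounding to
#' cents happens only at presentation.
#'
#' @param ledger a \code{unit_cost_ledger}.
#' @return List with \code{added_los_cost} and \code{overall_crbsi_cost}
#'   (Euro 2016), class \code{derived_costs}.
#' @examples
#' derive_costs(unit_cost_ledger())  # ~13246.08 and ~13961.09
#' @export
derive_costs <- function(ledger = unit_cost_ledger()) {
  added <- ledger$added_los_days * ledger$icu_day
  structure(list(added_los_cost = added,
                 overall_crbsi_cost = ledger$crbsi_direct + added),
            class = "derived_costs")
}

# canonical per-state per-arm cost inputs (Euro 2016); states 7/8 free
printed_state_costs <- function() {
  m <- rbind(
    "CHG-T1" = c(1188.09, 1791.45, 15149.15, 15752.52, 1575.76, 1155.65, 0, 0),
    "CHG-T4" = c(1166.39, 1772.48, 15127.46, 15733.54, 1542.78, 1166.92, 0, 0),
    "PVI-T1" = c(1143.48, 1808.87, 15104.54, 15769.94, 1543.31, 1144.02, 0, 0),
    "PVI-T4" = c(1158.12, 1827.83, 15119.19, 15788.89, 1554.13, 1158.71, 0, 0))
  colnames(m) <- 1:8
  m
}

#' Per-state per-arm cost table
#'
#' Builds the cost-per-patient-per-state table used to price occupancy.
#' The shipped default is the published base-case table (states 1--6
#' carry daily care costs; the CRBSI states 3--4 additionally carry the
#' full one-time episode cost; the absorbing states 7--8 cost zero).
#' With \code{reconstruct = TRUE} the CRBSI states are instead rebuilt
#' additively from the non-CRBSI states and the ledger-derived overall
#' episode cost (sensitivity analysis); states 1, 2, 5, 6 cannot be
#' decomposed from the listed unit costs and are always taken from
#' \code{values}.
#'
#' A consistency check warns when \code{state3 - state1} or
#' \code{state4 - state2} differs from the overall CRBSI cost by more
#' than \code{tol} euro (default 0.05, absorbing the cent-level rounding
#' of published tables).
#'
#' @param ledger a \code{unit_cost_ledger}.
#' @param derived a \code{derived_costs} (default: derived from ledger).
#' @param values optional 4 x 8 matrix (arms x states) overriding the
#'   shipped per-state costs.
#' @param reconstruct rebuild states 3--4 additively (default FALSE).
#' @param mode costing mode tag carried to pricing, one of
#'   \code{"occupancy_daily"} (default) or \code{"per_entry_event"}.
#' @param tol consistency band in euro (default 0.05).
#' @return An object of class \code{cost_table}: 4 x 8 numeric matrix
#'   with attributes \code{mode}, \code{derived}, \code{currency}.
#' @export
build_cost_table <- function(ledger = unit_cost_ledger(),
                             derived = derive_costs(ledger),
                             values = NULL, reconstruct = FALSE,
                             mode = c("occupancy_daily",
                                      "per_entry_event"),
                             tol = 0.05) {
  mode <- match.arg(mode)
  m <- if (is.null(values)) printed_state_costs() else {
    stopifnot(ncol(values) == 8L)
    values
  }
  if (reconstruct) {
    m[, 3L] <- m[, 1L] + derived$overall_crbsi_cost
    m[, 4L] <- m[, 2L] + derived$overall_crbsi_cost
  }
  m[, c(7L, 8L)] <- 0
  if (any(m < 0)) stop("negative state cost", call. = FALSE)
  gap <- cbind(m[, 3L] - m[, 1L], m[, 4L] - m[, 2L]) -
    derived$overall_crbsi_cost
  if (any(abs(gap) > tol))
    warning("CRBSI premium inconsistent with overall episode cost for ",
            paste(rownames(m)[rowSums(abs(gap) > tol) > 0],
                  collapse = ", "), call. = FALSE)
  structure(m, mode = mode, derived = derived, currency = "EUR 2016",
            class = c("cost_table", "matrix"))
}

#' Mean cost per patient from a prevalence curve
#'
#' Prices a prevalence curve against a cost table. In the default
#' \code{occupancy_daily} mode each day a patient starts in a state is
#' charged that state's cost: \eqn{\sum_{t=0}^{H-1} \sum_s \pi_t[s] c[s]}
#' (the absorbing states are free, so days spent discharged or dead
#' contribute nothing). In \code{per_entry_event} mode the event states
#' 3, 4 and 5 are charged once per expected entry (pass
#' \code{visits}) while states 1, 2 and 6 remain charged per occupied
#' day.
#'
#' Pricing is linear in the cost table, and pricing a panel
#' subject-by-subject then averaging equals pricing its observed
#' prevalence curve (exchange of summation) when no subject is censored
#' mid-horizon.
#'
#' @param curve a \code{prevalence_curve}.
#' @param table a \code{cost_table}.
#' @param arm arm row of the table; defaults to the curve's arm.
#' @param mode costing mode; defaults to the table's mode.
#' @param visits per-state expected entries (needed for
#'   \code{per_entry_event}).
#' @return Mean cost per patient, Euro 2016.
#' @export
mean_cost_per_patient <- function(curve, table, arm = attr(curve, "arm"),
                                  mode = attr(table, "mode"),
                                  visits = NULL) {
  if (!arm %in% rownames(table))
    stop("no cost column for arm ", arm, call. = FALSE)
  cost <- table[arm, ]
  H <- nrow(curve) - 1L
  days <- colSums(curve[seq_len(H), , drop = FALSE])  # days t = 0..H-1
  if (identical(mode, "per_entry_event")) {
    if (is.null(visits))
      stop("per_entry_event mode needs per-state expected visits",
           call. = FALSE)
    event_states <- c(3L, 4L, 5L)
    sum(days[-event_states] * cost[-event_states]) +
      sum(visits[event_states] * cost[event_states])
  } else {
    sum(days * cost)
  }
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("per-state cost table (%s, mode %s)\n",
              attr(x, "currency"), attr(x, "mode")))
  print(round(unclass(x), 2))
  d <- attr(x, "derived")
  cat(sprintf("overall CRBSI episode cost: EUR %.2f\n",
              d$overall_crbsi_cost))
  invisible(x)
}
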