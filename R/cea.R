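#' Pairwise cost-effectiveness comparison
#'
#' Compares a strategy against a reference: incremental cost
#' (\code{delta_cost} = comparator - reference), incremental
#' effectiveness (\code{delta_effectiveness} = comparator - reference,
#' in CRBSI patients per 1000; fewer is better), the incremental
#' cost-effectiveness ratio (ICER = delta cost / delta effectiveness)
#' where the pair sits in a trade-off quadrant, and a dominance
#' classification:
#' \describe{
#'   \item{dominant}{comparator no more costly and no less effective
#'     (fewer CRBSI patients), at least one strictly}
#'   \item{dominated}{the reverse}
#'   \item{icer_tradeoff}{cheaper but less effective, or costlier but
#'     more effective; the ICER (euro per CRBSI patient avoided) is the
#'     relevant summary and is reported as a magnitude with the quadrant
#'     label}
#'   \item{comparable}{both increments zero}
#' }
#'
#' @param ref,alt \code{cohort_summary} objects for the reference and
#'   comparator strategy (same horizon and analysis variant).
#' @return An object of class \code{cea_result}.
#' @examples
#' ref <- cohort_summary("PVI-T1", "simulated_global", 100, 24874, 22.37)
#' alt <- cohort_summary("PVI-T4", "simulated_global", 100, 24201, 22.91)
#' compare_strategies(ref, alt)  # ICER ~ 1246, less costly less effective
#' @export
compare_strategies <- function(ref, alt) {
  if (ref$horizon != alt$horizon)
    stop("horizon mismatch between summaries", call. = FALSE)
  if (!identical(ref$variant, alt$variant))
    stop("analysis-variant mismatch between summaries", call. = FALSE)
  dc <- alt$mean_cost_per_patient - ref$mean_cost_per_patient
  de <- alt$effectiveness_per_1000 - ref$effectiveness_per_1000
  icer <- NA_real_
  icer_undefined <- FALSE
  if (dc == 0 && de == 0) {
    dominance <- "comparable"
  } else if (dc <= 0 && de <= 0) {
    dominance <- "dominant"
  } else if (dc >= 0 && de >= 0) {
    dominance <- "dominated"
  } else {
    dominance <- "icer_tradeoff"
    if (de == 0) icer_undefined <- TRUE else icer <- abs(dc / de)
  }
  quadrant <- paste(if (dc <= 0) "less costly" else "more costly",
                    if (de <= 0) "more effective" else "less effective",
                    sep = ", ")
  structure(list(reference = ref$arm, comparator = alt$arm,
                 variant = ref$variant, horizon = ref$horizon,
                 delta_cost = dc, delta_effectiveness = de,
                 icer = icer, icer_undefined = icer_undefined,
                 dominance = dominance, quadrant = quadrant,
                 ci_overlap_cost = NA, ci_overlap_effect = NA),
            class = "cea_result")
}

#' Flag statistical comparability by confidence-interval overlap
#'
#' Sets the significance flags of a \code{cea_result} by the
#' interval-overlap convention: overlapping 95\% intervals between the
#' two strategies are read as "not statistically significant at the 0.05
#' level" (a conservative convention relative to a formal test of the
#' difference). Intervals are taken from the summaries' \code{cost_ci} /
#' \code{effectiveness_ci} fields unless given explicitly.
#'
#' @param result a \code{cea_result}.
#' @param ref,alt the \code{cohort_summary} objects compared, carrying
#'   95\% intervals.
#' @param ref_cost_ci,alt_cost_ci,ref_eff_ci,alt_eff_ci explicit
#'   \code{c(low, high)} intervals, overriding the summaries.
#' @return The \code{cea_result} with \code{ci_overlap_cost},
#'   \code{ci_overlap_effect} and a \code{significance} narrative filled
#'   in (flags stay \code{NA}, with a message, when an interval is
#'   missing).
#' @export
classify_significance <- function(result, ref = NULL, alt = NULL,
                                  ref_cost_ci = ref$cost_ci,
                                  alt_cost_ci = alt$cost_ci,
                                  ref_eff_ci = ref$effectiveness_ci,
                                  alt_eff_ci = alt$effectiveness_ci) {
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  if (is.null(ref_cost_ci) || is.null(alt_cost_ci)) {
    message("cost CI missing; overlap flag left unset")
  } else {
    result$ci_overlap_cost <- overlap(ref_cost_ci, alt_cost_ci)
  }
  if (is.null(ref_eff_ci) || is.null(alt_eff_ci)) {
    message("effectiveness CI missing; overlap flag left unset")
  } else {
    result$ci_overlap_effect <- overlap(ref_eff_ci, alt_eff_ci)
  }
  word <- function(f, what)
    if (is.na(f)) NULL
    else paste0("difference in ", what,
                if (f) " not statistically significant at 0.05 level (CIs overlap)"
                else " statistically significant at 0.05 level (CIs do not overlap)")
  result$significance <- paste(c(word(result$ci_overlap_cost, "cost"),
                                 word(result$ci_overlap_effect,
                                      "effectiveness")),
                               collapse = "; ")
  result
}

#' Cost difference between two follow-up horizons
#'
#' The horizon contrast: mean cost at the shorter horizon minus mean
#' cost at the longer one, for the same arm and analysis variant
#' (negative when the longer horizon costs more).
#'
#' @param summary_T \code{cohort_summary} at the longer horizon.
#' @param summary_t \code{cohort_summary} at the shorter horizon.
#' @return Euro difference (short - long).
#' @export
horizon_contrast <- function(summary_T, summary_t) {
  if (!identical(summary_T$arm, summary_t$arm))
    stop("horizon contrast requires the same arm", call. = FALSE)
  if (!identical(summary_T$variant, summary_t$variant))
    stop("horizon contrast requires the same analysis variant",
         call. = FALSE)
  if (summary_t$horizon >= summary_T$horizon)
    stop("summary_t must have the shorter horizon", call. = FALSE)
  summary_t$mean_cost_per_patient - summary_T$mean_cost_per_patient
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA: %s vs %s (reference) [%s, %d days]\n",
              x$comparator, x$reference, x$variant, x$horizon))
  cat(sprintf("  delta cost: EUR %+.0f   delta effectiveness: %+.2f /1000\n",
              x$delta_cost, x$delta_effectiveness))
  if (x$dominance == "dominant") {
    cat(sprintf("  dominates %s (in mean: %s)\n", x$reference, x$quadrant))
  } else if (x$dominance == "dominated") {
    cat(sprintf("  dominated by %s (in mean: %s)\n", x$reference,
                x$quadrant))
  } else if (x$dominance == "icer_tradeoff") {
    if (x$icer_undefined)
      cat("  trade-off with zero effectiveness difference: ICER undefined\n")
    else
      cat(sprintf("  ICER: EUR %.0f per CRBSI patient avoided (%s)\n",
                  x$icer, x$quadrant))
  } else cat("  strategies comparable (no difference in mean)\n")
  if (!is.null(x$significance) && nzchar(x$significance))
    cat("  ", x$significance, "\n", sep = "")
  invisible(x)
}
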