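#' The eight-state ICU health-state space
#'
#' Defines the fixed state space used throughout the package: six transient
#' states describing an ICU patient's catheter / CRBSI / dermatitis status
#' and two absorbing states (discharge alive, death in ICU).
#'
#' States (codes are fixed, labels are the field's shorthand):
#' \enumerate{
#'   \item \code{NoAE/noCRBSI/noCTnew} -- catheterized, no adverse event,
#'     no infection, no new catheter inserted that day
#'   \item \code{NoAE/noCRBSI/CTnew} -- a new catheter inserted
#'   \item \code{NoAE/CRBSI/noCTnew} -- CRBSI diagnosed, no new catheter
#'   \item \code{NoAE/CRBSI/CTnew} -- CRBSI diagnosed and a new catheter
#'   \item \code{AE/noCRBSI/noCTnew} -- contact dermatitis (adverse event)
#'   \item \code{Dressing G+S} -- switch to a semipermeable transparent
#'     dressing after dermatitis
#'   \item \code{Discharge} -- leaves the ICU alive (absorbing)
#'   \item \code{Death} -- dies during the ICU stay (absorbing)
#' }
#'
#' The allowed-transition mask encodes the model structure: all transient
#' states may persist (self-loop) or absorb; the CRBSI states are reached
#' from the catheterized states 1--2; the neutral-dressing state 6 is
#' reached only from the dermatitis state 5 (and may emit back to 5 or
#' resolve to 1); absorbing states only self-loop.
#'
#' @return An object of class \code{state_space}: a list with elements
#'   \code{codes} (integer 1:8), \code{labels} (character), \code{absorbing}
#'   (integer codes), \code{transient} (integer codes), \code{crbsi}
#'   (integer codes of the CRBSI states) and \code{allowed} (8 x 8 logical
#'   mask, \code{allowed[i, j]} is \code{TRUE} when i -> j is permitted).
#' @examples
#' ss <- state_space()
#' ss$labels[ss$crbsi]
#' @export
state_space <- function() {
  labels <- c("NoAE/noCRBSI/noCTnew", "NoAE/noCRBSI/CTnew",
              "NoAE/CRBSI/noCTnew", "NoAE/CRBSI/CTnew",
              "AE/noCRBSI/noCTnew", "Dressing G+S",
              "Discharge", "Death")
  allowed <- matrix(FALSE, 8L, 8L, dimnames = list(1:8, 1:8))
  allowed[1, c(1, 2, 3, 4, 5, 7, 8)] <- TRUE
  allowed[2, c(1, 2, 3, 4, 5, 7, 8)] <- TRUE
  allowed[3, c(1, 2, 3, 4, 7, 8)] <- TRUE
  allowed[4, c(1, 2, 3, 4, 7, 8)] <- TRUE
  allowed[5, c(1, 5, 6, 7, 8)] <- TRUE
  allowed[6, c(1, 5, 6, 7, 8)] <- TRUE
  allowed[7, 7] <- TRUE
  allowed[8, 8] <- TRUE
  structure(
    list(codes = 1:8, labels = labels,
         absorbing = c(7L, 8L), transient = 1:6,
         crbsi = c(3L, 4L), allowed = allowed),
    class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("ICU health-state space (8 states)\n")
  for (i in x$codes) {
    tag <- if (i %in% x$absorbing) " [absorbing]"
           else if (i %in% x$crbsi) " [CRBSI]" else ""
    cat(sprintf("  %d  %s%s\n", i, x$labels[i], tag))
  }
  invisible(x)
}

#' Trial arm labels
#'
#' The four skin-antiseptic strategies compared: chlorhexidine-alcohol
#' (CHG) and povidone iodine-alcohol (PVI), each applied with a one-step
#' (T1) or four-step (T4, preceded by detergent scrub) procedure.
#'
#' @return Character vector of the four arm labels.
#' @export
arm_labels <- function() c("CHG-T1", "CHG-T4", "PVI-T1", "PVI-T4")

# internal: stop unless states are valid codes
check_states <- function(state) {
  bad <- !(state %in% 1:8) | is.na(state)
  if (any(bad))
    stop("unknown state code(s): ",
         paste(unique(state[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
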