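## State vector layout. Stores are per mol biomass C; O2 is a cytoplasm
## concentration; logB tracks log relative biomass.
.state_names <- c("CH2O", "CS", "N", "O2",
                  "Fe_PS", "Fe_NF", "Fe_buffer", "Fe_storage", "Fe_maint",
                  "logB")
.fe_pools <- c("Fe_PS", "Fe_NF", "Fe_buffer", "Fe_storage", "Fe_maint")

#' Construct a cell state
#'
#' The model state of one trichome: carbohydrate (`CH2O`), carbon-skeleton
#' (`CS`) and fixed-N (`N`) stores in mol per mol biomass C, intracellular O2
#' (mol m^-3), the five intracellular Fe pools (photosystems, active
#' nitrogenase, buffer, storage, maintenance; umol Fe per mol C), and log
#' relative biomass.
#'
#' @param CH2O,CS,N,O2 scalar stores (see description for units).
#' @param Fe_PS,Fe_NF,Fe_buffer,Fe_storage,Fe_maint Fe pools
#'   (umol Fe (mol C)^-1).
#' @param logB log relative biomass (0 = reference biomass).
#' @return Named numeric vector of class `cell_state`.
#' @export
cell_state <- function(CH2O = 0.05, CS = 0.05, N = 0.01, O2 = 0.213,
                       Fe_PS = 20, Fe_NF = 2, Fe_buffer = 10,
                       Fe_storage = 5, Fe_maint = 2, logB = 0) {
  s <- c(CH2O = CH2O, CS = CS, N = N, O2 = O2,
         Fe_PS = Fe_PS, Fe_NF = Fe_NF, Fe_buffer = Fe_buffer,
         Fe_storage = Fe_storage, Fe_maint = Fe_maint, logB = logB)
  class(s) <- "cell_state"
  s
}

#' Check cell-state invariants
#'
#' Reports (rather than errors on) invariant violations: every store and pool
#' must be non-negative and finite, and, when a recorded total is supplied,
#' the Fe pools must sum to it within `tol`.
#'
#' @param state a [cell_state()] (or plain named numeric vector with the same
#'   elements).
#' @param fe_total optional recorded total Fe (umol Fe (mol C)^-1) to check
#'   pool closure against.
#' @param tol absolute tolerance for the Fe closure check.
#' @return Character vector of violation messages; `character(0)` if the
#'   state is valid.
#' @examples
#' validate_state(cell_state())            # character(0)
#' validate_state(cell_state(CH2O = -0.1)) # names the offending field
#' @export
validate_state <- function(state, fe_total = NULL, tol = 1e-9) {
  out <- character(0)
  for (nm in setdiff(.state_names, "logB")) {
    v <- unname(state[nm])
    if (!is.finite(v)) {
      out <- c(out, paste0(nm, " is not finite"))
    } else if (v < 0) {
      out <- c(out, paste0(nm, " = ", format(v), " violates ", nm, " >= 0"))
    }
  }
  if (!is.null(fe_total)) {
    s <- sum(state[.fe_pools])
    if (is.finite(s) && abs(s - fe_total) > tol) {
      out <- c(out, paste0("Fe pools sum to ", format(s),
                           " but recorded total is ", format(fe_total),
                           " (|diff| > ", format(tol), ")"))
    }
  }
  out
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state>\n")
  cat(sprintf("  CH2O = %.4g, CS = %.4g mol C (mol C)^-1; N = %.4g mol N (mol C)^-1\n",
              x["CH2O"], x["CS"], x["N"]))
  cat(sprintf("  O2 = %.4g mol m^-3; biomass = %.4g (relative)\n",
              x["O2"], exp(x["logB"])))
  cat(sprintf("  Fe pools (umol (mol C)^-1): PS %.3g | NF %.3g | buffer %.3g | storage %.3g | maint %.3g\n",
              x["Fe_PS"], x["Fe_NF"], x["Fe_buffer"], x["Fe_storage"],
              x["Fe_maint"]))
  invisible(x)
}
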