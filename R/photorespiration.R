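#' Maximal photorespiration rate
#'
#' The photorespiration cap set by ATP supply: the rate at which
#' photorespiration would run if the ATP produced by photosynthetic electron
#' transport were consumed by photorespiration alone,
#' `V_PR_max = V_ATP / q_ATP_PR`.
#' `V_ATP` is the total instantaneous ATP production of PET before
#' allocation; the realized rate is further limited by substrates
#' ([photorespiration_rate()]) and by the per-step energy closure.
#'
#' @param V_ATP ATP production rate (mol ATP (mol C)^-1 s^-1).
#' @param q_ATP_PR ATP:C ratio of photorespiration (default 7).
#' @return `V_PR_max` (mol C (mol C)^-1 s^-1).
#' @examples
#' max_photorespiration(7e-6)  # 1e-6
#' @export
max_photorespiration <- function(V_ATP, q_ATP_PR = 7) {
  if (any(!is.finite(V_ATP)) || any(V_ATP < 0)) {
    stop("V_ATP must be non-negative and finite", call. = FALSE)
  }
  V_ATP / q_ATP_PR
}

#' Photorespiration rate
#'
#' Substrate regulation of photorespiration by the carbohydrate store and by
#' intracellular O2:
#' `V_PR = V_PR_max * CH2O/(CH2O + k_CH2O_PR) * O2/(O2 + k_O2_PR)`.
#'
#' @param V_PR_max cap from [max_photorespiration()]
#'   (mol C (mol C)^-1 s^-1).
#' @param CH2O carbohydrate store (mol C (mol C)^-1).
#' @param O2 intracellular O2 (mol m^-3).
#' @param params a [tricho_params()] registry (fields `k_CH2O_PR`,
#'   `k_O2_PR`).
#' @return `V_PR` in `[0, V_PR_max]` (mol C (mol C)^-1 s^-1).
#' @export
photorespiration_rate <- function(V_PR_max, CH2O, O2,
                                  params = tricho_params()) {
  if (any(c(V_PR_max, CH2O, O2) < 0) ||
      any(!is.finite(c(V_PR_max, CH2O, O2)))) {
    stop("V_PR_max, CH2O and O2 must be non-negative and finite",
         call. = FALSE)
  }
  V_PR_max * CH2O / (CH2O + params$k_CH2O_PR) * O2 / (O2 + params$k_O2_PR)
}

#' Photorespiration resource demands
#'
#' NADPH, ATP and O2 consumption of a given photorespiration rate, using the
#' pathway stoichiometry (defaults 4 NADPH, 7 ATP and 3 O2 per mol C).
#'
#' @param V_PR photorespiration rate (mol C (mol C)^-1 s^-1).
#' @param params a [tricho_params()] registry.
#' @return Named numeric vector `c(V_NADPH_PR, V_ATP_PR, V_O2_PR)`.
#' @examples
#' photorespiration_demands(1)  # 4, 7, 3
#' @export
photorespiration_demands <- function(V_PR, params = tricho_params()) {
  if (any(!is.finite(V_PR)) || any(V_PR < 0)) {
    stop("V_PR must be non-negative and finite", call. = FALSE)
  }
  c(V_NADPH_PR = params$q_NADPH_PR * V_PR,
    V_ATP_PR   = params$q_ATP_PR * V_PR,
    V_O2_PR    = params$q_O2_PR * V_PR)
}
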