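#' N2 fixation rate
#'
#' Nitrogenase activity limited by the Fe allocated to (active) nitrogenase
#' and inhibited by intracellular O2:
#' `V_NF = V_NF_max * Fe_NF/(Fe_NF + k_Fe_NF) * (1 - O2/(O2 + k_O2_NF))`.
#' The O2 factor equals `k_O2_NF / (O2 + k_O2_NF)`, so fixation shuts down
#' when intracellular O2 is well above `k_O2_NF` — N2 fixation is confined
#' to the low-O2 window.
#'
#' @param V_NF_max maximal potential rate set by the ATP/NADPH supply
#'   (mol N (mol C)^-1 s^-1).
#' @param Fe_NF active nitrogenase Fe (umol Fe (mol C)^-1).
#' @param O2 intracellular O2 (mol m^-3).
#' @param params a [tricho_params()] registry (fields `k_Fe_NF`, `k_O2_NF`).
#' @return `V_NF` in `[0, V_NF_max]` (mol N (mol C)^-1 s^-1).
#' @export
n2_fixation_rate <- function(V_NF_max, Fe_NF, O2, params = tricho_params()) {
  if (any(c(V_NF_max, Fe_NF, O2) < 0) ||
      any(!is.finite(c(V_NF_max, Fe_NF, O2)))) {
    stop("V_NF_max, Fe_NF and O2 must be non-negative and finite",
         call. = FALSE)
  }
  V_NF_max * Fe_NF / (Fe_NF + params$k_Fe_NF) *
    (1 - O2 / (O2 + params$k_O2_NF))
}

#' Respiratory protection rate
#'
#' Wasteful respiration of carbohydrate that draws down intracellular O2 to
#' protect nitrogenase. The rate rises with the demand for N2 fixation,
#' falls as intracellular O2 rises, and requires carbohydrate substrate:
#' `V_RP = v_RP_max * nf_demand * k_O2_RP/(k_O2_RP + O2) * CH2O/(CH2O + k_CH2O_RP)`.
#' This is the package's default law (a single swappable function); it
#' satisfies every qualitative constraint of the model description.
#'
#' @param v_RP_max calibrated maximal rate (mol C (mol C)^-1 s^-1).
#' @param nf_demand dimensionless N2 fixation demand in `[0, 1]` (1 = fully
#'   N-starved).
#' @param O2 intracellular O2 (mol m^-3).
#' @param CH2O carbohydrate store (mol C (mol C)^-1).
#' @param params a [tricho_params()] registry (fields `k_O2_RP`,
#'   `k_CH2O_RP`).
#' @return `V_RP` in `[0, v_RP_max]` (mol C (mol C)^-1 s^-1).
#' @export
respiratory_protection_rate <- function(v_RP_max, nf_demand, O2, CH2O,
                                        params = tricho_params()) {
  if (any(c(v_RP_max, nf_demand, O2, CH2O) < 0) ||
      any(!is.finite(c(v_RP_max, nf_demand, O2, CH2O)))) {
    stop("inputs must be non-negative and finite", call. = FALSE)
  }
  v_RP_max * nf_demand * params$k_O2_RP / (params$k_O2_RP + O2) *
    CH2O / (CH2O + params$k_CH2O_RP)
}

#' O2 consumption of respiratory protection
#'
#' Converts a per-biomass respiratory protection carbon flux into a
#' volumetric O2 consumption using the respiratory O2:C ratio and the
#' biomass carbon density of the cytoplasm:
#' `q_O2_resp * V_RP * rho_C` (mol O2 m^-3 s^-1).
#'
#' @param V_RP respiratory protection rate (mol C (mol C)^-1 s^-1).
#' @param params a [tricho_params()] registry (fields `q_O2_resp`, `rho_C`).
#' @return O2 consumption (mol O2 m^-3 s^-1, reported positive).
#' @export
rp_o2_consumption <- function(V_RP, params = tricho_params()) {
  if (any(!is.finite(V_RP)) || any(V_RP < 0)) {
    stop("V_RP must be non-negative and finite", call. = FALSE)
  }
  params$q_O2_resp * V_RP * params$rho_C
}
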