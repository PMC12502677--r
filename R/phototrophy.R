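#' Photosynthetic electron transport rate
#'
#' Total PET rate (both pathways), regulated by irradiance and by the Fe
#' allocated to photosystems, and down-regulated by respiratory protection:
#' `V_PET = v_PET_max * I/(I + k_I) * Fe_PS/(Fe_PS + k_Fe_PS) * 1/(1 + c_RP_inhib * V_RP)`.
#'
#' @param I irradiance (umol photons m^-2 s^-1).
#' @param Fe_PS photosystem Fe (umol Fe (mol C)^-1).
#' @param V_RP respiratory protection rate (mol C (mol C)^-1 s^-1).
#' @param params a [tricho_params()] registry.
#' @return `V_PET` (mol e- (mol C)^-1 s^-1).
#' @export
pet_rate <- function(I, Fe_PS, V_RP = 0, params = tricho_params()) {
  if (any(c(I, Fe_PS, V_RP) < 0) || any(!is.finite(c(I, Fe_PS, V_RP)))) {
    stop("I, Fe_PS and V_RP must be non-negative and finite", call. = FALSE)
  }
  params$v_PET_max * I / (I + params$k_I) *
    Fe_PS / (Fe_PS + params$k_Fe_PS) /
    (1 + params$c_RP_inhib * V_RP)
}

#' Partition electrons between linear and alternative transport
#'
#' Splits total PET into linear electron transport (LPET: ATP + NADPH,
#' evolves O2) and alternative electron transport (AET: ATP only) so that
#' the ATP:NADPH production ratio matches the demand ratio. With per-electron
#' yields `aL` (ATP, LPET), `nL` (NADPH, LPET) and `aA` (ATP, AET), the LPET
#' fraction solving
#' `(aL f + aA (1 - f)) / (nL f) = atp_demand / nadph_demand`
#' is `f = aA / (aA + rho * nL - aL)` with `rho` the demand ratio, clipped to
#' `[0, 1]`. Zero NADPH demand routes everything through AET; zero total
#' demand with positive PET is all-AET by convention.
#'
#' @param V_PET total electron transport (mol e- (mol C)^-1 s^-1).
#' @param atp_demand,nadph_demand instantaneous demands
#'   (mol (mol C)^-1 s^-1).
#' @param params a [tricho_params()] registry (yields `y_ATP_LPET`,
#'   `y_NADPH_LPET`, `y_ATP_AET`).
#' @return Named list with `V_LPET`, `V_AET` (summing exactly to `V_PET`),
#'   and realized `V_ATP`, `V_NADPH` production.
#' @export
partition_electrons <- function(V_PET, atp_demand, nadph_demand,
                                params = tricho_params()) {
  if (any(c(V_PET, atp_demand, nadph_demand) < 0) ||
      any(!is.finite(c(V_PET, atp_demand, nadph_demand)))) {
    stop("V_PET and demands must be non-negative and finite", call. = FALSE)
  }
  aL <- params$y_ATP_LPET
  nL <- params$y_NADPH_LPET
  aA <- params$y_ATP_AET
  if (nadph_demand == 0) {
    f <- 0  # only ATP needed (or no demand at all): all-AET by convention
  } else {
    rho <- atp_demand / nadph_demand
    denom <- aA + rho * nL - aL
    f <- if (denom <= 0) 1 else min(1, max(0, aA / denom))
  }
  V_LPET <- f * V_PET
  V_AET <- V_PET - V_LPET
  list(V_LPET = V_LPET, V_AET = V_AET,
       V_ATP = aL * V_LPET + aA * V_AET,
       V_NADPH = nL * V_LPET)
}

#' Gross photosynthetic O2 evolution
#'
#' O2 is produced exclusively by linear electron transport (water splitting
#' at photosystem II); alternative electron transport contributes none:
#' `y_O2_LPET * V_LPET`, in per-biomass units.
#'
#' @param V_LPET linear electron transport (mol e- (mol C)^-1 s^-1).
#' @param V_AET alternative electron transport (ignored by the law; accepted
#'   so the full split can be passed through).
#' @param params a [tricho_params()] registry (field `y_O2_LPET`).
#' @return Gross O2 production (mol O2 (mol C)^-1 s^-1).
#' @export
o2_evolution <- function(V_LPET, V_AET = 0, params = tricho_params()) {
  if (any(c(V_LPET, V_AET) < 0) || any(!is.finite(c(V_LPET, V_AET)))) {
    stop("rates must be non-negative and finite", call. = FALSE)
  }
  params$y_O2_LPET * V_LPET
}

#' Allocate ATP and NADPH to competing processes
#'
#' Waterfall allocation of the instantaneous ATP and NADPH supplies:
#' maintenance is served first, then photorespiration (up to its
#' substrate-limited demand), then N2 fixation, with carbon fixation (which
#' carries the CCM ATP overhead) as the residual sink co-limited by both
#' currencies. Each process runs at
#' `min(demand, ATP_left / q_ATP, NADPH_left / q_NADPH)`.
#' No demand is over-satisfied; if maintenance exceeds supply a starvation
#' flag is raised (a growth penalty upstream, not an error).
#'
#' When the supplies come from [partition_electrons()] evaluated at the
#' demands this allocation generates, production and consumption close
#' exactly; in general at least one currency is fully drained whenever the
#' residual sink is unsaturated.
#'
#' @param V_ATP,V_NADPH supplies (mol (mol C)^-1 s^-1).
#' @param demands named list with elements `maintenance` (ATP flux),
#'   `photorespiration` (mol C flux cap), `n2_fixation` (mol N flux cap) and
#'   `carbon_fixation` (mol C flux cap, e.g. the RuBisCO cap).
#' @param params a [tricho_params()] registry (stoichiometries `q_*`).
#' @return Named list: realized fluxes `maintenance`, `V_PR`, `V_NF`,
#'   `V_CF`, `V_CCM` (ATP overhead flux), leftovers `atp_left`,
#'   `nadph_left`, and logical `starved`.
#' @export
allocate_energy <- function(V_ATP, V_NADPH, demands,
                            params = tricho_params()) {
  need <- c("maintenance", "photorespiration", "n2_fixation",
            "carbon_fixation")
  if (!all(need %in% names(demands))) {
    stop("demands must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  d <- lapply(demands[need], as.numeric)
  if (any(unlist(d) < 0) || any(c(V_ATP, V_NADPH) < 0)) {
    stop("supplies and demands must be non-negative", call. = FALSE)
  }
  A <- V_ATP
  N <- V_NADPH
  ## maintenance: pure ATP sink, priority 1
  mnt <- min(d$maintenance, A)
  A <- A - mnt
  starved <- mnt < d$maintenance - 1e-300
  ## photorespiration
  V_PR <- min(d$photorespiration, A / params$q_ATP_PR,
              N / params$q_NADPH_PR)
  A <- A - params$q_ATP_PR * V_PR
  N <- N - params$q_NADPH_PR * V_PR
  ## N2 fixation
  V_NF <- min(d$n2_fixation, A / params$q_ATP_NF, N / params$q_NADPH_NF)
  A <- A - params$q_ATP_NF * V_NF
  N <- N - params$q_NADPH_NF * V_NF
  ## carbon fixation takes the residual, co-limited, carrying the CCM cost
  qA_CF <- params$q_ATP_CF + params$q_ATP_CCM
  V_CF <- min(d$carbon_fixation, A / qA_CF, N / params$q_NADPH_CF)
  A <- A - qA_CF * V_CF
  N <- N - params$q_NADPH_CF * V_CF
  list(maintenance = mnt, V_PR = V_PR, V_NF = V_NF, V_CF = V_CF,
       V_CCM = params$q_ATP_CCM * V_CF,
       atp_left = A, nadph_left = N, starved = starved)
}

#' Carbon-skeleton production
#'
#' Conversion of carbohydrate into carbon skeletons for biosynthesis,
#' stimulated by the carbohydrate store and down-regulated by accumulated
#' skeletons:
#' `v_CS_max * CH2O/(CH2O + k_CH2O_CS) * k_CS_inh/(k_CS_inh + CS)`.
#'
#' @param CH2O carbohydrate store (mol C (mol C)^-1).
#' @param CS carbon-skeleton store (mol C (mol C)^-1).
#' @param params a [tricho_params()] registry.
#' @return Production rate (mol C (mol C)^-1 s^-1), bounded by `v_CS_max`.
#' @export
carbon_skeleton_production <- function(CH2O, CS, params = tricho_params()) {
  if (any(c(CH2O, CS) < 0) || any(!is.finite(c(CH2O, CS)))) {
    stop("CH2O and CS must be non-negative and finite", call. = FALSE)
  }
  params$v_CS_max * CH2O / (CH2O + params$k_CH2O_CS) *
    params$k_CS_inh / (params$k_CS_inh + CS)
}
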