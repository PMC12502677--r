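#' Iron uptake rate
#'
#' Uptake of dissolved inorganic Fe with Michaelis-Menten dependence on the
#' ambient concentration and quota-based shut-off as the cell approaches its
#' maximal Fe quota:
#' `v_upFe_max * Fe_diss/(Fe_diss + k_Fe_diss) * max(0, 1 - Q/Fe_quota_max)`
#' where `Q` is the current total cell Fe (sum of the five pools). The
#' defaults map the 20-1800 pM scenario range onto equilibrium quotas of
#' roughly 10-1000 umol Fe (mol C)^-1.
#'
#' @param Fe_diss dissolved inorganic Fe (pM).
#' @param state a [cell_state()] (used for the current quota), or `NULL` for
#'   an empty cell.
#' @param params a [tricho_params()] registry.
#' @return Uptake rate (umol Fe (mol C)^-1 s^-1).
#' @export
fe_uptake <- function(Fe_diss, state = NULL, params = tricho_params()) {
  if (any(!is.finite(Fe_diss)) || any(Fe_diss < 0)) {
    stop("Fe_diss must be non-negative and finite", call. = FALSE)
  }
  Q <- if (is.null(state)) 0 else sum(state[.fe_pools])
  params$v_upFe_max * Fe_diss / (Fe_diss + params$k_Fe_diss) *
    max(0, 1 - Q / params$Fe_quota_max)
}

## Instantaneous Fe translocation fluxes (umol Fe (mol C)^-1 s^-1), all
## expressed as source -> sink transfers among the five pools. Synthesis of
## photosystems and nitrogenase draws on the buffer; photosystem
## decomposition and O2-driven nitrogenase inactivation return Fe to the
## buffer; storage exchanges first-order with the buffer; the maintenance
## pool relaxes toward a fixed share of metabolic Fe.
fe_translocation_fluxes <- function(state, rates, params, O2, I, nf_demand) {
  ## positional access into the canonical state layout (.state_names)
  CH2O <- state[[1L]]
  ps  <- state[[5L]]
  nf  <- state[[6L]]
  buf <- state[[7L]]
  sto <- state[[8L]]
  mnt <- state[[9L]]
  buf_sat <- buf / (buf + params$k_Fe_buffer)
  ## photosystem synthesis: light-driven, suppressed when carbohydrate ample
  syn_ps <- rates[[2L]] * buf_sat *
    I / (I + params$k_I) *
    params$k_CH2O_PS / (params$k_CH2O_PS + CH2O)
  ## photosystem decomposition: triggered by ample carbohydrate
  dec_ps <- rates[[3L]] * ps / (ps + params$k_Fe_PS_dec) *
    CH2O / (CH2O + params$k_CH2O_PS)
  ## nitrogenase synthesis: N demand under low O2, daylight only
  syn_nf <- if (I > 0) {
    rates[[4L]] * buf_sat * nf_demand *
      params$k_O2_NFsyn / (params$k_O2_NFsyn + O2)
  } else 0
  ## nitrogenase inactivation above the O2 threshold (Fe recycled to buffer)
  inact_nf <- params$k_NF_inact * nf * max(0, O2 - params$O2_thr_inact)
  ## storage <-> buffer, first order both ways
  b2s <- params$k_buf2sto * buf
  s2b <- params$k_sto2buf * sto
  ## maintenance pool relaxes toward its share of metabolic Fe
  metab <- ps + nf + buf + mnt
  mnt_target <- params$f_Fe_maint * metab
  mnt_flux <- params$k_Fe_maint * (mnt_target - mnt)  # buffer <-> maint
  c(syn_ps = syn_ps, dec_ps = dec_ps, syn_nf = syn_nf, inact_nf = inact_nf,
    b2s = b2s, s2b = s2b, mnt_flux = mnt_flux)
}

#' Translocate Fe among intracellular pools
#'
#' Advances the five Fe pools over one interval `dt` under the calibrated
#' maximal translocation rates: photosystem and nitrogenase synthesis draw
#' only on the buffer, photosystem decomposition and O2-driven nitrogenase
#' inactivation return Fe to the buffer, storage exchanges with the buffer,
#' and the maintenance pool relaxes toward a fixed share of metabolic Fe.
#' Any transfer that would drive its source pool negative is clamped to the
#' pool content. Total Fe is conserved exactly (no uptake inside this
#' operation).
#'
#' @param state a [cell_state()].
#' @param rates named vector with `T_PS_max_BF`, `T_BF_max_PS`,
#'   `T_NF_max_BF` (umol Fe (mol C)^-1 s^-1), e.g. [calibrated_defaults()].
#' @param dt time step (s).
#' @param params a [tricho_params()] registry.
#' @param O2 intracellular O2 (mol m^-3); defaults to the state's value.
#' @param I irradiance (umol photons m^-2 s^-1).
#' @param nf_demand dimensionless N2 fixation demand in `[0, 1]`.
#' @return The state with updated Fe pools; attribute `"clamped"` counts
#'   transfers that hit a pool floor.
#' @export
translocate_fe <- function(state, rates, dt, params = tricho_params(),
                           O2 = unname(state["O2"]), I = 0, nf_demand = 0) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!("v_RP_max" %in% names(rates))) rates <- c(v_RP_max = 0, rates)
  rates <- validate_calibrated(rates)
  fl <- fe_translocation_fluxes(state, rates, params, O2, I, nf_demand)
  out <- apply_fe_transfers(state, fl, dt)
  out
}

## Apply translocation fluxes over dt with per-source clamping. Transfers
## are netted per pool; each source pool's outgoing total is scaled down if
## it would overdraw the pool. Conserves the pool sum exactly.
apply_fe_transfers <- function(state, fl, dt) {
  buf <- unname(state["Fe_buffer"]); ps <- unname(state["Fe_PS"])
  nf <- unname(state["Fe_NF"]); sto <- unname(state["Fe_storage"])
  mnt <- unname(state["Fe_maint"])
  clamped <- 0L
  ## amounts over dt
  a_syn_ps <- fl[["syn_ps"]] * dt
  a_syn_nf <- fl[["syn_nf"]] * dt
  a_b2s <- fl[["b2s"]] * dt
  a_m <- fl[["mnt_flux"]] * dt        # buffer -> maint if positive
  a_dec_ps <- fl[["dec_ps"]] * dt
  a_inact <- fl[["inact_nf"]] * dt
  a_s2b <- fl[["s2b"]] * dt
  ## outgoing from buffer
  out_buf <- a_syn_ps + a_syn_nf + a_b2s + max(0, a_m)
  if (out_buf > buf && out_buf > 0) {
    sc <- buf / out_buf
    a_syn_ps <- a_syn_ps * sc; a_syn_nf <- a_syn_nf * sc
    a_b2s <- a_b2s * sc
    if (a_m > 0) a_m <- a_m * sc
    clamped <- clamped + 1L
  }
  ## outgoing from PS
  if (a_dec_ps > ps) { a_dec_ps <- ps; clamped <- clamped + 1L }
  ## outgoing from NF
  if (a_inact > nf) { a_inact <- nf; clamped <- clamped + 1L }
  ## outgoing from storage
  if (a_s2b > sto) { a_s2b <- sto; clamped <- clamped + 1L }
  ## outgoing from maintenance (negative mnt_flux = maint -> buffer)
  if (a_m < 0 && -a_m > mnt) { a_m <- -mnt; clamped <- clamped + 1L }
  state["Fe_buffer"] <- buf - a_syn_ps - a_syn_nf - a_b2s - a_m +
    a_dec_ps + a_inact + a_s2b
  state["Fe_PS"] <- ps + a_syn_ps - a_dec_ps
  state["Fe_NF"] <- nf + a_syn_nf - a_inact
  state["Fe_storage"] <- sto + a_b2s - a_s2b
  state["Fe_maint"] <- mnt + a_m
  attr(state, "clamped") <- clamped
  state
}
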