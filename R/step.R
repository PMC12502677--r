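## Compiled scenario: unpacks every registry constant into closure locals
## once per run and returns the per-instant evaluators used by the
## integrator. `o2bal(t, s, O2, pf)` is the slim volumetric O2 balance used
## inside the quasi-steady-state root solve; `full(t, s, O2, pf)` computes
## the state derivatives and the named flux record.
##
## The ATP/NADPH closure is solved in closed form: ATP is allocated down the
## priority list (maintenance, photorespiration, N2 fixation, carbon
## fixation + CCM as the residual sink); unused ATP down-regulates PET (sink
## limitation); the LPET fraction is then set so NADPH production equals
## NADPH consumption exactly. This requires equal per-electron ATP yields of
## the two pathways (the default), which makes total ATP production
## independent of the split.
compile_model <- function(env, params, mode, rates) {
  ## environment
  P <- env$photoperiod * 3600
  I_peak <- if (env$light == "sine") env$I_max else env$I_const
  sine <- env$light == "sine"
  O2_ext <- env$O2_ext
  Fe_diss <- env$Fe_diss
  dyn <- mode == "dynamic"
  ## geometry -> conductance pieces: g = gfac / (r_mem_ln / eps + r_bl)
  gm <- params$geometry
  r_mem_ln <- log((gm$R + gm$Lg) / gm$R)
  r_bl <- log((gm$R + gm$Lg + gm$Lb) / (gm$R + gm$Lg))
  gfac <- 2 * pi * params$d_O2 * gm$L / gm$V
  g_fixed <- gfac / (r_mem_ln / params$eps_fixed + r_bl)
  ## registry scalars
  eps_max <- params$eps_max; k_O2_diff <- params$k_O2_diff
  eps_fixed <- params$eps_fixed
  q_ATP_PR <- params$q_ATP_PR; q_NADPH_PR <- params$q_NADPH_PR
  q_O2_PR <- params$q_O2_PR; k_CH2O_PR <- params$k_CH2O_PR
  k_O2_PR <- params$k_O2_PR
  k_Fe_NF <- params$k_Fe_NF; k_O2_NF <- params$k_O2_NF
  q_ATP_NF <- params$q_ATP_NF; q_NADPH_NF <- params$q_NADPH_NF
  k_O2_RP <- params$k_O2_RP; k_CH2O_RP <- params$k_CH2O_RP
  k_N_demand <- params$k_N_demand; q_O2_resp <- params$q_O2_resp
  k_Fe_NF_RP <- params$k_Fe_NF_RP
  q_ATP_OR <- params$q_ATP_OR; k_O2_avail <- params$k_O2_avail
  v_PET_max <- params$v_PET_max; k_I <- params$k_I
  k_Fe_PS <- params$k_Fe_PS; c_RP_inhib <- params$c_RP_inhib
  y_ATP <- params$y_ATP_AET; y_NADPH_LPET <- params$y_NADPH_LPET
  y_O2_LPET <- params$y_O2_LPET
  q_ATP_CF <- params$q_ATP_CF; q_NADPH_CF <- params$q_NADPH_CF
  q_ATP_CCM <- params$q_ATP_CCM; V_CF_max <- params$V_CF_max
  v_CS_max <- params$v_CS_max; k_CH2O_CS <- params$k_CH2O_CS
  k_CS_inh <- params$k_CS_inh
  v_BIO_max <- params$v_BIO_max; k_CS_BIO <- params$k_CS_BIO
  k_N_BIO <- params$k_N_BIO; q_N_BIO <- params$q_N_BIO
  m_ATP <- params$m_ATP
  v_upFe_max <- params$v_upFe_max; k_Fe_diss <- params$k_Fe_diss
  Fe_quota_max <- params$Fe_quota_max; k_Fe_buffer <- params$k_Fe_buffer
  k_Fe_PS_dec <- params$k_Fe_PS_dec; k_CH2O_PS <- params$k_CH2O_PS
  k_O2_NFsyn <- params$k_O2_NFsyn; k_NF_inact <- params$k_NF_inact
  ## clock-driven diel allocation phases (s since dawn)
  tPSe <- params$t_PS_syn_end * P
  tPDs <- params$t_PS_dec_start * P
  tNFs <- params$t_NF_syn_start * P
  O2_thr_inact <- params$O2_thr_inact
  k_buf2sto <- params$k_buf2sto; k_sto2buf <- params$k_sto2buf
  f_Fe_maint <- params$f_Fe_maint; k_Fe_maint <- params$k_Fe_maint
  rho_C <- params$rho_C
  qA_CF <- q_ATP_CF + q_ATP_CCM
  up_base <- v_upFe_max * Fe_diss / (Fe_diss + k_Fe_diss)
  v_RP_cal <- rates[[1L]]; T_PS_syn <- rates[[2L]]
  T_PS_dec <- rates[[3L]]; T_NF_syn <- rates[[4L]]

  light <- function(t) {
    if (t < 0 || t >= P) 0 else if (sine) I_peak * sin(pi * t / P) else
      I_peak
  }

  ## energy chain shared by both evaluators; returns the realized carbon /
  ## nitrogen / electron fluxes at a given intracellular O2
  chain <- function(t, s, O2, pf) {
    I <- light(t)
    day <- I > 0
    CH2O <- s[[1L]]; N <- s[[3L]]
    nf_demand <- max(0, 1 - N / k_N_demand)
    ## RP protects working nitrogenase: its demand signal is the N deficit
    ## scaled by the active nitrogenase actually present, following the
    ## circadian nif program (nothing to protect before the phase opens)
    rp_demand <- nf_demand * s[[6L]] / (s[[6L]] + k_Fe_NF_RP)
    avail <- O2 / (O2 + k_O2_avail)
    V_RP <- if (day && t >= tNFs) {
      v_RP_cal * rp_demand * k_O2_RP / (k_O2_RP + O2) *
        CH2O / (CH2O + k_CH2O_RP) * avail
    } else 0
    V_PET_pot <- if (day) {
      v_PET_max * I / (I + k_I) * s[[5L]] / (s[[5L]] + k_Fe_PS) /
        (1 + c_RP_inhib * V_RP)
    } else 0
    V_ATP <- y_ATP * V_PET_pot
    A <- V_ATP
    mnt <- if (A < m_ATP) A else m_ATP
    A <- A - mnt
    short <- m_ATP - mnt
    V_OR <- if (short > 0) {
      short / q_ATP_OR * avail * CH2O / (CH2O + k_CH2O_RP)
    } else 0
    starved <- short > 0 && V_OR * q_ATP_OR < 0.999 * short
    V_PR_max <- V_ATP / q_ATP_PR
    ## native substrate-limited photorespiration at the current O2
    V_PR_nat <- if (day) {
      V_PR_max * CH2O / (CH2O + k_CH2O_PR) * O2 / (O2 + k_O2_PR)
    } else 0
    ## a forced trajectory (substitution counterfactual) replaces the rate
    ## charged to the carbon and energy books; the O2 balance keeps the
    ## native photorespiratory sink so the counterfactual isolates the
    ## photorespiration burden rather than crediting it as O2 removal
    V_PR_dem <- if (!is.null(pf)) pf else V_PR_nat
    V_PR <- min(V_PR_dem, A / q_ATP_PR)
    A <- A - q_ATP_PR * V_PR
    ## the ATP committed to N2 fixation is regulated by the fixed-N
    ## deficit (product feedback) and by the circadian nif program (no
    ## commitment before the nitrogenase-synthesis phase opens)
    V_NF_max <- if (day && t >= tNFs) A / q_ATP_NF * nf_demand else 0
    V_NF <- V_NF_max * s[[6L]] / (s[[6L]] + k_Fe_NF) *
      k_O2_NF / (O2 + k_O2_NF)
    A <- A - q_ATP_NF * V_NF
    V_CF <- if (day) min(A / qA_CF, V_CF_max) else 0
    A_left <- A - qA_CF * V_CF
    V_PET <- V_PET_pot - A_left / y_ATP
    N_dem <- q_NADPH_PR * V_PR + q_NADPH_NF * V_NF + q_NADPH_CF * V_CF
    V_LPET <- min(V_PET, N_dem / y_NADPH_LPET)
    ## volumetric O2 balance
    o2_pr <- q_O2_PR * (if (is.null(pf)) V_PR else min(V_PR_nat, V_PR_max))
    P_O2 <- y_O2_LPET * V_LPET * rho_C
    C_O2 <- (o2_pr + q_O2_resp * (V_RP + V_OR)) * rho_C
    eps <- if (dyn) eps_max * O2 / (O2 + k_O2_diff) else eps_fixed
    g <- if (dyn) gfac / (r_mem_ln / max(eps, 1e-12) + r_bl) else g_fixed
    T_O2 <- g * (O2_ext - O2)
    list(I = I, nf_demand = nf_demand, V_RP = V_RP, V_OR = V_OR,
         V_PR = V_PR, V_PR_max = V_PR_max, V_NF = V_NF,
         V_NF_max = V_NF_max, V_CF = V_CF, V_PET = V_PET,
         V_LPET = V_LPET, V_AET = V_PET - V_LPET,
         V_ATP = V_ATP - A_left, N_dem = N_dem,
         P_O2 = P_O2, C_O2 = C_O2, T_O2 = T_O2, eps = eps,
         dO2 = P_O2 - C_O2 + T_O2, starved = starved)
  }

  ## slim O2 balance for the root solve (skips Fe and store bookkeeping)
  o2bal <- function(t, s, O2, pf) {
    I <- light(t)
    day <- I > 0
    CH2O <- s[[1L]]
    avail <- O2 / (O2 + k_O2_avail)
    nf_demand <- max(0, 1 - s[[3L]] / k_N_demand)
    rp_demand <- nf_demand * s[[6L]] / (s[[6L]] + k_Fe_NF_RP)
    V_RP <- if (day && t >= tNFs) {
      v_RP_cal * rp_demand *
        k_O2_RP / (k_O2_RP + O2) * CH2O / (CH2O + k_CH2O_RP) * avail
    } else 0
    V_PET_pot <- if (day) {
      v_PET_max * I / (I + k_I) * s[[5L]] / (s[[5L]] + k_Fe_PS) /
        (1 + c_RP_inhib * V_RP)
    } else 0
    V_ATP <- y_ATP * V_PET_pot
    A <- V_ATP
    mnt <- if (A < m_ATP) A else m_ATP
    A <- A - mnt
    short <- m_ATP - mnt
    V_OR <- if (short > 0) {
      short / q_ATP_OR * avail * CH2O / (CH2O + k_CH2O_RP)
    } else 0
    V_PR_nat <- if (day) {
      (V_ATP / q_ATP_PR) * CH2O / (CH2O + k_CH2O_PR) * O2 / (O2 + k_O2_PR)
    } else 0
    V_PR <- min(if (!is.null(pf)) pf else V_PR_nat, A / q_ATP_PR)
    A <- A - q_ATP_PR * V_PR
    V_NF <- if (day && t >= tNFs) {
      (A / q_ATP_NF) * nf_demand *
        s[[6L]] / (s[[6L]] + k_Fe_NF) * k_O2_NF / (O2 + k_O2_NF)
    } else 0
    A <- A - q_ATP_NF * V_NF
    V_CF <- if (day) min(A / qA_CF, V_CF_max) else 0
    A_left <- A - qA_CF * V_CF
    V_PET <- V_PET_pot - A_left / y_ATP
    N_dem <- q_NADPH_PR * V_PR + q_NADPH_NF * V_NF + q_NADPH_CF * V_CF
    V_LPET <- min(V_PET, N_dem / y_NADPH_LPET)
    o2_pr <- q_O2_PR * (if (is.null(pf)) V_PR else
      min(V_PR_nat, V_ATP / q_ATP_PR))
    eps <- if (dyn) eps_max * O2 / (O2 + k_O2_diff) else eps_fixed
    g <- if (dyn) gfac / (r_mem_ln / max(eps, 1e-12) + r_bl) else g_fixed
    y_O2_LPET * V_LPET * rho_C -
      (o2_pr + q_O2_resp * (V_RP + V_OR)) * rho_C +
      g * (O2_ext - O2)
  }

  ## full evaluation: derivatives + flux record fields
  full <- function(t, s, O2, pf) {
    ch <- chain(t, s, O2, pf)
    CH2O <- s[[1L]]; CS <- s[[2L]]; N <- s[[3L]]
    V_CS <- v_CS_max * CH2O / (CH2O + k_CH2O_CS) *
      k_CS_inh / (k_CS_inh + CS)
    G <- v_BIO_max * CS / (CS + k_CS_BIO) * N / (N + k_N_BIO)
    quota <- s[[5L]] + s[[6L]] + s[[7L]] + s[[8L]] + s[[9L]]
    up <- up_base * max(0, 1 - quota / Fe_quota_max)
    ## Fe translocation
    buf <- s[[7L]]
    buf_sat <- buf / (buf + k_Fe_buffer)
    syn_ps <- if (t >= 0 && t < tPSe) {
      T_PS_syn * buf_sat * ch$I / (ch$I + k_I) *
        k_CH2O_PS / (k_CH2O_PS + CH2O)
    } else 0
    dec_ps <- if (t >= tPDs && t < P) {
      T_PS_dec * s[[5L]] / (s[[5L]] + k_Fe_PS_dec) *
        CH2O / (CH2O + k_CH2O_PS)
    } else 0
    syn_nf <- if (ch$I > 0 && t >= tNFs) {
      T_NF_syn * buf_sat * ch$nf_demand * k_O2_NFsyn / (k_O2_NFsyn + O2)
    } else 0
    inact <- k_NF_inact * s[[6L]] * max(0, O2 - O2_thr_inact)
    b2s <- k_buf2sto * buf
    s2b <- k_sto2buf * s[[8L]]
    mnt_target <- f_Fe_maint * (s[[5L]] + s[[6L]] + buf + s[[9L]])
    mnt_fl <- k_Fe_maint * (mnt_target - s[[9L]])
    d <- c(ch$V_CF - ch$V_PR - ch$V_RP - ch$V_OR - V_CS - G * CH2O,
           V_CS - G - G * CS,
           ch$V_NF - q_N_BIO * G - G * N,
           ch$dO2,
           syn_ps - dec_ps - G * s[[5L]],
           syn_nf - inact - G * s[[6L]],
           up - syn_ps - syn_nf + dec_ps + inact - b2s + s2b - mnt_fl -
             G * buf,
           b2s - s2b - G * s[[8L]],
           mnt_fl - G * s[[9L]],
           G)
    if (any(!is.finite(d))) {
      bad <- .state_names[!is.finite(d)]
      stop("non-finite derivative in term(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    list(d = d, ch = ch, V_CS = V_CS, G = G, up = up)
  }

  list(o2bal = o2bal, full = full, light = light,
       g_fixed = g_fixed, env = env)
}

## Named flux record from a full evaluation (built only when recording).
flux_record <- function(ev, params) {
  ch <- ev$ch
  c(V_PET = ch$V_PET, V_LPET = ch$V_LPET, V_AET = ch$V_AET,
    V_ATP = ch$V_ATP, V_NADPH = ch$N_dem,
    V_CF = ch$V_CF, V_PR = ch$V_PR, V_PR_max = ch$V_PR_max,
    V_ATP_PR = params$q_ATP_PR * ch$V_PR,
    V_NADPH_PR = params$q_NADPH_PR * ch$V_PR,
    V_O2_PR = params$q_O2_PR * ch$V_PR,
    V_NF = ch$V_NF, V_NF_max = ch$V_NF_max,
    V_RP = ch$V_RP, V_OR = ch$V_OR, V_CS = ev$V_CS,
    V_CCM = params$q_ATP_CCM * ch$V_CF,
    T_O2 = ch$T_O2, P_O2 = ch$P_O2, C_O2 = ch$C_O2,
    eps = ch$eps, G = ev$G, I = ch$I, Fe_uptake = ev$up,
    starved = as.numeric(ch$starved))
}

## Quasi-steady-state intracellular O2: root of the slim O2 balance at the
## current slow state. Warm-started secant iteration with a bracketed
## bisection fallback.
qss_root <- function(o2bal, t, s, pf, o2_start, O2_ext, atol = 1e-12) {
  x1 <- max(o2_start, 1e-9)
  f1 <- o2bal(t, s, x1, pf)
  if (abs(f1) <= atol) return(x1)
  x2 <- x1 * 1.02 + 1e-7
  f2 <- o2bal(t, s, x2, pf)
  for (i in 1:20) {
    if (abs(f2) <= atol) return(x2)
    if (f2 == f1) break
    x3 <- x2 - f2 * (x2 - x1) / (f2 - f1)
    if (!is.finite(x3) || x3 < 0 || x3 > 50) break
    x1 <- x2; f1 <- f2
    x2 <- x3; f2 <- o2bal(t, s, x2, pf)
  }
  ## fallback: the balance is >= 0 at O2 = 0 (no consumption, no efflux);
  ## expand upward until negative, then bisect
  lo <- 0; hi <- max(2 * o2_start, O2_ext + 0.5)
  fh <- o2bal(t, s, hi, pf)
  while (fh > 0 && hi < 1e4) { hi <- hi * 4; fh <- o2bal(t, s, hi, pf) }
  if (fh > 0) stop("QSS O2 solve failed to bracket a root", call. = FALSE)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    fm <- o2bal(t, s, mid, pf)
    if (abs(fm) <= atol || (hi - lo) < 1e-16) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Advance the model one time step
#'
#' One integration step of the diel model. With `o2_method = "qss"` (the
#' default) intracellular O2 is taken at its quasi-steady state — the root
#' of the volumetric O2 balance at the current slow state, re-solved at
#' every stage — and the slow states advance by Heun's method (explicit
#' trapezoidal RK2). With `o2_method = "explicit"` all states, O2 included,
#' advance by classic RK4; the membrane conductance makes O2 stiff
#' (relaxation time ~0.1 s for the default geometry), so explicit stepping
#' requires `dt` safely below the stability bound and the function errors
#' on an unconditionally unstable step.
#'
#' Stores are floored at zero after the update (consumption in excess of a
#' store within one step is clamped); the number of floored components is
#' returned in the `"clamped"` attribute.
#'
#' @param state a [cell_state()] (or named numeric vector in the same
#'   layout).
#' @param t time since dawn (s).
#' @param env a [tricho_env()].
#' @param params a [tricho_params()].
#' @param dt time step (s).
#' @param mode `"dynamic"` or `"fixed"` membrane permeability.
#' @param rates calibrated rate vector (default: shipped per-mode values).
#' @param o2_method `"qss"` or `"explicit"`.
#' @param pr_force optional forced photorespiration rate for this step
#'   (mol C (mol C)^-1 s^-1), used by the substitution experiment.
#' @return List with `state` (advanced state, `"clamped"` attribute) and
#'   `flux` (named flux record at the start of the step, including `eps`,
#'   `T_O2` and the growth rate `G`).
#' @export
diel_step <- function(state, t, env, params, dt,
                      mode = c("dynamic", "fixed"),
                      rates = calibrated_defaults(mode),
                      o2_method = c("qss", "explicit"), pr_force = NULL) {
  mode <- match.arg(mode)
  o2_method <- match.arg(o2_method)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  check_energy_yields(params)
  rates <- validate_calibrated(rates)
  s <- as.numeric(state)
  cm <- compile_model(env, params, mode, rates)
  if (o2_method == "qss") {
    s[[4L]] <- qss_root(cm$o2bal, t, s, pr_force, s[[4L]], env$O2_ext)
    ev1 <- cm$full(t, s, s[[4L]], pr_force)
    k1 <- ev1$d; k1[[4L]] <- 0
    sp <- s + dt * k1
    sp[sp < 0] <- 0
    o2p <- qss_root(cm$o2bal, t + dt, sp, pr_force, s[[4L]], env$O2_ext)
    ev2 <- cm$full(t + dt, sp, o2p, pr_force)
    k2 <- ev2$d; k2[[4L]] <- 0
    out <- s + dt * 0.5 * (k1 + k2)
    out[[4L]] <- o2p
    flux <- flux_record(ev1, params)
  } else {
    g_max <- o2_conductance(params$eps_max, params$geometry, params$d_O2)
    if (dt * g_max > 2.5) {
      stop("explicit O2 integration unstable: dt * conductance = ",
           format(dt * g_max), " > 2.5; reduce dt or use o2_method = 'qss'",
           call. = FALSE)
    }
    f <- function(tt, ss) cm$full(tt, ss, max(ss[[4L]], 0), pr_force)$d
    k1 <- f(t, s)
    k2 <- f(t + dt / 2, pmax(s + dt / 2 * k1, .state_floor))
    k3 <- f(t + dt / 2, pmax(s + dt / 2 * k2, .state_floor))
    k4 <- f(t + dt, pmax(s + dt * k3, .state_floor))
    out <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    flux <- flux_record(cm$full(t, s, max(s[[4L]], 0), pr_force), params)
  }
  clamped <- sum(out[seq_len(9L)] < 0)
  out[seq_len(9L)] <- pmax(out[seq_len(9L)], 0)
  names(out) <- .state_names
  class(out) <- "cell_state"
  attr(out, "clamped") <- clamped
  list(state = out, flux = flux)
}

.state_floor <- c(rep(0, 9), -Inf)

## Back-compatible single-point evaluation used by tests and diagnostics:
## derivatives, flux record and O2 tendency at a prescribed O2.
flux_eval <- function(t, s, env, params, mode, rates, O2,
                      pr_force = NULL) {
  cm <- compile_model(env, params, mode, validate_calibrated(rates))
  ev <- cm$full(t, as.numeric(s), O2, pr_force)
  list(d = ev$d, flux = flux_record(ev, params), dO2 = ev$ch$dO2)
}

check_energy_yields <- function(params) {
  if (abs(params$y_ATP_LPET - params$y_ATP_AET) > 1e-12) {
    stop("the closed-form energy closure requires equal per-electron ATP ",
         "yields for LPET and AET (y_ATP_LPET == y_ATP_AET)", call. = FALSE)
  }
  invisible(TRUE)
}
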