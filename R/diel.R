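#' Run the diel model to a periodic steady state
#'
#' Integrates the full trichome model over repeated day cycles (default:
#' 12 h half-sine photoperiod + 12 h dark) until the daily growth rate is
#' periodic — successive cycles differ by less than `conv_tol` (d^-1) — or
#' `max_cycles` is reached. The returned object carries the final cycle's
#' time series, the biomass-weighted daily integrals, the carbon-budget
#' decomposition, carbon and Fe use efficiencies, and the diagnosed low-O2
#' window.
#'
#' @param env a [tricho_env()] scenario forcing.
#' @param mode `"dynamic"` (O2-regulated membrane permeability) or
#'   `"fixed"`.
#' @param params a [tricho_params()] registry.
#' @param rates calibrated rate vector (`v_RP_max`, `T_PS_max_BF`,
#'   `T_BF_max_PS`, `T_NF_max_BF`); defaults to `params$calibrated` if set,
#'   otherwise the shipped per-mode values.
#' @param dt integration step (s).
#' @param day_length_h cycle length (h). The default 24 runs photoperiod +
#'   dark; set equal to `env$photoperiod` for a photoperiod-only cycle.
#' @param conv_tol periodicity tolerance on the daily growth rate (d^-1).
#' @param max_cycles spin-up cap; non-convergence warns and returns the last
#'   cycle.
#' @param init_state starting [cell_state()].
#' @param pr_force optional forced photorespiration trajectory: a function
#'   of time-of-day (s) returning mol C (mol C)^-1 s^-1 (used by the
#'   substitution experiment).
#' @return An object of class `diel_run`.
#' @examples
#' \donttest{
#' run <- run_diel(tricho_env(Fe_diss = 40), mode = "dynamic", dt = 120,
#'                 conv_tol = 1e-3, max_cycles = 10)
#' summary(run)
#' }
#' @export
run_diel <- function(env, mode = c("dynamic", "fixed"),
                     params = tricho_params(), rates = NULL, dt = 20,
                     day_length_h = 24, conv_tol = 1e-5, max_cycles = 60,
                     init_state = cell_state(O2 = env$O2_ext),
                     pr_force = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "tricho_env"), inherits(params, "tricho_params"))
  check_energy_yields(params)
  if (is.null(rates)) {
    rates <- if (!is.null(params$calibrated)) params$calibrated else
      calibrated_defaults(mode)
  }
  rates <- validate_calibrated(rates)
  if (day_length_h < env$photoperiod) {
    stop("day_length_h must be at least the photoperiod", call. = FALSE)
  }
  n_steps <- max(2L, as.integer(round(day_length_h * 3600 / dt)))
  dt <- day_length_h * 3600 / n_steps
  tgrid <- (seq_len(n_steps) - 1L) * dt
  pr_vec <- if (is.null(pr_force)) NULL else
    pmax(vapply(tgrid, pr_force, numeric(1)), 0)

  s <- as.numeric(init_state)
  cm <- compile_model(env, params, mode, rates)
  o2bal <- cm$o2bal
  full <- cm$full
  states <- matrix(NA_real_, n_steps, length(.state_names))
  colnames(states) <- .state_names
  fluxes <- NULL
  acc_names <- c("V_CF", "V_PR", "V_RP", "V_OR", "G", "V_NF", "V_CS")
  mu <- mu_prev <- NA_real_
  last_delta <- NA_real_
  converged <- FALSE
  clamp_events <- 0L
  n_cycles <- 0L
  day_days <- day_length_h / 24

  for (cycle in seq_len(max_cycles)) {
    n_cycles <- cycle
    logB0 <- s[[10L]]
    acc <- numeric(length(acc_names))
    stores0 <- s[[1L]] + s[[2L]]
    metab_fe_acc <- 0
    for (i in seq_len(n_steps)) {
      t <- tgrid[[i]]
      pf <- if (is.null(pr_vec)) NULL else pr_vec[[i]]
      s[[4L]] <- qss_root(o2bal, t, s, pf, s[[4L]], env$O2_ext)
      ev1 <- full(t, s, s[[4L]], pf)
      k1 <- ev1$d; k1[[4L]] <- 0
      sp <- s + dt * k1
      sp[sp < 0] <- 0
      pf2 <- if (is.null(pr_vec)) NULL else
        pr_vec[[if (i == n_steps) 1L else i + 1L]]
      o2p <- qss_root(o2bal, t + dt, sp, pf2, s[[4L]], env$O2_ext)
      ev2 <- full(t + dt, sp, o2p, pf2)
      k2 <- ev2$d; k2[[4L]] <- 0
      out <- s + dt * 0.5 * (k1 + k2)
      out[[4L]] <- o2p
      neg <- out[seq_len(9L)] < 0
      if (any(neg)) {
        clamp_events <- clamp_events + sum(neg)
        out[seq_len(9L)][neg] <- 0
      }
      ## record and accumulate (biomass-weighted, relative to cycle start)
      B <- exp(s[[10L]] - logB0)
      fx <- flux_record(ev1, params)
      if (is.null(fluxes)) {
        fluxes <- matrix(NA_real_, n_steps, length(fx))
        colnames(fluxes) <- names(fx)
      }
      states[i, ] <- s
      fluxes[i, ] <- fx
      ch <- ev1$ch
      acc <- acc + B * dt *
        c(ch$V_CF, ch$V_PR, ch$V_RP, ch$V_OR, ev1$G, ch$V_NF, ev1$V_CS)
      metab_fe_acc <- metab_fe_acc +
        s[[5L]] + s[[6L]] + s[[7L]] + s[[9L]]
      s <- out
    }
    mu <- (s[[10L]] - logB0) / day_days
    if (!is.na(mu_prev)) {
      last_delta <- abs(mu - mu_prev)
      if (last_delta < conv_tol) {
        converged <- TRUE
        break
      }
    }
    mu_prev <- mu
  }
  if (!converged) {
    warning("diel spin-up did not reach periodicity within ", max_cycles,
            " cycles (last growth change ",
            format(last_delta, digits = 3), " d^-1)", call. = FALSE)
  }

  names(acc) <- acc_names
  B_end <- exp(s[[10L]] - logB0)
  stores_d <- B_end * (s[[1L]] + s[[2L]]) - stores0
  CF_d <- acc[["V_CF"]]
  bio_net <- acc[["G"]] + stores_d
  closure <- CF_d - acc[["V_PR"]] - acc[["V_RP"]] - acc[["V_OR"]] - bio_net
  budget <- c(photorespiration = acc[["V_PR"]] / CF_d,
              respiratory_protection = acc[["V_RP"]] / CF_d,
              ordinary_respiration = acc[["V_OR"]] / CF_d,
              biosynthesis = bio_net / CF_d)
  metab_fe <- metab_fe_acc / n_steps
  win <- low_o2_window(tgrid, states[, "O2"], fluxes[, "V_NF"],
                       env, exp(states[, "logB"] - logB0), dt)

  structure(list(
    time = tgrid, states = states, fluxes = fluxes,
    growth = mu, growth_delta = last_delta, converged = converged,
    cycles = n_cycles,
    daily = c(gross_carbon_fixation = CF_d,
              photorespiration = acc[["V_PR"]],
              respiratory_protection = acc[["V_RP"]],
              ordinary_respiration = acc[["V_OR"]],
              biosynthesis = acc[["G"]],
              net_storage_change = stores_d,
              n2_fixation = acc[["V_NF"]]),
    budget_fractions = budget,
    carbon_use_efficiency = unname(budget[["biosynthesis"]]),
    fe_use_efficiency = acc[["V_NF"]] / metab_fe,
    metabolic_fe = metab_fe,
    budget_closure = closure / CF_d,
    window = win,
    clamp_events = clamp_events,
    mode = mode, env = env, dt = dt, day_length_h = day_length_h,
    rates = rates, params = params,
    final_state = `class<-`(stats::setNames(s, .state_names), "cell_state"),
    pr_traj = fluxes[, "V_PR"]
  ), class = "diel_run")
}

## Longest contiguous photoperiod interval with intracellular O2 below the
## ambient concentration, and the share of daily N2 fixation inside it.
low_o2_window <- function(tgrid, O2, V_NF, env, Bw, dt) {
  P <- env$photoperiod * 3600
  in_day <- tgrid < P
  below <- in_day & (O2 < env$O2_ext)
  if (!any(below)) {
    return(list(start_h = NA_real_, end_h = NA_real_, width_h = 0,
                nf_inside_fraction = 0))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  nf_tot <- sum(Bw * V_NF) * dt
  nf_in <- sum(Bw[idx] * V_NF[idx]) * dt
  list(start_h = tgrid[idx[1L]] / 3600,
       end_h = tgrid[idx[length(idx)]] / 3600,
       width_h = (tgrid[idx[length(idx)]] - tgrid[idx[1L]]) / 3600 +
         dt / 3600,
       nf_inside_fraction = if (nf_tot > 0) nf_in / nf_tot else 0)
}

#' @export
print.diel_run <- function(x, ...) {
  cat("<diel_run> ", x$mode, "-permeability, Fe_diss = ", x$env$Fe_diss,
      " pM, ", x$env$light, " light\n", sep = "")
  cat(sprintf("  growth %.4f d^-1 (%s after %d cycles)\n", x$growth,
              if (x$converged) "periodic" else "NOT converged", x$cycles))
  cat(sprintf("  gross C fixation %.3f mol C (mol C)^-1 d^-1; CUE %.3f\n",
              x$daily[["gross_carbon_fixation"]],
              x$carbon_use_efficiency))
  invisible(x)
}

#' @export
summary.diel_run <- function(object, ...) {
  x <- object
  print(x)
  b <- x$budget_fractions
  cat("  carbon budget fractions of gross fixation:\n")
  for (nm in names(b)) cat(sprintf("    %-24s %6.2f%%\n", nm, 100 * b[[nm]]))
  cat(sprintf("  daily N2 fixation %.4g mol N (mol C)^-1 d^-1; Fe use efficiency %.4g mol N (umol Fe)^-1 d^-1\n",
              x$daily[["n2_fixation"]], x$fe_use_efficiency))
  w <- x$window
  if (w$width_h > 0) {
    cat(sprintf("  low-O2 window %.2f-%.2f h (%.2f h); %.1f%% of N2 fixation inside\n",
                w$start_h, w$end_h, w$width_h, 100 * w$nf_inside_fraction))
  } else {
    cat("  no low-O2 window detected\n")
  }
  cat(sprintf("  carbon-budget closure residual %.3g of gross fixation; %d clamp events\n",
              x$budget_closure, x$clamp_events))
  invisible(x)
}

#' @export
as.data.frame.diel_run <- function(x, ...) {
  data.frame(time_h = x$time / 3600, x$states, x$fluxes,
             check.names = TRUE)
}

#' Plot a diel run
#'
#' Four panels over the cycle: irradiance and intracellular vs ambient O2;
#' carbon fluxes (fixation, photorespiration, respiratory protection); N2
#' fixation and membrane permeability; Fe pools.
#'
#' @param x a `diel_run`.
#' @param ... ignored.
#' @export
plot.diel_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  th <- x$time / 3600
  graphics::plot(th, x$states[, "O2"], type = "l", xlab = "time (h)",
                 ylab = "O2 (mol m^-3)", main = "intracellular O2")
  graphics::abline(h = x$env$O2_ext, lty = 2)
  graphics::matplot(th, x$fluxes[, c("V_CF", "V_PR", "V_RP")], type = "l",
                    lty = 1, xlab = "time (h)",
                    ylab = "mol C (mol C)^-1 s^-1", main = "carbon fluxes")
  graphics::legend("topright", c("CF", "PR", "RP"), col = 1:3, lty = 1,
                   bty = "n", cex = 0.8)
  graphics::plot(th, x$fluxes[, "V_NF"], type = "l", xlab = "time (h)",
                 ylab = "mol N (mol C)^-1 s^-1", main = "N2 fixation")
  graphics::par(new = TRUE)
  graphics::plot(th, x$fluxes[, "eps"], type = "l", col = 4, axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = 4)
  graphics::matplot(th, x$states[, .fe_pools], type = "l", lty = 1,
                    xlab = "time (h)", ylab = "umol Fe (mol C)^-1",
                    main = "Fe pools")
  graphics::legend("topright", .fe_pools, col = seq_along(.fe_pools),
                   lty = 1, bty = "n", cex = 0.7)
  invisible(x)
}
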