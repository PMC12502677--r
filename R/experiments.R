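#' Scenario experiments
#'
#' Runs one of the model's standard experiments and returns a result table
#' (one row per scenario):
#'
#' * `"compare_permeability"`: both permeability modes at the focal
#'   dissolved-Fe levels; growth, daily N2 fixation, gross carbon fixation,
#'   the carbon-budget fractions (photorespiration, respiratory protection,
#'   ordinary respiration, biosynthesis), carbon use efficiency and Fe use
#'   efficiency.
#' * `"fe_gradient"`: both modes across `n_fe` log-spaced dissolved-Fe
#'   levels (default 10 levels, 20-1800 pM); the growth-promotion column is
#'   the percent gain of the dynamic over the fixed mode.
#' * `"o2_scan"`: both modes across external O2 concentrations.
#' * `"epsmax_scan"`: the dynamic mode across maximal relative
#'   diffusivities `eps_max`.
#' * `"pr_substitution"`: re-runs the dynamic mode while forcing the
#'   photorespiration trajectory recorded from the converged fixed mode,
#'   and reports the growth change. The forced trajectory is charged to
#'   the carbon and energy books while intracellular O2 keeps its native
#'   photorespiratory sink: the counterfactual isolates the
#'   photorespiration burden instead of crediting the forced flux as O2
#'   removal (which would conflate it with respiratory protection).
#'
#' @param name experiment name (see above).
#' @param params a [tricho_params()].
#' @param fe_levels dissolved-Fe levels (pM) for the focal comparisons.
#' @param n_fe number of gradient levels.
#' @param fe_range gradient range (pM).
#' @param o2_levels external O2 concentrations (mol m^-3) for `"o2_scan"`.
#' @param epsmax_levels `eps_max` values for `"epsmax_scan"`.
#' @param ... further arguments passed to [run_diel()] (e.g. `dt`,
#'   `conv_tol`, `max_cycles`).
#' @return A `data.frame`; for `"compare_permeability"` also of class
#'   `"permeability_comparison"`.
#' @export
run_experiment <- function(name = c("fe_gradient", "compare_permeability",
                                    "o2_scan", "epsmax_scan",
                                    "pr_substitution"),
                           params = tricho_params(),
                           fe_levels = c(40, 1250), n_fe = 10,
                           fe_range = c(20, 1800),
                           o2_levels = c(0.107, 0.16, 0.213, 0.32, 0.426),
                           epsmax_levels = c(1e-4, 1.5e-4, 2e-4, 4e-4,
                                             8e-4),
                           ...) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown experiment '", if (length(name)) name[[1]] else "",
         "'; options: fe_gradient, compare_permeability, o2_scan, ",
         "epsmax_scan, pr_substitution", call. = FALSE)
  })
  switch(name,
    compare_permeability = exp_compare(params, fe_levels, ...),
    fe_gradient = exp_fe_gradient(params, n_fe, fe_range, ...),
    o2_scan = exp_o2_scan(params, o2_levels, fe_levels[[1L]], ...),
    epsmax_scan = exp_epsmax(params, epsmax_levels, fe_levels[[1L]], ...),
    pr_substitution = exp_pr_subst(params, fe_levels, ...))
}

run_row <- function(run, extra = NULL) {
  b <- run$budget_fractions
  out <- data.frame(mode = run$mode, fe_diss = run$env$Fe_diss,
                   o2_ext = run$env$O2_ext,
                   growth = run$growth,
                   n2_fixation = run$daily[["n2_fixation"]],
                   gross_c_fixation = run$daily[["gross_carbon_fixation"]],
                   frac_photorespiration = b[["photorespiration"]],
                   frac_respiratory_protection =
                     b[["respiratory_protection"]],
                   frac_ordinary_respiration = b[["ordinary_respiration"]],
                   frac_biosynthesis = b[["biosynthesis"]],
                   carbon_use_efficiency = run$carbon_use_efficiency,
                   fe_use_efficiency = run$fe_use_efficiency,
                   window_width_h = run$window$width_h,
                   nf_inside_window = run$window$nf_inside_fraction,
                   converged = run$converged,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, as.data.frame(extra))
  out
}

exp_compare <- function(params, fe_levels, ...) {
  rows <- list()
  for (fe in fe_levels) {
    for (mode in c("fixed", "dynamic")) {
      run <- run_diel(tricho_env(Fe_diss = fe), mode = mode,
                      params = params, ...)
      rows[[length(rows) + 1L]] <- run_row(run)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("permeability_comparison", class(out))
  out
}

exp_fe_gradient <- function(params, n_fe, fe_range, ...) {
  fe_levels <- exp(seq(log(fe_range[[1L]]), log(fe_range[[2L]]),
                       length.out = n_fe))
  rows <- list()
  for (fe in fe_levels) {
    env <- tricho_env(Fe_diss = fe)
    r_fix <- run_diel(env, mode = "fixed", params = params, ...)
    r_dyn <- run_diel(env, mode = "dynamic", params = params, ...)
    promo <- 100 * (r_dyn$growth - r_fix$growth) / r_fix$growth
    rows[[length(rows) + 1L]] <- data.frame(
      fe_diss = fe, growth_fixed = r_fix$growth,
      growth_dynamic = r_dyn$growth, growth_promotion_pct = promo,
      n2_fix_fixed = r_fix$daily[["n2_fixation"]],
      n2_fix_dynamic = r_dyn$daily[["n2_fixation"]],
      converged = r_fix$converged && r_dyn$converged)
  }
  do.call(rbind, rows)
}

exp_o2_scan <- function(params, o2_levels, fe, ...) {
  rows <- list()
  for (o2 in o2_levels) {
    env <- tricho_env(Fe_diss = fe, O2_ext = o2)
    r_fix <- run_diel(env, mode = "fixed", params = params, ...)
    r_dyn <- run_diel(env, mode = "dynamic", params = params, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      o2_ext = o2, fe_diss = fe,
      growth_fixed = r_fix$growth, growth_dynamic = r_dyn$growth,
      growth_promotion_pct =
        100 * (r_dyn$growth - r_fix$growth) / r_fix$growth,
      pr_frac_fixed = r_fix$budget_fractions[["photorespiration"]],
      pr_frac_dynamic = r_dyn$budget_fractions[["photorespiration"]])
  }
  do.call(rbind, rows)
}

exp_epsmax <- function(params, epsmax_levels, fe, ...) {
  rows <- list()
  for (em in epsmax_levels) {
    p <- params
    p$eps_max <- em
    if (p$eps_fixed > em) p$eps_fixed <- em
    run <- run_diel(tricho_env(Fe_diss = fe), mode = "dynamic",
                    params = p, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      eps_max = em, fe_diss = fe, growth = run$growth,
      n2_fixation = run$daily[["n2_fixation"]],
      pr_frac = run$budget_fractions[["photorespiration"]])
  }
  do.call(rbind, rows)
}

exp_pr_subst <- function(params, fe_levels, ...) {
  rows <- list()
  for (fe in fe_levels) {
    env <- tricho_env(Fe_diss = fe)
    r_fix <- run_diel(env, mode = "fixed", params = params, ...)
    r_dyn <- run_diel(env, mode = "dynamic", params = params, ...)
    pr_fun <- stats::approxfun(r_fix$time, r_fix$pr_traj, rule = 2)
    r_sub <- run_diel(env, mode = "dynamic", params = params,
                      pr_force = pr_fun, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      fe_diss = fe,
      growth_dynamic = r_dyn$growth,
      growth_substituted = r_sub$growth,
      growth_fixed = r_fix$growth,
      growth_change_pct =
        100 * (r_sub$growth - r_dyn$growth) / r_dyn$growth)
  }
  do.call(rbind, rows)
}
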