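#' Default search box for the growth-maximization calibration
#'
#' Lower/upper bounds over `(v_RP_max, T_PS_max_BF, T_BF_max_PS,
#' T_NF_max_BF)`. The respiratory-protection bound is commensurate with the
#' largest O2 influx plus production that protection can usefully counter
#' at the default geometry; the translocation bounds span rates that can
#' turn the whole cellular Fe complement over within a fraction of the
#' photoperiod.
#'
#' @return A 2 x 4 numeric matrix with rows `lower` and `upper`.
#' @export
default_calibration_bounds <- function() {
  rbind(lower = c(v_RP_max = 1e-5, T_PS_max_BF = 1e-4,
                  T_BF_max_PS = 1e-4, T_NF_max_BF = 1e-4),
        upper = c(v_RP_max = 1.4e-3, T_PS_max_BF = 5e-2,
                  T_BF_max_PS = 5e-2, T_NF_max_BF = 5e-2))
}

#' Calibrate the four free rate parameters by growth maximization
#'
#' Fits the model's four free parameters — the maximal respiratory
#' protection rate and the maximal synthesis/decomposition rates of
#' photosystems and the maximal synthesis rate of nitrogenase — by
#' maximizing the converged daily growth rate (averaged over the supplied
#' dissolved-Fe levels) for one permeability mode. The optimizer is a
#' seeded multistart: `n_starts` Latin-hypercube points over the bounded
#' box, each polished by bounded Nelder-Mead (box-clamped with a quadratic
#' out-of-bounds penalty). The growth surface is evaluated through a full
#' diel spin-up, so the local polisher is derivative-free by design.
#'
#' @param mode `"dynamic"` or `"fixed"` membrane permeability.
#' @param params a [tricho_params()].
#' @param fe_levels dissolved-Fe levels (pM) whose mean converged growth is
#'   the objective.
#' @param bounds 2 x 4 matrix (`lower`/`upper` rows) over
#'   `(v_RP_max, T_PS_max_BF, T_BF_max_PS, T_NF_max_BF)`.
#' @param n_starts number of Latin-hypercube starts (>= 1).
#' @param seed integer seed; the whole calibration is reproducible given
#'   the seed.
#' @param start optional explicit starting vector (replaces the first
#'   hypercube start), e.g. a previous optimum.
#' @param control list passed to [stats::optim()] Nelder-Mead (notably
#'   `maxit`, `reltol`).
#' @param dt,conv_tol,max_cycles diel-run settings used for every objective
#'   evaluation (coarser than production settings by default: the optimum
#'   of a smooth growth surface moves little, and each evaluation is a full
#'   spin-up).
#' @return An object of class `tricho_calibration` with `par` (named
#'   optimum), `value` (achieved mean growth, d^-1), `trace` (per-start
#'   table), `bounds`, `seed`, `mode` and the evaluation settings. Methods:
#'   [coef()], `print`, `summary`, [predict()] (converged `diel_run` at the
#'   optimum), [simulate()] (synthetic observations from that run).
#' @export
calibrate_growth <- function(mode = c("dynamic", "fixed"),
                             params = tricho_params(),
                             fe_levels = c(40, 1250),
                             bounds = default_calibration_bounds(),
                             n_starts = 16, seed = 1L, start = NULL,
                             control = list(maxit = 60, reltol = 1e-4),
                             dt = 60, conv_tol = 1e-4, max_cycles = 30) {
  mode <- match.arg(mode)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (!is.matrix(bounds) || nrow(bounds) != 2 || ncol(bounds) != 4) {
    stop("bounds must be a 2 x 4 matrix (lower and upper rows)",
         call. = FALSE)
  }
  lb <- bounds[1L, ]; ub <- bounds[2L, ]
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(ub <= lb)) {
    stop("bounds must be finite with upper > lower", call. = FALSE)
  }
  pnames <- c("v_RP_max", "T_PS_max_BF", "T_BF_max_PS", "T_NF_max_BF")

  ## warm-start cache: each Fe level's spin-up starts from the previous
  ## evaluation's converged state (parameter moves are small within a
  ## Nelder-Mead polish, so the periodic state is nearby)
  warm <- vector("list", length(fe_levels))
  objective <- function(u) {
    ## unit-box parameterization with a quadratic penalty outside [0, 1]
    pen <- sum(pmax(0, u - 1)^2 + pmax(0, -u)^2)
    uc <- pmin(pmax(u, 0), 1)
    rates <- stats::setNames(lb + uc * (ub - lb), pnames)
    g <- vapply(seq_along(fe_levels), function(i) {
      env <- tricho_env(Fe_diss = fe_levels[[i]])
      init <- if (is.null(warm[[i]])) cell_state(O2 = env$O2_ext) else
        warm[[i]]
      run <- suppressWarnings(run_diel(
        env, mode = mode, params = params, rates = rates, dt = dt,
        conv_tol = conv_tol, max_cycles = max_cycles,
        init_state = init))
      warm[[i]] <<- run$final_state
      ## the quantity sought is the growth of the periodic attractor: a
      ## non-periodic evaluation is discounted by its residual cycle-to-
      ## cycle growth change
      run$growth -
        (if (is.finite(run$growth_delta)) run$growth_delta else 0)
    }, numeric(1))
    -(mean(g) - 10 * pen)
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, 4L)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  if (!is.null(start)) {
    start <- validate_calibrated(start)
    starts[1L, ] <- (start - lb) / (ub - lb)
  }

  trace <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                   control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      trace[[i]] <- data.frame(start = i, growth = NA_real_,
                               error = conditionMessage(fit))
      next
    }
    uc <- pmin(pmax(fit$par, 0), 1)
    rates <- stats::setNames(lb + uc * (ub - lb), pnames)
    trace[[i]] <- data.frame(start = i, growth = -fit$value,
                             error = NA_character_,
                             t(as.data.frame(rates)))
    if (is.null(best) || -fit$value > best$value) {
      best <- list(par = rates, value = -fit$value, start = i)
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("calibration failed: no start produced a finite growth rate; ",
         "per-start diagnostics:\n",
         paste(utils::capture.output(do.call(rbind, trace)),
               collapse = "\n"), call. = FALSE)
  }
  structure(list(par = best$par, value = best$value,
                 best_start = best$start,
                 trace = do.call(rbind, trace),
                 bounds = bounds, seed = seed, mode = mode,
                 fe_levels = fe_levels, params = params,
                 settings = list(dt = dt, conv_tol = conv_tol,
                                 max_cycles = max_cycles,
                                 n_starts = n_starts, control = control)),
            class = "tricho_calibration")
}

#' @export
coef.tricho_calibration <- function(object, ...) object$par

#' @export
print.tricho_calibration <- function(x, ...) {
  cat("<tricho_calibration> growth-maximized rate parameters (",
      x$mode, " permeability)\n", sep = "")
  cat(sprintf("  mean growth over Fe = {%s} pM: %.4f d^-1 (best of %d starts, seed %d)\n",
              paste(x$fe_levels, collapse = ", "), x$value,
              x$settings$n_starts, x$seed))
  print(signif(x$par, 6))
  invisible(x)
}

#' @export
summary.tricho_calibration <- function(object, ...) {
  print(object)
  ok <- !is.na(object$trace$growth)
  cat(sprintf("  starts: %d finished, %d failed; growth range %.4f-%.4f d^-1\n",
              sum(ok), sum(!ok),
              min(object$trace$growth[ok]), max(object$trace$growth[ok])))
  invisible(object)
}

#' Converged diel run at the calibrated optimum
#'
#' @param object a `tricho_calibration`.
#' @param fe_diss dissolved Fe (pM) of the prediction scenario (default:
#'   the first calibration level).
#' @param ... passed to [run_diel()]; defaults to the calibration's own
#'   evaluation settings.
#' @return A `diel_run`.
#' @export
predict.tricho_calibration <- function(object, fe_diss = NULL, ...) {
  fe <- if (is.null(fe_diss)) object$fe_levels[[1L]] else fe_diss
  args <- list(env = tricho_env(Fe_diss = fe), mode = object$mode,
               params = object$params, rates = object$par, ...)
  if (is.null(args$dt)) args$dt <- object$settings$dt
  if (is.null(args$conv_tol)) args$conv_tol <- object$settings$conv_tol
  if (is.null(args$max_cycles)) args$max_cycles <-
      object$settings$max_cycles
  do.call(run_diel, args)
}

#' Simulate synthetic observations from a calibration
#'
#' Draws `nsim` synthetic diel observation sets (photosystem Fe,
#' nitrogenase Fe, growth) from the converged run at the calibrated
#' optimum.
#'
#' @param object a `tricho_calibration`.
#' @param nsim number of observation sets.
#' @param seed integer seed.
#' @param noise_cv,n_times passed to [make_synthetic_observations()].
#' @param ... passed to [predict.tricho_calibration()].
#' @return A list of `diel_observations` (length `nsim`).
#' @export
simulate.tricho_calibration <- function(object, nsim = 1, seed = 1L,
                                        noise_cv = 0.1, n_times = 5, ...) {
  run <- predict(object, ...)
  lapply(seq_len(nsim), function(i) {
    make_synthetic_observations(run, noise_cv = noise_cv,
                                n_times = n_times,
                                seed = seed + i - 1L)
  })
}
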