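#' Reliability index
#'
#' Multiplicative model-skill metric: the exponential of the root-mean-square
#' log-ratio between observations and model,
#' `RI = exp( sqrt( (1/n) * sum( ln(obs_i / model_i)^2 ) ) )`.
#' `RI = 1` is perfect agreement; `RI = 2` means the model is off by a factor
#' of 2 on average (in the RMS sense). The metric is symmetric in its
#' arguments. `form = "literal"` omits the square root (the mean squared
#' log-ratio inside the exponential) for comparison; the RMS form is the
#' standard definition and the default.
#'
#' @param obs,model positive numeric vectors of equal length.
#' @param form `"rms"` (default) or `"literal"`.
#' @return The reliability index (dimensionless, >= 1 for `"rms"`).
#' @examples
#' reliability_index(c(1, 4), c(2, 2))  # exp(ln 2) = 2
#' @export
reliability_index <- function(obs, model, form = c("rms", "literal")) {
  form <- match.arg(form)
  if (length(obs) != length(model)) {
    stop("obs and model must have equal length", call. = FALSE)
  }
  if (length(obs) < 1) stop("need at least one observation", call. = FALSE)
  if (any(!is.finite(obs)) || any(!is.finite(model)) ||
      any(obs <= 0) || any(model <= 0)) {
    stop("reliability index requires strictly positive values",
         call. = FALSE)
  }
  msq <- mean(log(obs / model)^2)
  if (form == "rms") exp(sqrt(msq)) else exp(msq)
}

#' Coefficient of determination
#'
#' Standard R^2 of model values against observations,
#' `1 - SS_res / SS_tot`, with `SS_res = sum((obs - model)^2)` and
#' `SS_tot = sum((obs - mean(obs))^2)`. Can be negative when the model does
#' worse than the observation mean. Zero observation variance is flagged as
#' undefined (`NA` with a warning) rather than an error.
#'
#' @param obs,model numeric vectors of equal length, `n >= 2`.
#' @return R^2 (dimensionless, <= 1), or `NA` if the observations have zero
#'   variance.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(obs, model) {
  if (length(obs) != length(model)) {
    stop("obs and model must have equal length", call. = FALSE)
  }
  if (length(obs) < 2) stop("need at least two points", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("zero observation variance: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((obs - model)^2) / ss_tot
}

#' Generate synthetic diel observations
#'
#' Emulates a sparse laboratory sampling of a diel run: photosystem Fe,
#' nitrogenase Fe and the daily growth rate are subsampled at `n_times`
#' points of the light period and multiplicative lognormal noise with
#' coefficient of variation `noise_cv` is applied (mean-preserving:
#' `sdlog^2 = log(1 + cv^2)`, `meanlog = -sdlog^2/2`). The default
#' `n_times = 5` matches a typical culture-experiment sampling density.
#'
#' @param truth a `diel_run` (the generating model trajectory).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns exact subsamples).
#' @param n_times number of sampling times in the light period.
#' @param seed integer seed for reproducibility.
#' @return A list of class `diel_observations`: `time_h`, `fe_ps`, `fe_nf`
#'   (noisy series), `growth` (noisy scalar), the noise-free `truth_*`
#'   counterparts, and the generating settings.
#' @export
make_synthetic_observations <- function(truth, noise_cv = 0.1, n_times = 5,
                                        seed = 1L) {
  stopifnot(inherits(truth, "diel_run"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_times < 1) stop("n_times must be >= 1", call. = FALSE)
  P <- truth$env$photoperiod * 3600
  t_obs <- seq(P / (2 * n_times), P - P / (2 * n_times),
               length.out = n_times)
  idx <- vapply(t_obs, function(tt) which.min(abs(truth$time - tt)),
                integer(1))
  fe_ps <- truth$states[idx, "Fe_PS"]
  fe_nf <- truth$states[idx, "Fe_NF"]
  gr <- truth$growth
  sdlog <- sqrt(log(1 + noise_cv^2))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  set.seed(seed)
  noise <- function(n) {
    if (sdlog == 0) rep(1, n) else
      exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  out <- list(time_h = truth$time[idx] / 3600,
              fe_ps = fe_ps * noise(n_times),
              fe_nf = fe_nf * noise(n_times),
              growth = gr * noise(1),
              truth_fe_ps = fe_ps, truth_fe_nf = fe_nf, truth_growth = gr,
              noise_cv = noise_cv, n_times = n_times, seed = seed)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  class(out) <- "diel_observations"
  out
}

#' Skill of a diel run against observations
#'
#' Convenience wrapper computing R^2 and the reliability index of a run's
#' photosystem-Fe and nitrogenase-Fe trajectories against a
#' `diel_observations` object (matched at the observation times).
#'
#' @param run a `diel_run`.
#' @param obs a [make_synthetic_observations()] result.
#' @return A data.frame with one row per observed series.
#' @export
fit_metrics <- function(run, obs) {
  stopifnot(inherits(run, "diel_run"), inherits(obs, "diel_observations"))
  idx <- vapply(obs$time_h * 3600,
                function(tt) which.min(abs(run$time - tt)), integer(1))
  mod_ps <- run$states[idx, "Fe_PS"]
  mod_nf <- run$states[idx, "Fe_NF"]
  data.frame(
    series = c("fe_ps", "fe_nf"),
    n = obs$n_times,
    r_squared = c(r_squared(obs$fe_ps, mod_ps),
                  r_squared(obs$fe_nf, mod_nf)),
    reliability_index = c(reliability_index(obs$fe_ps, mod_ps),
                          reliability_index(obs$fe_nf, mod_nf)))
}
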