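## Shared coarse-resolution converged runs for the emergent-behavior and
## acceptance tests. Settings trade step-size precision for suite runtime;
## the step-halving test bounds the discretization error they carry.
.test_run_settings <- list(dt = 90, conv_tol = 2e-4, max_cycles = 35)

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(mode, fe, ...) {
  key <- paste(mode, fe, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressWarnings(run_diel(
      tricho_env(Fe_diss = fe), mode = mode,
      dt = .test_run_settings$dt, conv_tol = .test_run_settings$conv_tol,
      max_cycles = .test_run_settings$max_cycles, ...))
  }
  .run_cache[[key]]
}

cached_gradient <- function(n_fe = 10) {
  if (is.null(.run_cache[["gradient"]])) {
    .run_cache[["gradient"]] <- suppressWarnings(run_experiment(
      "fe_gradient", n_fe = n_fe,
      dt = .test_run_settings$dt, conv_tol = .test_run_settings$conv_tol,
      max_cycles = .test_run_settings$max_cycles))
  }
  .run_cache[["gradient"]]
}

## deterministic pseudo-random positive inputs for brute-force law checks
law_inputs <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    O2 = stats::runif(n, 0, 2),
    CH2O = stats::runif(n, 0, 3),
    Fe = stats::runif(n, 0, 500),
    V = stats::runif(n, 0, 1e-3)
  )
}
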