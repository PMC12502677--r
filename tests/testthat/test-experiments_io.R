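test_that("unknown experiment names produce a usage error listing options", {
  expect_error(run_experiment("not_an_experiment"), "fe_gradient")
})

test_that("experiment tables carry closed budgets and the expected columns", {
  ## reuse the cached focal runs through a tiny two-level comparison
  tab <- suppressWarnings(run_experiment(
    "compare_permeability", fe_levels = c(40),
    dt = .test_run_settings$dt, conv_tol = .test_run_settings$conv_tol,
    max_cycles = .test_run_settings$max_cycles))
  expect_s3_class(tab, "data.frame")
  expect_identical(nrow(tab), 2L)
  fr <- tab$frac_photorespiration + tab$frac_respiratory_protection +
    tab$frac_ordinary_respiration + tab$frac_biosynthesis
  expect_equal(fr, rep(1, nrow(tab)), tolerance = 0.005)
  expect_true(all(c("carbon_use_efficiency", "fe_use_efficiency",
                    "n2_fixation") %in% names(tab)))
})

test_that("written outputs round-trip and carry provenance", {
  run <- cached_run("dynamic", 40)
  out <- tempfile("outdir")
  files <- write_outputs(run, out, seed = 7)
  expect_true(all(file.exists(file.path(out, c("timeseries.csv",
                                               "daily.json")))))
  ts <- utils::read.csv(file.path(out, "timeseries.csv"))
  ## round-trip reproduces values to the 12-digit serialization precision
  orig <- as.data.frame(run)
  orig <- orig[seq(1, nrow(orig), by = 3), ]
  expect_equal(ts$O2, signif(orig$O2, 12), tolerance = 1e-11)
  daily <- jsonlite::read_json(file.path(out, "daily.json"))
  expect_identical(daily$provenance$seed, 7L)
  expect_equal(daily$growth_per_day, run$growth, tolerance = 1e-12)

  ## provenance hash changes iff the configuration changes
  run2 <- cached_run("fixed", 40)
  out2 <- tempfile("outdir")
  write_outputs(run2, out2)
  d1 <- jsonlite::read_json(file.path(out, "daily.json"))
  d2 <- jsonlite::read_json(file.path(out2, "daily.json"))
  expect_false(identical(d1$provenance$config_hash,
                         d2$provenance$config_hash))
  out3 <- tempfile("outdir")
  write_outputs(run, out3)
  d3 <- jsonlite::read_json(file.path(out3, "daily.json"))
  expect_identical(d1$provenance$config_hash, d3$provenance$config_hash)

  ## an empty experiment table yields a header-only CSV
  empty <- data.frame(fe_diss = numeric(0), growth = numeric(0))
  f <- write_outputs(empty, tempfile("outdir"), name = "empty")
  expect_identical(nrow(utils::read.csv(f)), 0L)
  expect_identical(names(utils::read.csv(f)), c("fe_diss", "growth"))
})

test_that("the command-line interface runs a scenario end to end", {
  cli <- system.file("cli", "trichodiel", package = "trichodiel")
  skip_if(cli == "", "CLI script not installed")
  out <- tempfile("cliout")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("environment:", "  fe_diss: 40",
               "scenarios:", "- name: smoke", "  mode: dynamic",
               "  fe_diss: 40"), cfg)
  res <- system2("Rscript",
                 c(cli, "simulate", "--config", cfg, "--outdir", out,
                   "--dt", "600", "--max-cycles", "2"),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(),
                                               collapse = .Platform$path.sep)))
  expect_identical(attr(res, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(out, "smoke", "daily.json")))
  ## unknown subcommand exits with the usage code
  res2 <- suppressWarnings(
    system2("Rscript", c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(),
                                          collapse = .Platform$path.sep))))
  expect_identical(attr(res2, "status"), 2L)
})

test_that("external-O2 and permeability-amplitude scans produce ordered tables", {
  o2 <- suppressWarnings(run_experiment(
    "o2_scan", o2_levels = c(0.107, 0.32), fe_levels = 40,
    dt = 600, conv_tol = 1e-2, max_cycles = 3))
  expect_identical(nrow(o2), 2L)
  expect_true(all(is.finite(o2$growth_dynamic)))
  em <- suppressWarnings(run_experiment(
    "epsmax_scan", epsmax_levels = c(1e-4, 4e-4), fe_levels = 40,
    dt = 600, conv_tol = 1e-2, max_cycles = 3))
  expect_identical(nrow(em), 2L)
  expect_identical(em$eps_max, c(1e-4, 4e-4))
  expect_true(all(is.finite(em$growth)))
})
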