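fluids <- reference_fluids()
geom <- reference_geometry()

test_that("cfl_model builds from parameters, planes, and profiles", {
  m <- cfl_model(fluids$blood_5pct, geom, a = 0.5, h_cfl_ss = 20)
  expect_s3_class(m, "cfl_model")
  co <- coef(m)
  expect_equal(unname(co[c("a", "x0", "h_cfl_ss")]), c(0.5, 1, 20))
  expect_equal(unname(co["mu_step_steady"]),
               oracle_step_core(150, 40, 1.45e-3, 1.38e-3))
  # from (x, H_CFL) calibration planes
  m2 <- cfl_model(fluids$blood_5pct, geom,
                  planes = rbind(c(401, 10), c(1601, 20)), h_cfl_ss = 20)
  expect_equal(coef(m2)[["a"]], 0.5, tolerance = 1e-12)
  # from measured profiles with station metadata
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  scen <- profile_scenario(0.05, n_bins = 300,
                           measurement_planes = c(401, 1601))
  planes <- generate_development_planes(scen, dev, geom)
  steady <- generate_profile(scen, geom, x_station = geom$L)
  m3 <- cfl_model(fluids$blood_5pct, geom, planes = planes,
                  steady_profile = steady)
  expect_equal(coef(m3)[["a"]], 0.5, tolerance = 0.05)
  expect_error(cfl_model(fluids$blood_5pct, geom), "provide one of")
})

test_that("model methods expose the fitted structure", {
  m <- cfl_model(fluids$blood_5pct, geom, a = 0.5, h_cfl_ss = 20)
  expect_output(print(m), "steady CFL = 20")
  expect_output(print(summary(m)), "consistency")
  # prediction matches the analytic sectioned model
  expect_equal(predict(m, x = 0.5, h = c(5, 75)),
               rep(fluids$blood_5pct$mu_rheo, 2))
  expect_equal(predict(m, x = 3e4, h = 5), fluids$blood_5pct$mu_carrier)
  expect_equal(predict(m, x = 3e4, h = 75),
               oracle_step_core(150, 40, 1.45e-3, 1.38e-3))
  # development section: step value at the local layer height
  x_dev <- 401  # H_CFL = 10 um
  expect_equal(predict(m, x = x_dev, h = 5),
               fluids$blood_5pct$mu_carrier)
  expect_equal(predict(m, x = x_dev, h = 75),
               oracle_step_core(150, 20, 1.45e-3, 1.38e-3))
  expect_error(predict(m, x = 10, h = 200), "h must lie")
  expect_error(residuals(m), "local_distribution")
  # simulate: reproducible profiles consistent with the model
  sims <- simulate(m, nsim = 2, seed = 42)
  expect_length(sims, 2)
  expect_identical(simulate(m, seed = 42)[[1]]$phi, sims[[1]]$phi)
  # detection threshold above the simulated noise floor
  expect_lt(abs(mean(detect_cfl_height(sims[[1]], epsilon = 0.02)) - 20),
            150 / 128 + 0.5)
})

test_that("local-distribution model carries fit residuals", {
  scen <- profile_scenario(0.05, n_bins = 300)
  steady <- generate_profile(scen, geom)
  m <- cfl_model(fluids$baf_5pct, geom, a = 0.5, h_cfl_ss = 20,
                 submodel = "local_distribution", steady_profile = steady)
  expect_lt(max(abs(residuals(m))), 1e-12)  # plateau input fits exactly
  expect_gt(coef(m)[["adjustment_factor"]], 1)  # BAF: law underpredicts
})

test_that("plot methods draw without error", {
  m <- cfl_model(fluids$blood_5pct, geom, a = 0.5, h_cfl_ss = 20,
                 n_h = 64, n_x_dev = 8, n_x_steady = 4)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error({
    plot(m, type = "profile")
    plot(m, type = "development")
    plot(m, type = "field")
    plot(solve_flow(m, reynolds = 100))
  })
  grDevices::dev.off()
  expect_true(file.exists(path))
})

make_config <- function(dir, seed = 1L) {
  cfg <- list(
    schema = "cflvisc-run/1", seed = seed,
    fluid = list(preset = "blood_5pct"),
    geometry = list(H_um = 150, W_um = 1200, L_um = 30000),
    development = list(a = 0.5, x0_um = 1, h_cfl_ss_um = 20),
    submodel = "step",
    conditions = list(reynolds = c(100, 125)),
    grid = list(n_h = 64, n_x_dev = 8, n_x_steady = 4),
    scenario = list(phi_bulk = 0.03, h_cfl_um = c(20, 20),
                    core_shape = "plateau", noise_sd = 0.002, n_bins = 64,
                    planes_um = c(2000, 8000)))
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("configs are validated and runs are reproducible end to end", {
  dir <- withr::local_tempdir()
  cfg_path <- make_config(dir)
  cfg <- read_run_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  bad <- yaml::read_yaml(cfg_path)
  bad$schema <- "other/9"
  expect_error(read_run_config(bad), "schema")
  bad2 <- yaml::read_yaml(cfg_path)
  bad2$geometry$H_um <- NULL
  expect_error(read_run_config(bad2), "H_um")
  bad3 <- yaml::read_yaml(cfg_path)
  bad3$fluid <- list(preset = "nope")
  expect_error(run_build_field(bad3, file.path(dir, "x")), "unknown fluid")

  out1 <- file.path(dir, "out1")
  out2 <- file.path(dir, "out2")
  run_build_field(cfg_path, out1)
  run_build_field(cfg_path, out2)
  expect_true(file.exists(file.path(out1, "field.csv")))
  summary_txt <- readLines(file.path(out1, "field_summary.txt"))
  expect_true(any(grepl("steady mu_STEP: 1.47545", summary_txt)))
  # byte-identical reruns
  expect_identical(tools::md5sum(file.path(out1, "field.csv"))[[1]],
                   tools::md5sum(file.path(out2, "field.csv"))[[1]])
  # exported field re-imports losslessly
  back <- read_field(file.path(out1, "field.csv"))
  expect_equal(field_height_average(back),
               rep(1.45e-3, length(back$x_grid)), tolerance = 1e-12)
  # manifest checksums describe the emitted files
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 1L)
  md5s <- vapply(man$files, function(f) f$md5, character(1))
  names(md5s) <- vapply(man$files, function(f) f$name, character(1))
  expect_identical(unname(md5s["field.csv"]),
                   tools::md5sum(file.path(out1, "field.csv"))[[1]])
})

test_that("solve and synth commands emit the documented tables", {
  dir <- withr::local_tempdir()
  cfg_path <- make_config(dir)
  out <- file.path(dir, "solve")
  run_solve(cfg_path, out)
  runs <- utils::read.csv(file.path(out, "runs.csv"))
  expect_equal(runs$reynolds, c(100, 125))
  expect_true(all(runs$cp_ratio > 0.9517 & runs$cp_ratio < 1))
  expect_true(all(abs(runs$cp_ratio_single - 1) < 1e-10))
  st <- utils::read.csv(file.path(out, "stations_Re100.csv"))
  expect_named(st, c("x_um", "G_Pa_m", "tau_w_bottom_Pa", "tau_w_top_Pa"))
  expect_true(all(diff(st$G_Pa_m[-1]) <= 1e-9))  # loss falls as CFL grows

  outs <- file.path(dir, "synth")
  run_synth(cfg_path, outs)
  expect_true(file.exists(file.path(outs, "profile_steady.csv")))
  expect_true(file.exists(file.path(outs, "profile_M1.csv")))
  man <- jsonlite::read_json(file.path(outs, "manifest.json"))
  expect_equal(man$seed_used, man$config$seed)
  prof <- read_profile(file.path(outs, "profile_M2.csv"))
  expect_equal(attr(prof, "x_station"), 8000)
})

test_that("the command-line entry point runs a synth verb", {
  cli <- system.file("cli", "cflvisc.R", package = "cflvisc")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  cfg_path <- make_config(dir)
  out <- file.path(dir, "cli_out")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "synth", "--config", cfg_path, "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(),
                                               collapse = .Platform$path.sep)))
  expect_equal(attr(res, "status"), NULL)  # exit code 0
  expect_true(file.exists(file.path(out, "manifest.json")))
})
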