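fluids <- reference_fluids()
geom <- reference_geometry()

test_that("step core viscosity follows the conservative mixing rule", {
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  # frozen hand arithmetic: (150*5.95 - 40*2.85)/110 and (150*1.45 - 40*1.38)/110
  expect_equal(step_viscosity_at(3e4, fluids$baf_5pct, geom, dev),
               7.0773e-3, tolerance = 1e-4)
  expect_equal(step_viscosity_at(3e4, fluids$blood_5pct, geom, dev),
               1.47545e-3, tolerance = 1e-5)
  # no CFL yet: bulk viscosity
  expect_equal(step_viscosity_at(0.5, fluids$baf_5pct, geom, dev),
               fluids$baf_5pct$mu_rheo)
  # per-wall sensitivity reading uses half the thickness
  expect_equal(step_viscosity_at(3e4, fluids$baf_5pct, geom, dev,
                                 cfl_interpretation = "per_wall"),
               oracle_step_core(150, 20, 5.95e-3, 2.85e-3))
  # layer swallowing the channel
  wide <- cfl_development(a = 5, h_cfl_ss = 74.9, H = 150)
  expect_error(step_viscosity_at(3e4, fluids$baf_5pct,
                                 channel_geometry(H = 149.0, W = 1200),
                                 wide),
               "exceeds channel")
})

test_that("assembled field honours the three sections", {
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  fld <- assemble_field(fluids$blood_5pct, geom, dev, n_h = 150)
  # inlet column is uniformly at the bulk viscosity
  expect_true(all(fld$mu[, fld$x_grid <= 1] == fluids$blood_5pct$mu_rheo))
  # steady column: carrier fluid strictly inside the CFL band
  j <- length(fld$x_grid)
  inside <- fld$h_grid < 19.5 | fld$h_grid > 150 - 19.5
  expect_true(all(fld$mu[inside, j] == fluids$blood_5pct$mu_carrier))
  # core value equals the mixing rule
  expect_equal(fld$mu[75, j], oracle_step_core(150, 40, 1.45e-3, 1.38e-3))
  # field never drops below the carrier viscosity
  expect_true(all(fld$mu >= fluids$blood_5pct$mu_carrier - 1e-15))
  # development and steady sections coincide at the completion station:
  # the growth law lands exactly on the steady height there, so the first
  # steady column (at x_star) equals every later steady column
  js <- min(which(fld$section == "steady"))
  expect_equal(fld$x_grid[js], dev$x_star)
  expect_equal(fld$mu[, js], fld$mu[, length(fld$x_grid)])
  expect_equal(dev$a * sqrt(dev$x_star - dev$x0), dev$h_cfl_ss,
               tolerance = 1e-12)
})

test_that("degenerate inputs collapse to a single-phase field", {
  fld <- assemble_field(fluids$baf_5pct, geom, cfl_development(a = 0))
  expect_true(all(fld$mu == fluids$baf_5pct$mu_rheo))
  # mu_carrier == mu_rheo: CFL present but dynamically invisible
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  fld2 <- assemble_field(fluids$plasma, geom, dev)
  expect_true(all(abs(fld2$mu - fluids$plasma$mu_rheo) < 1e-18))
})

test_that("assembly guards its preconditions", {
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  expect_error(assemble_field(fluids$baf_5pct, geom, dev, n_h = 16),
               "grid too coarse")
  expect_error(assemble_field(fluids$baf_5pct, geom, dev,
                              submodel = "local_distribution"),
               "steady_profile")
  short <- channel_geometry(H = 150, W = 1200, L = 800)
  expect_warning(assemble_field(fluids$baf_5pct, short, dev),
                 "ends inside development")
})

test_that("height-average consistency holds exactly at every station", {
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  for (fl in list(fluids$blood_5pct, fluids$baf_5pct)) {
    fld <- assemble_field(fl, geom, dev, n_h = 97)  # deliberately unaligned
    avg <- field_height_average(fld)
    expect_lt(max(abs(avg - fl$mu_rheo)) / fl$mu_rheo, 1e-12)
  }
  # per-wall sensitivity reading deliberately breaks the constraint
  fld_pw <- assemble_field(fluids$baf_5pct, geom, dev,
                           cfl_interpretation = "per_wall")
  avg_pw <- field_height_average(fld_pw)
  expect_gt(max(abs(avg_pw - fluids$baf_5pct$mu_rheo)) /
              fluids$baf_5pct$mu_rheo, 1e-3)
})

test_that("adjustment factor rescales the core onto the bulk constraint", {
  h <- seq(0, 150, length.out = 301)
  # raw profile that already satisfies the constraint: beta = 1, untouched
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  core <- oracle_step_core(150, 40, 1.45e-3, 1.38e-3)
  # cell-averaged conservative column from the field builder
  fld <- assemble_field(fluids$blood_5pct, geom, dev, n_h = 300)
  mu_raw <- fld$mu[, length(fld$x_grid)]
  adj <- apply_adjustment(h, mu_raw, fluids$blood_5pct)
  expect_equal(adj$adjustment_factor, 1, tolerance = 1e-12)
  expect_equal(adj$mu, mu_raw)

  # Einstein-Roscoe on a conserving plateau: blood overpredicts (beta < 1),
  # BAF underpredicts (beta > 1); both land on mu_rheo exactly
  plateau <- 0.05 * 150 / 110
  for (fl in list(fluids$blood_5pct, fluids$baf_5pct)) {
    mu_er <- ifelse(h <= 20 | h >= 130, fl$mu_carrier,
                    einstein_roscoe(plateau, fl$mu_carrier))
    a2 <- apply_adjustment(h, mu_er, fl)
    expect_equal(pracma::trapz(h, a2$mu) / 150, fl$mu_rheo,
                 tolerance = 1e-12)
    if (fl$label == "porcine blood 5%") expect_lt(a2$adjustment_factor, 1)
    else expect_gt(a2$adjustment_factor, 1)
    # linearity: doubling the core excess halves beta
    mu2 <- fl$mu_carrier + 2 * (mu_er - fl$mu_carrier)
    a3 <- apply_adjustment(h, mu2, fl)
    expect_equal(a3$adjustment_factor, a2$adjustment_factor / 2,
                 tolerance = 1e-12)
  }
  expect_error(apply_adjustment(h, rep(1e-3, length(h)),
                                fluids$blood_5pct),
               "below mu_carrier")
})

test_that("quartic core fits are recovered exactly and floored when needed", {
  fl <- fluids$baf_5pct
  H <- 150
  h <- seq(0, H, length.out = 151)
  # an exactly quartic core profile (coefficients in h)
  true_h <- c(3.0e-3, 2e-8, 3e-10, -1e-12, -2e-15)
  poly_h <- function(hh) drop(outer(hh, 0:4, `^`) %*% true_h)
  fit <- fit_local_distribution(h, poly_h(h), fl, geom, c(20, 20))
  expect_equal(unname(fit$coef_h), true_h, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-15)
  # symmetric input: odd coefficients vanish in the centred basis
  sym <- 3e-3 + 1e-3 * (1 - ((h - 75) / 75)^2)^2
  fit_s <- fit_local_distribution(h, sym, fl, geom, c(20, 20))
  expect_lt(max(abs(fit_s$coef_scaled[c(2, 4)])), 1e-10)
  expect_error(fit_local_distribution(h[c(1, 70, 80, 151)],
                                      rep(3e-3, 4), fl, geom, c(20, 20)),
               ">= 5")
})

test_that("step and local-distribution submodels agree on a step input", {
  fl <- fluids$baf_5pct
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  scen <- profile_scenario(0.05, h_cfl = c(20, 20), n_bins = 300)
  prof <- generate_profile(scen, geom)
  fld_ld <- assemble_field(fl, geom, dev, submodel = "local_distribution",
                           steady_profile = prof, n_h = 300)
  fld_st <- assemble_field(fl, geom, dev, submodel = "step", n_h = 300)
  j <- length(fld_ld$x_grid)
  core <- fld_ld$h_grid > 25 & fld_ld$h_grid < 125
  # same core level up to the one-bin ambiguity of edge detection
  expect_equal(fld_ld$mu[core, j], fld_st$mu[core, j], tolerance = 2e-2)
  # and both conserve the bulk viscosity exactly
  expect_lt(abs(mean(field_height_average(fld_ld)[j]) - fl$mu_rheo) /
              fl$mu_rheo, 1e-12)
})

test_that("viscosity fields round-trip through the text export", {
  dev <- cfl_development(a = 0.5, h_cfl_ss = 20, H = 150)
  fld <- assemble_field(fluids$blood_5pct, geom, dev, n_h = 64,
                        n_x_dev = 8, n_x_steady = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, path)
  back <- read_field(path)
  expect_equal(back$mu, fld$mu)
  expect_equal(back$x_grid, fld$x_grid)
  expect_equal(back$section, fld$section)
  expect_equal(back$fluid$mu_rheo, fld$fluid$mu_rheo)
  expect_equal(back$dev$h_cfl_ss, fld$dev$h_cfl_ss)
})
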