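# Synthetic APTV-style particle-distribution profiles: seeded, conservative
# fixtures standing in for optical measurements, plus the Student-t
# measurement-uncertainty formula used for pressure-loss experiments and a
# catalog of the reference fluids.

#' Scenario for synthetic particle-distribution profiles
#'
#' Describes the wall-normal concentration profile an APTV measurement would
#' deliver: zero concentration in near-wall cell-free bands of prescribed
#' thickness, a particle-laden core (flat plateau or mid-plane-clustered
#' quartic bump), per-bin sampling noise, and the streamwise stations of the
#' two development-calibration measurement planes.
#'
#' @param phi_bulk Bulk volume fraction.
#' @param h_cfl Per-wall steady CFL heights `c(bottom, top)` in um.
#' @param core_shape `"plateau"` (uniform laden core) or `"quartic_bump"`
#'   (symmetric fourth-degree polynomial peaking at mid-gap, emulating
#'   mid-plane clustering).
#' @param noise_sd Absolute volume-fraction noise per bin (Gaussian,
#'   truncated at zero).
#' @param noise_model `"gaussian"` (default) or `"binomial"` (count-based:
#'   per-bin counts drawn from a binomial with `count_scale` trials).
#' @param n_bins Number of wall-normal bins (>= 16).
#' @param seed Integer seed; identical seed and scenario give bit-identical
#'   profiles.
#' @param measurement_planes Streamwise stations (um) of the development
#'   measurement planes.
#' @param count_scale Trials per bin for the binomial noise model.
#' @return An object of class `profile_scenario`.
#' @export
profile_scenario <- function(phi_bulk, h_cfl = c(20, 20),
                             core_shape = c("plateau", "quartic_bump"),
                             noise_sd = 0, noise_model = c("gaussian",
                                                           "binomial"),
                             n_bins = 128, seed = 1L,
                             measurement_planes = c(2000, 8000),
                             count_scale = 2000L) {
  core_shape <- match.arg(core_shape)
  noise_model <- match.arg(noise_model)
  stopifnot(.is_number(phi_bulk), phi_bulk > 0, phi_bulk < PHI_SINGULARITY,
            length(h_cfl) == 2, all(h_cfl >= 0), .is_number(noise_sd),
            noise_sd >= 0, .is_number(n_bins))
  if (n_bins < 16) .stopf("n_bins must be >= 16")
  structure(
    list(phi_bulk = phi_bulk, h_cfl = h_cfl, core_shape = core_shape,
         noise_sd = noise_sd, noise_model = noise_model,
         n_bins = as.integer(n_bins), seed = as.integer(seed),
         measurement_planes = measurement_planes,
         count_scale = as.integer(count_scale)),
    class = "profile_scenario")
}

# Cumulative integral from the bottom wall of the ideal (noiseless) profile.
# Closed forms keep the cell-averaged discretisation exactly conservative.
.ideal_profile_cdf <- function(hq, H, h_cfl, phi_bulk, core_shape) {
  lo <- h_cfl[1]
  hi <- H - h_cfl[2]
  wc <- hi - lo
  if (core_shape == "plateau") {
    A <- phi_bulk * H / wc
    A * pmax(0, pmin(hq, hi) - lo)
  } else {
    # phi = A (1 - xi^2)^2 on the core, xi in [-1, 1]; integral matches
    # phi_bulk * H when A = 15 phi_bulk H / (8 wc)
    A <- 15 * phi_bulk * H / (8 * wc)
    xi <- pmin(1, pmax(-1, (hq - (lo + hi) / 2) / (wc / 2)))
    g <- function(z) z - 2 * z^3 / 3 + z^5 / 5
    A * (wc / 2) * (g(xi) - g(-1))
  }
}

#' Generate a synthetic particle-distribution profile
#'
#' Builds the noiseless skeleton so that mass is bookkept exactly: the
#' concentration is zero inside the cell-free bands and the core amplitude is
#' set by conservation (`phi_bulk * H / (H - h_cfl_bottom - h_cfl_top)` for
#' the plateau shape), so the height average of the skeleton equals
#' `phi_bulk` exactly. Nodal values are control-cell averages of the ideal
#' profile, making that conservation statement hold under the trapezoid rule
#' on the emitted grid, not just in the continuum. Noise (if any) is added
#' per bin afterwards and truncated at zero.
#'
#' @param scenario A [profile_scenario].
#' @param geom A [channel_geometry].
#' @param x_station Station recorded in the profile metadata (um).
#' @param h_cfl Optional per-wall CFL override in um (used by the
#'   development-plane generator).
#' @param seed Optional seed override.
#' @return A [particle_profile].
#' @export
generate_profile <- function(scenario, geom, x_station = NA_real_,
                             h_cfl = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "profile_scenario"),
            inherits(geom, "channel_geometry"))
  H <- geom$H
  if (is.null(h_cfl)) h_cfl <- scenario$h_cfl
  if (is.null(seed)) seed <- scenario$seed
  if (sum(h_cfl) >= H)
    .stopf("cell-free layers (%g + %g um) exceed the gap height %g um",
           h_cfl[1], h_cfl[2], H)
  h <- seq(0, H, length.out = scenario$n_bins + 1)
  ce <- .cell_edges(h)
  cdf <- function(q) .ideal_profile_cdf(q, H, h_cfl, scenario$phi_bulk,
                                        scenario$core_shape)
  phi <- (cdf(ce$hi) - cdf(ce$lo)) / (ce$hi - ce$lo)
  counts <- NULL
  if (scenario$noise_model == "binomial") {
    counts <- .with_seed(seed, stats::rbinom(length(phi),
                                             scenario$count_scale,
                                             pmin(phi, 1)))
    phi <- counts / scenario$count_scale
  } else if (scenario$noise_sd > 0) {
    phi <- .with_seed(seed, pmax(0, phi + stats::rnorm(length(phi), 0,
                                                       scenario$noise_sd)))
  }
  particle_profile(h, phi, x_station = x_station, n_samples = counts)
}

#' Generate development-section measurement planes
#'
#' Emits one synthetic profile per measurement plane, each with the per-wall
#' CFL thickness dictated by the development law at that station (a uniform,
#' CFL-free profile for stations before the migration onset). Feeding the
#' plane heights back through [calibrate_parabola()] recovers the configured
#' widening coefficient, which is the closure test used throughout the test
#' suite.
#'
#' @param scenario A [profile_scenario]; core amplitudes are re-balanced per
#'   plane so each plane conserves `phi_bulk`.
#' @param dev A [cfl_development].
#' @param geom A [channel_geometry].
#' @param stations Streamwise stations in um (default the scenario's
#'   measurement planes).
#' @return A named list of [particle_profile]s ("M1", "M2", ...). Per-plane
#'   seeds are `seed + plane index`, keeping planes independent but
#'   reproducible.
#' @export
generate_development_planes <- function(scenario, dev, geom,
                                        stations =
                                          scenario$measurement_planes) {
  stopifnot(inherits(dev, "cfl_development"))
  if (any(stations < 0 | stations > geom$L))
    .stopf("stations must lie inside the channel [0, %g um]", geom$L)
  out <- lapply(seq_along(stations), function(i) {
    hw <- hcfl_profile(stations[i], dev)
    generate_profile(scenario, geom, x_station = stations[i],
                     h_cfl = c(hw, hw), seed = scenario$seed + i)
  })
  names(out) <- paste0("M", seq_along(stations))
  out
}

#' Measurement uncertainty of repeated pressure readings
#'
#' Total uncertainty `u_x = x_s + t * s_x`, combining an estimated maximum
#' systematic error `x_s` (default 2000 Pa, the value used for the channel
#' pressure sensors) with the Student-t confidence limit on the mean of the
#' repeats: `s_x` is the standard deviation of the mean and `t` the
#' two-sided Student coverage factor at the given confidence level (default
#' 95%) with `n - 1` degrees of freedom.
#'
#' @param measurements Numeric vector of repeated measurements in Pa
#'   (`n >= 2`).
#' @param x_s Systematic error bound in Pa (default 2000).
#' @param confidence Two-sided confidence level (default 0.95).
#' @return An object of class `uncertainty_result`: `mean`, `s_mean`,
#'   `t_factor`, `x_s`, `u_x`, `n`, `confidence`.
#' @examples
#' measurement_uncertainty(c(100000, 102000, 98000, 101000, 99000))
#' @export
measurement_uncertainty <- function(measurements, x_s = 2000,
                                    confidence = 0.95) {
  stopifnot(is.numeric(measurements), .is_number(x_s), x_s >= 0,
            .is_number(confidence), confidence > 0, confidence < 1)
  n <- length(measurements)
  if (n < 2) .stopf("cannot estimate dispersion from %d measurement(s)", n)
  s_mean <- stats::sd(measurements) / sqrt(n)
  t_factor <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  structure(
    list(mean = mean(measurements), s_mean = s_mean, t_factor = t_factor,
         x_s = x_s, u_x = x_s + t_factor * s_mean, n = n,
         confidence = confidence),
    class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("Measurement uncertainty (n = %d, %.0f%% confidence)\n",
              x$n, 100 * x$confidence))
  cat(sprintf("  mean = %.6g Pa, s_mean = %.6g Pa, t = %.4g\n",
              x$mean, x$s_mean, x$t_factor))
  cat(sprintf("  u_x = x_s + t * s_mean = %.6g + %.6g = %.6g Pa\n",
              x$x_s, x$t_factor * x$s_mean, x$u_x))
  invisible(x)
}

#' Catalog of reference fluids and scenarios
#'
#' The published fluid sets the model was developed and validated on: a
#' PEG-water blood analog fluid (BAF) with polystyrene/PMMA particles
#' (carrier 2.85 mPa s, suspension 5.95 mPa s at 5%), porcine blood (plasma
#' 1.38 mPa s, whole blood 1.45 mPa s at 5% hematocrit, plus the
#' hypothetical 45% scenario at 3.63 mPa s), together with the reference
#' channel (H = 150 um) and profile scenarios at bulk fractions of 1%, 3%
#' and 5% with 20 um per-wall steady cell-free layers.
#'
#' The measurement-plane stations (2000 and 8000 um) are package choices:
#' the source experiments show the planes only graphically. Densities
#' default to 1050 kg/m^3; no dimensionless output depends on them.
#'
#' @return A list with elements `fluids` (named [fluid_spec]s:
#'   `baf_carrier`, `baf_5pct`, `plasma`, `blood_5pct`, `blood_45pct`),
#'   `geometry` (a [channel_geometry]), and `scenarios` (named
#'   [profile_scenario]s: `phi_1pct`, `phi_3pct`, `phi_5pct`).
#' @export
fluid_presets <- function() {
  fluids <- list(
    baf_carrier = fluid_spec(2.85, 2.85, 0, label = "BAF carrier",
                             units = "mPa.s"),
    baf_5pct = fluid_spec(2.85, 5.95, 0.05, label = "BAF 5%",
                          units = "mPa.s"),
    plasma = fluid_spec(1.38, 1.38, 0, label = "porcine plasma",
                        units = "mPa.s"),
    blood_5pct = fluid_spec(1.38, 1.45, 0.05, label = "porcine blood 5%",
                            units = "mPa.s"),
    # hypothetical high-hematocrit scenario; the >5% warning is by design
    blood_45pct = suppressWarnings(
      fluid_spec(1.38, 3.63, 0.45, label = "porcine blood 45% (hypothetical)",
                 units = "mPa.s")))
  scenarios <- list(
    phi_1pct = profile_scenario(0.01, noise_sd = 0.001),
    phi_3pct = profile_scenario(0.03, noise_sd = 0.003),
    phi_5pct = profile_scenario(0.05, noise_sd = 0.005))
  list(fluids = fluids,
       geometry = channel_geometry(H = 150, W = 1200, L = 30000),
       scenarios = scenarios)
}
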