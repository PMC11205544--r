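# Reduced-order laminar solver for plane-channel flow with wall-normal (and
# slowly varying streamwise) viscosity. The fully developed problem
# d/dh (mu du/dh) = -G, u(0) = u(H) = 0 is solved exactly by quadrature:
# shear stress is linear in h, tau(h) = G (h0 - h), with the zero-stress
# height h0 fixed by the no-slip conditions, and G scaled to match the bulk
# velocity. All reciprocal-viscosity integrals are evaluated in closed form
# for piecewise-linear mu(h), so grids with repeated nodes represent
# viscosity jumps exactly.

#' Flow conditions for a channel run
#'
#' Exactly one of the Reynolds number or the bulk velocity is prescribed; the
#' other is derived through `Re = rho * c * L_c / mu_rheo`, the convention in
#' which the suspension's own rheometer viscosity defines the Reynolds number
#' of a particle-laden run. The characteristic length defaults to the gap
#' height; the hydraulic diameter `2HW/(H+W)` is available as an alternative
#' convention. A warning flags Reynolds numbers outside `[1, 500]` (the model
#' is built for 50-150).
#'
#' @param fluid A [fluid_spec].
#' @param geom A [channel_geometry].
#' @param reynolds Reynolds number (or `NULL`).
#' @param bulk_velocity Bulk velocity in m/s (or `NULL`).
#' @param char_convention `"H"` (default) or `"hydraulic"`.
#' @param char_length Optional explicit characteristic length in m,
#'   overriding the convention.
#' @return An object of class `flow_conditions` with both `reynolds` and
#'   `bulk_velocity` filled in.
#' @export
flow_conditions <- function(fluid, geom, reynolds = NULL,
                            bulk_velocity = NULL,
                            char_convention = c("H", "hydraulic"),
                            char_length = NULL) {
  char_convention <- match.arg(char_convention)
  stopifnot(inherits(fluid, "fluid_spec"), inherits(geom, "channel_geometry"))
  if (is.null(char_length)) {
    char_length <- if (char_convention == "H") geom$H * 1e-6
                   else 2 * geom$H * geom$W / (geom$H + geom$W) * 1e-6
  }
  if (is.null(reynolds) == is.null(bulk_velocity))
    .stopf("prescribe exactly one of reynolds and bulk_velocity")
  if (is.null(bulk_velocity)) {
    stopifnot(.is_number(reynolds), reynolds >= 0)
    bulk_velocity <- bulk_velocity_from_re(reynolds, fluid, char_length)
  } else {
    stopifnot(.is_number(bulk_velocity), bulk_velocity >= 0)
    reynolds <- fluid$density * bulk_velocity * char_length / fluid$mu_rheo
  }
  if (reynolds > 0 && (reynolds < 1 || reynolds > 500))
    .warnf("Re = %.3g outside the [1, 500] band; model validity is Re 50-150",
           reynolds)
  structure(
    list(reynolds = reynolds, bulk_velocity = bulk_velocity,
         char_length = char_length, char_convention = char_convention,
         density = fluid$density, mu_rheo = fluid$mu_rheo),
    class = "flow_conditions")
}

#' Bulk velocity from a Reynolds number
#'
#' `c = Re * mu_rheo / (rho * L_c)` with the suspension viscosity in the
#' Reynolds definition.
#'
#' @param re Reynolds number (>= 0).
#' @param fluid A [fluid_spec].
#' @param char_length Characteristic length in m.
#' @return Bulk velocity in m/s.
#' @examples
#' blood <- fluid_spec(1.38, 1.45, 0.05, units = "mPa.s")
#' bulk_velocity_from_re(100, blood, 150e-6)  # 0.92063 m/s
#' @export
bulk_velocity_from_re <- function(re, fluid, char_length) {
  stopifnot(inherits(fluid, "fluid_spec"), .is_number(re), re >= 0,
            .is_number(char_length), char_length > 0)
  re * fluid$mu_rheo / (fluid$density * char_length)
}

#' Fully developed velocity profile for a variable-viscosity channel
#'
#' Exact quadrature solution of plane-Poiseuille flow with wall-normal
#' viscosity `mu(h)`: the pressure gradient `G = -dp/dx` is chosen so the
#' bulk (height-averaged) velocity matches the prescription, the zero-shear
#' height is `h0 = int(s/mu) / int(1/mu)`, and the wall shear stresses are
#' `G*h0` (bottom) and `G*(H - h0)` (top). For constant viscosity this
#' reduces to the closed forms `tau_w = 6 mu c / H`, `G = 12 mu c / H^2`.
#'
#' The profile is interpreted as piecewise linear between nodes; repeated
#' `h` values encode discontinuities (e.g. the two-layer step profile) and
#' are integrated exactly.
#'
#' @param h Ascending wall-normal coordinates in um spanning `[0, H]`
#'   (repeats allowed at jumps).
#' @param mu Viscosity at the nodes in Pa s, all > 0.
#' @param bulk_velocity Bulk velocity in m/s (>= 0).
#' @return A list: `G` (Pa/m), `u` (m/s at the nodes), `tau_w_bottom`,
#'   `tau_w_top` (Pa), `h0` (um), `mu_eff` (Pa s, the constant viscosity
#'   yielding the same `G` at the same bulk velocity).
#' @export
solve_developed_profile <- function(h, mu, bulk_velocity) {
  stopifnot(is.numeric(h), is.numeric(mu), length(h) == length(mu),
            length(h) >= 2, .is_number(bulk_velocity), bulk_velocity >= 0)
  if (any(mu <= 0)) .stopf("viscosity must be positive everywhere")
  if (any(diff(h) < 0)) .stopf("h must be non-decreasing")
  hm <- h * 1e-6
  n <- length(hm)
  d <- diff(hm)
  mom <- .recip_moments(mu[-n], mu[-1], d)
  a0 <- hm[-n]
  dA <- mom$I0
  dB <- a0 * mom$I0 + mom$I1
  dC <- a0^2 * mom$I0 + 2 * a0 * mom$I1 + mom$I2
  A <- c(0, cumsum(dA))
  B <- c(0, cumsum(dB))
  C <- c(0, cumsum(dC))
  H <- hm[n] - hm[1]
  AH <- A[n]
  BH <- B[n]
  CH <- C[n]
  h0 <- BH / AH
  # int_0^H u dh for G = 1, via integration by parts
  q_unit <- h0 * (H * AH - BH) - (H * BH - CH)
  c_unit <- q_unit / H
  G <- if (bulk_velocity == 0) 0 else bulk_velocity / c_unit
  list(G = G,
       u = G * (h0 * A - B),
       tau_w_bottom = G * h0,
       tau_w_top = G * (H - h0),
       h0 = h0 * 1e6,
       mu_eff = H^2 / (12 * c_unit))
}

#' March the pressure loss along a viscosity field
#'
#' Quasi-developed streamwise marching: at every station of the field the
#' fully developed variable-viscosity problem is solved for the local column
#' `mu(., x)` at the common bulk velocity, and the pressure gradients are
#' integrated over the channel length, `delta_p = int G(x) dx`. This
#' lubrication-style approximation is appropriate because the modelled
#' viscosity varies slowly in `x` and the observables of interest are the
#' integrated loss and the steady-section wall shear stress.
#'
#' @param field A [viscosity_field].
#' @param conditions A [flow_conditions] (positive bulk velocity).
#' @return An object of class `flow_solution`: per-station `G`, `tau_w_bottom`,
#'   `tau_w_top`, `mu_eff`, the total `delta_p` (Pa), the pressure-loss
#'   coefficient `cp`, and the run metadata.
#' @export
march_pressure_loss <- function(field, conditions) {
  stopifnot(inherits(field, "viscosity_field"),
            inherits(conditions, "flow_conditions"))
  if (conditions$bulk_velocity <= 0)
    .stopf("bulk velocity must be positive for a pressure-loss run")
  nx <- length(field$x_grid)
  G <- taub <- taut <- mueff <- numeric(nx)
  for (j in seq_len(nx)) {
    sol <- solve_developed_profile(field$h_grid, field$mu[, j],
                                   conditions$bulk_velocity)
    G[j] <- sol$G
    taub[j] <- sol$tau_w_bottom
    taut[j] <- sol$tau_w_top
    mueff[j] <- sol$mu_eff
  }
  delta_p <- .trapz(field$x_grid * 1e-6, G)
  cp <- pressure_loss_coefficient(delta_p, conditions$density,
                                  conditions$bulk_velocity)
  structure(
    list(x_grid = field$x_grid, section = field$section, G = G,
         tau_w_bottom = taub, tau_w_top = taut, mu_eff = mueff,
         delta_p = delta_p, cp = cp, reynolds = conditions$reynolds,
         bulk_velocity = conditions$bulk_velocity,
         density = conditions$density, submodel = field$submodel,
         fluid_label = field$fluid$label),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Channel flow solution (%s field%s)\n", x$submodel,
              if (nzchar(x$fluid_label)) paste0(", ", x$fluid_label) else ""))
  cat(sprintf("  Re = %.4g, c = %.4g m/s\n", x$reynolds, x$bulk_velocity))
  cat(sprintf("  delta_p = %.6g Pa over %d stations, cp = %.6g\n",
              x$delta_p, length(x$x_grid), x$cp))
  last <- length(x$x_grid)
  cat(sprintf("  steady-section wall shear stress: %.6g Pa\n",
              x$tau_w_bottom[last]))
  invisible(x)
}

#' Pressure-loss coefficient
#'
#' `cp = delta_p / (rho c^2 / 2)`, the dynamic-pressure normalization of the
#' channel pressure loss. Any constant multiple would cancel in the reported
#' `cp / cp_0%` ratio, which is the quantity used for model validation.
#'
#' @param delta_p Pressure loss in Pa.
#' @param density Density in kg/m^3.
#' @param bulk_velocity Bulk velocity in m/s (> 0).
#' @return Dimensionless pressure-loss coefficient.
#' @export
pressure_loss_coefficient <- function(delta_p, density, bulk_velocity) {
  stopifnot(.is_number(delta_p), .is_number(density), density > 0,
            .is_number(bulk_velocity))
  if (bulk_velocity == 0) .stopf("bulk velocity must be non-zero for cp")
  delta_p / (0.5 * density * bulk_velocity^2)
}

#' Normalized pressure-loss coefficient cp / cp_0%
#'
#' Ratio of a model run's pressure-loss coefficient to that of a
#' carrier-fluid-only reference at the same Reynolds number (each run's
#' Reynolds number built with its own fluid's rheometer viscosity). In the
#' fully developed limit the ratio equals `mu_eff / mu_rheo`, so a uniform
#' field at the bulk viscosity returns exactly 1 and any cell-free layer
#' pushes the ratio below 1, bounded by `mu_carrier / mu_rheo`.
#'
#' @param model_run,carrier_reference_run [march_pressure_loss()] results at
#'   matched Reynolds numbers.
#' @return The dimensionless ratio `cp / cp_0`.
#' @export
normalized_cp <- function(model_run, carrier_reference_run) {
  stopifnot(inherits(model_run, "flow_solution"),
            inherits(carrier_reference_run, "flow_solution"))
  re1 <- model_run$reynolds
  re2 <- carrier_reference_run$reynolds
  if (abs(re1 - re2) > 1e-9 * max(re1, re2, 1))
    .stopf("mismatched Reynolds numbers (%.6g vs %.6g)", re1, re2)
  model_run$cp / carrier_reference_run$cp
}

#' Wall shear stress: model field versus single-phase assumption
#'
#' Runs the assembled heterogeneous field and a uniform single-phase field at
#' the bulk viscosity through the solver at identical flow conditions and
#' compares steady-section wall shear stresses. The relative difference is a
#' dimensionless function of the viscosity profile only (it equals
#' `mu_eff / mu_rheo - 1` in the developed limit) and is therefore
#' independent of the assumed density.
#'
#' @param fluid A [fluid_spec].
#' @param geom A [channel_geometry].
#' @param dev A [cfl_development].
#' @param conditions A [flow_conditions].
#' @param submodel,steady_profile,n_h Passed to [assemble_field()].
#' @param station `"last"` (default) reports the final station;
#'   `"average"` the mean over the steady section.
#' @return A list: `tau_single`, `tau_model` (Pa), `rel_diff`
#'   (`(model - single)/single`) and `ratio`.
#' @export
wall_shear_comparison <- function(fluid, geom, dev, conditions,
                                  submodel = "step", steady_profile = NULL,
                                  n_h = 512, station = c("last", "average")) {
  station <- match.arg(station)
  model_field <- assemble_field(fluid, geom, dev, submodel = submodel,
                                steady_profile = steady_profile, n_h = n_h)
  single_dev <- cfl_development(a = 0)
  single_field <- assemble_field(fluid, geom, single_dev, submodel = "step",
                                 n_h = n_h)
  run_m <- march_pressure_loss(model_field, conditions)
  run_s <- march_pressure_loss(single_field, conditions)
  pick <- function(run) {
    if (station == "last") run$tau_w_bottom[length(run$tau_w_bottom)]
    else mean(run$tau_w_bottom[run$section == "steady"])
  }
  tau_m <- pick(run_m)
  tau_s <- pick(run_s)
  list(tau_single = tau_s, tau_model = tau_m,
       rel_diff = (tau_m - tau_s) / tau_s, ratio = tau_m / tau_s)
}
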