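# The user-facing model object: bundles fluid, geometry, calibrated
# development law and the assembled viscosity field behind one classed
# interface, in the style of R's classic modelling functions.

#' Fit a cell-free-layer viscosity model
#'
#' Central constructor tying the modules together. The development law comes
#' from one of three sources, tried in order: an explicit [cfl_development]
#' object, a widening coefficient `a` (with optional steady height), or a set
#' of measurement planes (either `(x, H_CFL)` pairs or [particle_profile]s,
#' whose CFL heights are detected first) passed to [calibrate_parabola()].
#' The sectioned viscosity field is then assembled with [assemble_field()].
#'
#' @param fluid A [fluid_spec].
#' @param geometry A [channel_geometry].
#' @param development Optional [cfl_development].
#' @param a,x0,h_cfl_ss Optional parabola parameters (used when
#'   `development` is `NULL`).
#' @param planes Optional calibration planes: a two-column matrix of
#'   `(x_um, h_cfl_um)` or a list of [particle_profile]s with station
#'   metadata.
#' @param submodel Steady-state submodel, `"step"` (default) or
#'   `"local_distribution"`.
#' @param steady_profile A [particle_profile] for the local-distribution
#'   submodel.
#' @param epsilon_detect Detection threshold for profile-based inputs.
#' @param ... Further arguments to [assemble_field()] (`n_h`, `n_x_dev`,
#'   `n_x_steady`, `cfl_interpretation`, ...).
#' @return An object of class `cfl_model`.
#' @examples
#' presets <- fluid_presets()
#' m <- cfl_model(presets$fluids$blood_5pct, presets$geometry,
#'                a = 0.5, h_cfl_ss = 20)
#' coef(m)
#' @export
cfl_model <- function(fluid, geometry, development = NULL, a = NULL,
                      x0 = 1, h_cfl_ss = NULL, planes = NULL,
                      submodel = c("step", "local_distribution"),
                      steady_profile = NULL, epsilon_detect = 1e-4, ...) {
  submodel <- match.arg(submodel)
  stopifnot(inherits(fluid, "fluid_spec"),
            inherits(geometry, "channel_geometry"))
  if (is.null(development)) {
    if (!is.null(a)) {
      development <- cfl_development(a = a, x0 = x0, h_cfl_ss = h_cfl_ss,
                                     H = geometry$H)
    } else if (!is.null(planes)) {
      if (is.list(planes) && length(planes) &&
          inherits(planes[[1]], "particle_profile")) {
        planes <- t(vapply(planes, function(p) {
          hts <- detect_cfl_height(p, epsilon_detect)
          c(attr(p, "x_station"), mean(hts))
        }, numeric(2)))
      }
      if (is.null(h_cfl_ss) && !is.null(steady_profile))
        h_cfl_ss <- mean(detect_cfl_height(steady_profile, epsilon_detect))
      development <- calibrate_parabola(planes, x0 = x0,
                                        h_cfl_ss = h_cfl_ss, H = geometry$H)
    } else {
      .stopf("provide one of: development, a, or calibration planes")
    }
  }
  field <- assemble_field(fluid, geometry, development, submodel = submodel,
                          steady_profile = steady_profile,
                          epsilon_detect = epsilon_detect, ...)
  structure(
    list(fluid = fluid, geom = geometry, dev = development, field = field,
         submodel = submodel, fit = field$fit,
         steady_profile = steady_profile, call = match.call()),
    class = "cfl_model")
}

#' @export
print.cfl_model <- function(x, ...) {
  cat("Cell-free-layer viscosity model\n")
  cat(sprintf("  fluid: %s (mu_carrier %.4g, mu_rheo %.4g mPa.s)\n",
              if (nzchar(x$fluid$label)) x$fluid$label else "<unnamed>",
              x$fluid$mu_carrier * 1e3, x$fluid$mu_rheo * 1e3))
  cat(sprintf("  gap H = %g um, steady CFL = %.4g um per wall, x* = %.5g um\n",
              x$geom$H, x$dev$h_cfl_ss, x$dev$x_star))
  cat(sprintf("  steady submodel: %s", x$submodel))
  if (x$submodel == "step") {
    cat(sprintf(" (core viscosity %.6g mPa.s)\n",
                step_viscosity_at(x$geom$L, x$fluid, x$geom, x$dev) * 1e3))
  } else {
    cat(sprintf(" (adjustment factor %.4g)\n", x$fit$adjustment_factor))
  }
  invisible(x)
}

#' @export
summary.cfl_model <- function(object, ...) {
  avg <- field_height_average(object$field)
  out <- list(model = object,
              consistency = max(abs(avg - object$fluid$mu_rheo)) /
                object$fluid$mu_rheo,
              coef = coef(object))
  class(out) <- "summary.cfl_model"
  out
}

#' @export
print.summary.cfl_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  height-average consistency: %.2e (relative)\n",
              x$consistency))
  cat("  coefficients:\n")
  print(signif(x$coef, 6))
  invisible(x)
}

#' @export
coef.cfl_model <- function(object, ...) {
  out <- c(a = object$dev$a, x0 = object$dev$x0,
           x_star = object$dev$x_star, h_cfl_ss = object$dev$h_cfl_ss)
  if (object$submodel == "step") {
    c(out, mu_step_steady = step_viscosity_at(object$geom$L, object$fluid,
                                              object$geom, object$dev))
  } else {
    c(out, adjustment_factor = object$fit$adjustment_factor,
      object$fit$coef_h)
  }
}

#' Predict local viscosity at arbitrary positions
#'
#' Evaluates the model's ideal (continuum) viscosity at the requested
#' `(x, h)` positions: the bulk viscosity in the homogeneous inlet, the
#' two-band step profile in the development section, and the steady
#' submodel's profile beyond the completion station. `x` and `h` are
#' recycled against each other.
#'
#' @param object A [cfl_model].
#' @param x Streamwise positions in um.
#' @param h Wall-normal positions in um.
#' @param ... Unused.
#' @return Local viscosities in Pa s.
#' @export
predict.cfl_model <- function(object, x, h, ...) {
  stopifnot(is.numeric(x), is.numeric(h))
  n <- max(length(x), length(h))
  x <- rep_len(x, n)
  h <- rep_len(h, n)
  H <- object$geom$H
  if (any(h < 0 | h > H)) .stopf("h must lie in [0, %g um]", H)
  f <- object$fluid
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (x[i] <= object$dev$x0) {
      out[i] <- f$mu_rheo
      next
    }
    if (object$submodel == "local_distribution" &&
        x[i] >= object$dev$x_star) {
      hc <- object$fit$h_cfl
      if (h[i] <= hc[1] || h[i] >= H - hc[2]) {
        out[i] <- f$mu_carrier
      } else {
        beta <- object$fit$adjustment_factor
        raw <- max(object$fit$eval_poly(h[i]), f$mu_carrier)
        out[i] <- f$mu_carrier + beta * (raw - f$mu_carrier)
      }
      next
    }
    pw <- hcfl_profile(x[i], object$dev)
    if (h[i] < pw || h[i] > H - pw) {
      out[i] <- f$mu_carrier
    } else {
      out[i] <- step_viscosity_at(x[i], f, object$geom, object$dev,
                                  object$field$cfl_interpretation)
    }
  }
  out
}

#' @export
residuals.cfl_model <- function(object, ...) {
  if (object$submodel != "local_distribution")
    .stopf("residuals are defined for the local_distribution submodel only")
  object$fit$residuals
}

#' Simulate synthetic measurement profiles from a fitted model
#'
#' Draws APTV-like particle-distribution profiles consistent with the
#' model's steady cell-free layer and the fluid's bulk volume fraction, with
#' per-bin Gaussian sampling noise. Seeds follow the base-R `simulate`
#' contract.
#'
#' @param object A [cfl_model].
#' @param nsim Number of profiles.
#' @param seed Optional integer seed.
#' @param x_station Station recorded in the metadata (default: channel end).
#' @param noise_sd Per-bin noise (default 10% of the bulk fraction).
#' @param n_bins Wall-normal bins.
#' @param ... Unused.
#' @return A list of [particle_profile]s.
#' @export
simulate.cfl_model <- function(object, nsim = 1, seed = NULL,
                               x_station = NULL, noise_sd = NULL,
                               n_bins = 128, ...) {
  if (object$fluid$phi_bulk <= 0)
    .stopf("cannot simulate particle profiles for a particle-free fluid")
  if (is.null(seed)) seed <- 1L
  if (is.null(noise_sd)) noise_sd <- 0.1 * object$fluid$phi_bulk
  if (is.null(x_station)) x_station <- object$geom$L
  hw <- hcfl_profile(x_station, object$dev)
  scen <- profile_scenario(object$fluid$phi_bulk, h_cfl = c(hw, hw),
                           noise_sd = noise_sd, n_bins = n_bins,
                           seed = seed)
  lapply(seq_len(nsim), function(i)
    generate_profile(scen, object$geom, x_station = x_station,
                     seed = seed + i - 1L))
}

#' Plot a cell-free-layer viscosity model
#'
#' `type = "profile"` draws the steady-state wall-normal viscosity profile,
#' `type = "development"` the streamwise CFL growth with the completion
#' station, and `type = "field"` an image of the full `mu(h, x)` field.
#'
#' @param x A [cfl_model].
#' @param type One of `"profile"`, `"development"`, `"field"`.
#' @param ... Passed to the underlying base-graphics call.
#' @return Invisibly, `x`.
#' @export
plot.cfl_model <- function(x, type = c("profile", "development", "field"),
                           ...) {
  type <- match.arg(type)
  if (type == "profile") {
    j <- length(x$field$x_grid)
    graphics::plot(x$field$mu[, j] * 1e3, x$field$h_grid, type = "l",
                   xlab = expression(mu[loc] ~ "(mPa s)"),
                   ylab = "h (um)",
                   main = "Steady-state viscosity profile", ...)
    graphics::abline(v = x$fluid$mu_rheo * 1e3, lty = 3)
    graphics::abline(h = c(x$dev$h_cfl_ss, x$geom$H - x$dev$h_cfl_ss),
                     lty = 2, col = "grey50")
  } else if (type == "development") {
    xs <- seq(0, min(x$geom$L, 2 * x$dev$x_star), length.out = 400)
    graphics::plot(xs, hcfl_profile(xs, x$dev), type = "l",
                   xlab = "x (um)", ylab = expression(H[CFL] ~ "(um)"),
                   main = "Cell-free layer development", ...)
    graphics::abline(v = x$dev$x_star, lty = 2, col = "grey50")
  } else {
    graphics::image(x$field$x_grid, x$field$h_grid, t(x$field$mu) * 1e3,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (um)", ylab = "h (um)",
                    main = expression(mu[loc](h, x) ~ "(mPa s)"), ...)
  }
  invisible(x)
}

#' Solve the channel flow for a fitted model
#'
#' Runs three cases through the marching solver at a common Reynolds number:
#' the heterogeneous model field, a uniform single-phase field at the bulk
#' viscosity, and a carrier-fluid-only reference (its bulk velocity rebuilt
#' from the same Reynolds number with the carrier viscosity). Reports wall
#' shear stresses, pressure losses, pressure-loss coefficients and the
#' normalized coefficients `cp / cp_0%`.
#'
#' @param model A [cfl_model].
#' @param reynolds Reynolds number (or `NULL` if `bulk_velocity` given).
#' @param bulk_velocity Bulk velocity in m/s (or `NULL`).
#' @param char_convention Reynolds length convention, see
#'   [flow_conditions()].
#' @return An object of class `cfl_flow`: the three [march_pressure_loss()]
#'   runs plus `cp_ratio` (model / carrier reference), `cp_ratio_single`
#'   (single-phase / carrier reference) and the steady wall-shear comparison.
#' @export
solve_flow <- function(model, reynolds = NULL, bulk_velocity = NULL,
                       char_convention = "H") {
  stopifnot(inherits(model, "cfl_model"))
  cond <- flow_conditions(model$fluid, model$geom, reynolds = reynolds,
                          bulk_velocity = bulk_velocity,
                          char_convention = char_convention)
  run_model <- march_pressure_loss(model$field, cond)
  single_field <- assemble_field(model$fluid, model$geom,
                                 cfl_development(a = 0), submodel = "step",
                                 n_h = length(model$field$h_grid) - 1)
  run_single <- march_pressure_loss(single_field, cond)
  carrier <- fluid_spec(model$fluid$mu_carrier, model$fluid$mu_carrier, 0,
                        density = model$fluid$density,
                        label = paste0(model$fluid$label, " carrier"))
  cond0 <- flow_conditions(carrier, model$geom, reynolds = cond$reynolds,
                           char_convention = char_convention)
  carrier_field <- assemble_field(carrier, model$geom,
                                  cfl_development(a = 0), submodel = "step",
                                  n_h = length(model$field$h_grid) - 1)
  run_carrier <- march_pressure_loss(carrier_field, cond0)
  last_of <- function(run) run$tau_w_bottom[length(run$tau_w_bottom)]
  structure(
    list(model_run = run_model, single_run = run_single,
         carrier_run = run_carrier,
         cp_ratio = normalized_cp(run_model, run_carrier),
         cp_ratio_single = normalized_cp(run_single, run_carrier),
         tau_w_model = last_of(run_model),
         tau_w_single = last_of(run_single),
         reynolds = cond$reynolds, bulk_velocity = cond$bulk_velocity),
    class = "cfl_flow")
}

#' @export
print.cfl_flow <- function(x, ...) {
  cat(sprintf("Channel flow at Re = %.4g (c = %.4g m/s)\n", x$reynolds,
              x$bulk_velocity))
  cat(sprintf("  delta_p: model %.6g Pa | single-phase %.6g Pa | carrier %.6g Pa\n",
              x$model_run$delta_p, x$single_run$delta_p,
              x$carrier_run$delta_p))
  cat(sprintf("  steady wall shear stress: model %.6g Pa | single-phase %.6g Pa (%+.1f%%)\n",
              x$tau_w_model, x$tau_w_single,
              100 * (x$tau_w_single / x$tau_w_model - 1)))
  cat(sprintf("  cp/cp_0%%: model %.6g | single-phase %.6g\n",
              x$cp_ratio, x$cp_ratio_single))
  invisible(x)
}

#' @export
plot.cfl_flow <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$model_run$x_grid, x$model_run$G, type = "l",
                 xlab = "x (um)", ylab = "G (Pa/m)",
                 main = "Pressure gradient", ...)
  graphics::lines(x$single_run$x_grid, x$single_run$G, lty = 2)
  graphics::legend("topright", c("model", "single-phase"), lty = c(1, 2),
                   bty = "n")
  graphics::plot(x$model_run$x_grid, x$model_run$tau_w_bottom, type = "l",
                 xlab = "x (um)", ylab = expression(tau[w] ~ "(Pa)"),
                 main = "Wall shear stress", ...)
  graphics::lines(x$single_run$x_grid, x$single_run$tau_w_bottom, lty = 2)
  invisible(x)
}
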