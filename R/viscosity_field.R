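# Assembly of the sectioned local-viscosity field mu_loc(h, x): homogeneous
# inlet, developing cell-free layer described by a step profile, and a
# steady-state section served by either the step submodel or the
# local-distribution (quartic polynomial) submodel. Every station satisfies
# the height-average consistency constraint: the mean of mu over the gap
# equals the rheometer viscosity mu_rheo.

#' Plane-channel geometry
#'
#' Gap height, width and length of the straight plane channel standing in for
#' a narrow device gap. The plane-channel (infinitely wide) approximation is
#' assumed; a width-to-height ratio below 7 triggers a warning because the
#' cross-sectional shape then starts to influence the particle distribution.
#'
#' @param H Gap height in um (default 150).
#' @param W Channel width in um.
#' @param L Channel length in um.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(H = 150, W = 8 * H, L = 30000) {
  stopifnot(.is_number(H), .is_number(W), .is_number(L))
  if (H <= 0 || W <= 0 || L <= 0) .stopf("all dimensions must be positive")
  if (W / H < 7)
    .warnf("width-to-height ratio %.2f < 7: plane-channel approximation questionable",
           W / H)
  structure(list(H = H, W = W, L = L), class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Plane channel: H = %g um, W = %g um (W/H = %.1f), L = %g um\n",
              x$H, x$W, x$W / x$H, x$L))
  invisible(x)
}

#' Core viscosity of the step profile at a station
#'
#' The two-band step profile puts carrier viscosity in the cell-free bands
#' and a single elevated core value chosen so the height-averaged viscosity
#' equals the bulk rheometer value:
#' `mu_step = (H * mu_rheo - H_cfl * mu_carrier) / (H - H_cfl)`,
#' where `H_cfl` is the total cell-free thickness. Under the default
#' interpretation the total combines both wall layers
#' (`2 * hcfl_profile(x)`), which makes the consistency constraint hold
#' exactly; `cfl_interpretation = "per_wall"` instead inserts the per-wall
#' height into the formula, a sensitivity mode that deliberately gives up the
#' constraint.
#'
#' @param x Streamwise station in um.
#' @param fluid A [fluid_spec].
#' @param geom A [channel_geometry].
#' @param dev A [cfl_development].
#' @param cfl_interpretation `"total"` (default) or `"per_wall"`.
#' @return Core viscosity in Pa s (`mu_rheo` when no CFL is present).
#' @export
step_viscosity_at <- function(x, fluid, geom, dev,
                              cfl_interpretation = c("total", "per_wall")) {
  cfl_interpretation <- match.arg(cfl_interpretation)
  stopifnot(inherits(fluid, "fluid_spec"), inherits(geom, "channel_geometry"),
            inherits(dev, "cfl_development"))
  per_wall <- hcfl_profile(x, dev)
  h_tot <- if (cfl_interpretation == "total") 2 * per_wall else per_wall
  .step_core_value(h_tot, geom$H, fluid$mu_rheo, fluid$mu_carrier)
}

.step_core_value <- function(h_cfl_total, H, mu_rheo, mu_carrier) {
  if (any(h_cfl_total >= H)) .stopf("cell-free layer exceeds channel")
  (H * mu_rheo - h_cfl_total * mu_carrier) / (H - h_cfl_total)
}

# Cell-averaged two-band step column on a nodal grid: node values are the
# averages of the ideal profile over each node's control cell, so the
# trapezoid height-average reproduces the analytic integral exactly.
.step_column <- function(h_grid, H, h_bottom, h_top, mu_carrier, mu_core) {
  ce <- .cell_edges(h_grid)
  w <- ce$hi - ce$lo
  cfl <- pmax(0, pmin(ce$hi, h_bottom) - ce$lo) +
    pmax(0, ce$hi - pmax(ce$lo, H - h_top))
  cfl <- pmin(cfl, w)
  (cfl * mu_carrier + (w - cfl) * mu_core) / w
}

#' Rescale a core viscosity profile onto the bulk constraint
#'
#' Multiplies the core excess over the carrier viscosity,
#' `mu(h) - mu_carrier`, by the unique factor `beta >= 0` that makes the
#' height-averaged viscosity equal the rheometer value `mu_rheo`
#' (trapezoid rule on the supplied grid). Cell-free bands, already at the
#' carrier viscosity, are untouched: the CFL viscosity is fixed by the model
#' and never rescaled. This is the adjustment step needed because measured
#' particle distributions pushed through the Einstein-Roscoe law can over- or
#' under-predict the bulk viscosity of real particle suspensions.
#'
#' @param h Ascending wall-normal grid in um spanning the gap.
#' @param mu_raw Raw viscosity profile in Pa s, everywhere `>= mu_carrier`,
#'   with CFL bands already at `mu_carrier`.
#' @param fluid A [fluid_spec].
#' @return A list with `mu` (adjusted profile) and `adjustment_factor`
#'   (`beta`; 1 when the raw profile already satisfies the constraint).
#' @export
apply_adjustment <- function(h, mu_raw, fluid) {
  stopifnot(inherits(fluid, "fluid_spec"), is.numeric(h), is.numeric(mu_raw),
            length(h) == length(mu_raw))
  mc <- fluid$mu_carrier
  if (any(mu_raw < mc * (1 - 1e-9)))
    .stopf("raw profile dips below mu_carrier; floor it before adjustment")
  H <- h[length(h)] - h[1]
  excess <- pmax(0, mu_raw - mc)
  target <- H * (fluid$mu_rheo - mc)
  got <- .trapz(h, excess)
  if (target > 0 && got <= 0)
    .stopf("inconsistent inputs: bulk viscosity below carrier over the core")
  beta <- if (target == 0) 0 else target / got
  list(mu = mc + beta * excess, adjustment_factor = beta)
}

#' Fit the local-distribution (quartic) steady-state submodel
#'
#' Least-squares fourth-degree polynomial fit of the viscosity profile on the
#' particle-laden core (between the cell-free bands), with the carrier
#' viscosity inside the bands. The fit uses a centred, scaled abscissa
#' `xi = (h - H/2) / (H/2)` for conditioning; coefficients are reported in
#' both the scaled and the raw-`h` basis. A fitted core dipping below the
#' carrier viscosity is floored there with a warning. The assembled profile
#' is then rescaled with [apply_adjustment()] so its height average equals
#' `mu_rheo`.
#'
#' @param h Wall-normal coordinates in um (full gap).
#' @param mu Viscosity samples in Pa s (e.g. [einstein_roscoe()] applied to a
#'   measured particle distribution).
#' @param fluid A [fluid_spec].
#' @param geom A [channel_geometry].
#' @param h_cfl Per-wall CFL heights `c(bottom, top)` in um.
#' @param edge_guard_bins Number of grid bins adjacent to each CFL edge
#'   excluded from the fit (default 1): the bin straddling the layer edge
#'   mixes cell-free and laden fluid and would bias the polynomial.
#' @return An object of class `local_distribution_fit`: scaled and raw
#'   polynomial coefficients, per-wall CFL heights, fit residuals, and the
#'   adjustment factor for the reference grid.
#' @export
fit_local_distribution <- function(h, mu, fluid, geom, h_cfl,
                                   edge_guard_bins = 1) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(geom, "channel_geometry"),
            is.numeric(h), is.numeric(mu), length(h) == length(mu),
            length(h_cfl) == 2, all(h_cfl >= 0))
  H <- geom$H
  bin <- stats::median(diff(h))
  guard <- edge_guard_bins * bin
  core <- h > h_cfl[1] + guard & h < H - h_cfl[2] - guard
  if (sum(core) < 5)
    .stopf("core region has %d support points; >= 5 required", sum(core))
  xi <- (h - H / 2) / (H / 2)
  X <- outer(xi[core], 0:4, `^`)
  fit <- stats::lm.fit(X, mu[core])
  coef_scaled <- fit$coefficients
  eval_poly <- function(hh) {
    drop(outer((hh - H / 2) / (H / 2), 0:4, `^`) %*% coef_scaled)
  }
  core_dense <- seq(h_cfl[1], H - h_cfl[2], length.out = 501)
  if (min(eval_poly(core_dense)) < fluid$mu_carrier * (1 - 1e-9))
    .warnf("fitted polynomial dips below mu_carrier on the core; flooring")
  # adjustment factor on a dense reference grid (recomputed exactly on the
  # field grid at assembly time)
  h_ref <- seq(0, H, length.out = 2001)
  mu_ref <- .local_distribution_column(h_ref, H, h_cfl, fluid$mu_carrier,
                                       eval_poly)
  adj <- apply_adjustment(h_ref, mu_ref, fluid)
  structure(
    list(coef_scaled = coef_scaled,
         coef_h = .poly_rebase(coef_scaled, 2 / H, -1),
         h_cfl = h_cfl, H = H,
         adjustment_factor = adj$adjustment_factor,
         residuals = fit$residuals, fitted = X %*% coef_scaled,
         h_core = h[core], mu_core = mu[core],
         eval_poly = eval_poly),
    class = "local_distribution_fit")
}

# Raw (floored, unadjusted) local-distribution column on a grid.
.local_distribution_column <- function(h_grid, H, h_cfl, mu_carrier,
                                       eval_poly) {
  mu <- pmax(eval_poly(h_grid), mu_carrier)
  mu[h_grid <= h_cfl[1] | h_grid >= H - h_cfl[2]] <- mu_carrier
  mu
}

# Rebase polynomial coefficients: p(xi) with xi = alpha * h + beta into
# coefficients of h.
.poly_rebase <- function(coefs, alpha, beta) {
  deg <- length(coefs) - 1
  out <- numeric(deg + 1)
  for (k in 0:deg) {
    for (j in 0:k) {
      out[j + 1] <- out[j + 1] +
        coefs[k + 1] * choose(k, j) * alpha^j * beta^(k - j)
    }
  }
  names(out) <- paste0("h^", 0:deg)
  out
}

#' @export
print.local_distribution_fit <- function(x, ...) {
  cat("Local-distribution submodel (quartic core polynomial)\n")
  cat(sprintf("  CFL heights: %.3g / %.3g um (bottom / top)\n",
              x$h_cfl[1], x$h_cfl[2]))
  cat(sprintf("  adjustment factor beta = %.6g\n", x$adjustment_factor))
  cat(sprintf("  fit RMS residual: %.3g Pa.s on %d core points\n",
              sqrt(mean(x$residuals^2)), length(x$residuals)))
  invisible(x)
}

#' Assemble the sectioned viscosity field
#'
#' Builds `mu_loc(h, x)` on a rectangular grid from the three streamwise
#' sections of the model: a homogeneous inlet at the bulk viscosity
#' (`x <= x0`), a development section where the cell-free layer grows along
#' the calibrated parabola and the profile is the two-band step of
#' [step_viscosity_at()], and a steady section (`x >= x_star`) served by
#' either the step submodel or the fitted local-distribution submodel.
#'
#' Nodal values are control-cell averages of the ideal piecewise profile, so
#' the trapezoid height average of every column equals `mu_rheo` exactly
#' (under the default total-thickness interpretation); the local-distribution
#' column is rescaled on the field grid itself for the same guarantee.
#'
#' @param fluid A [fluid_spec].
#' @param geom A [channel_geometry].
#' @param dev A [cfl_development].
#' @param submodel `"step"` or `"local_distribution"`.
#' @param steady_profile A [particle_profile] at a steady-state station;
#'   required for the local-distribution submodel.
#' @param n_h Number of wall-normal bins (default 256; the steady CFL must be
#'   resolved by at least 4 bins).
#' @param n_x_dev,n_x_steady Streamwise stations in the development and
#'   steady sections.
#' @param cfl_interpretation Meaning of the CFL thickness in the step
#'   formula; see [step_viscosity_at()].
#' @param h_cfl_steady Optional per-wall CFL heights for the steady
#'   local-distribution submodel, overriding detection from
#'   `steady_profile`.
#' @param epsilon_detect Detection threshold passed to [detect_cfl_height()].
#' @return An object of class `viscosity_field`: `x_grid`, `h_grid` (um),
#'   `mu` (matrix, rows = h, cols = x, Pa s), `section` labels per station,
#'   plus the inputs and any submodel fit.
#' @export
assemble_field <- function(fluid, geom, dev,
                           submodel = c("step", "local_distribution"),
                           steady_profile = NULL, n_h = 256, n_x_dev = 64,
                           n_x_steady = 16,
                           cfl_interpretation = c("total", "per_wall"),
                           h_cfl_steady = NULL, epsilon_detect = 1e-4) {
  submodel <- match.arg(submodel)
  cfl_interpretation <- match.arg(cfl_interpretation)
  stopifnot(inherits(fluid, "fluid_spec"), inherits(geom, "channel_geometry"),
            inherits(dev, "cfl_development"))
  H <- geom$H
  L <- geom$L
  if (L <= dev$x0) .stopf("channel length must exceed the inlet section")
  if (dev$h_cfl_ss >= H / 2) .stopf("cell-free layer exceeds channel")
  if (dev$a > 0 && dev$h_cfl_ss > 0 && dev$h_cfl_ss < 4 * H / n_h)
    .stopf("grid too coarse: steady CFL of %.3g um needs n_h >= %d to be resolved by 4 bins",
           dev$h_cfl_ss, ceiling(4 * H / dev$h_cfl_ss))
  if (submodel == "local_distribution" && is.null(steady_profile))
    .stopf("local_distribution submodel requires a steady_profile")

  h_grid <- seq(0, H, length.out = n_h + 1)

  truncated <- L < dev$x_star
  if (truncated)
    .warnf("channel ends inside development section (L = %g um < x* = %g um)",
           L, dev$x_star)
  x_dev_end <- min(dev$x_star, L)
  x_grid <- c(0, dev$x0)
  section <- c("homogeneous", "homogeneous")
  if (dev$a > 0) {
    xd <- seq(dev$x0, x_dev_end, length.out = n_x_dev + 1)[-1]
    x_grid <- c(x_grid, xd)
    section <- c(section, rep("development", length(xd)))
  }
  if (!truncated && L > dev$x_star) {
    xs <- seq(dev$x_star, L, length.out = n_x_steady + 1)[-1]
    x_grid <- c(x_grid, xs)
    section <- c(section, rep("steady", length(xs)))
  }
  section[x_grid >= dev$x_star] <- "steady"

  fit <- NULL
  steady_col <- NULL
  if (submodel == "local_distribution") {
    h_cfl <- if (!is.null(h_cfl_steady)) h_cfl_steady
             else detect_cfl_height(steady_profile, epsilon_detect)
    mu_meas <- einstein_roscoe(steady_profile$phi, fluid$mu_carrier)
    fit <- fit_local_distribution(steady_profile$h, mu_meas, fluid, geom,
                                  h_cfl)
    raw <- .local_distribution_column(h_grid, H, h_cfl, fluid$mu_carrier,
                                      fit$eval_poly)
    adj <- apply_adjustment(h_grid, raw, fluid)
    fit$adjustment_factor <- adj$adjustment_factor
    steady_col <- adj$mu
  }

  mu <- matrix(NA_real_, nrow = length(h_grid), ncol = length(x_grid))
  for (j in seq_along(x_grid)) {
    if (section[j] == "homogeneous") {
      mu[, j] <- fluid$mu_rheo
    } else if (section[j] == "steady" && submodel == "local_distribution") {
      mu[, j] <- steady_col
    } else {
      pw <- hcfl_profile(x_grid[j], dev)
      h_tot <- if (cfl_interpretation == "total") 2 * pw else pw
      core <- .step_core_value(h_tot, H, fluid$mu_rheo, fluid$mu_carrier)
      mu[, j] <- .step_column(h_grid, H, pw, pw, fluid$mu_carrier, core)
    }
  }

  structure(
    list(x_grid = x_grid, h_grid = h_grid, mu = mu, section = section,
         submodel = submodel, fluid = fluid, geom = geom, dev = dev,
         cfl_interpretation = cfl_interpretation, fit = fit),
    class = "viscosity_field")
}

#' Height-averaged viscosity per station
#'
#' Trapezoid height average of each field column, the quantity pinned to the
#' rheometer viscosity by the model's consistency constraint.
#'
#' @param field A [viscosity_field].
#' @return Numeric vector, one mean viscosity (Pa s) per station.
#' @export
field_height_average <- function(field) {
  stopifnot(inherits(field, "viscosity_field"))
  w <- .trapz_weights(field$h_grid)
  drop(crossprod(w, field$mu)) / diff(range(field$h_grid))
}

#' @export
print.viscosity_field <- function(x, ...) {
  cat(sprintf("Viscosity field (%s submodel, CFL thickness read as %s)\n",
              x$submodel, x$cfl_interpretation))
  cat(sprintf("  grid: %d h-nodes x %d stations; H = %g um, L = %g um\n",
              length(x$h_grid), length(x$x_grid), x$geom$H, x$geom$L))
  cat(sprintf("  sections: %s\n",
              paste(sprintf("%s (%d)", names(table(x$section)),
                            table(x$section)), collapse = ", ")))
  avg <- field_height_average(x)
  cat(sprintf("  height-average consistency: max |mean - mu_rheo|/mu_rheo = %.2e\n",
              max(abs(avg - x$fluid$mu_rheo)) / x$fluid$mu_rheo))
  invisible(x)
}

#' @export
summary.viscosity_field <- function(object, ...) {
  avg <- field_height_average(object)
  out <- list(
    field = object,
    consistency = max(abs(avg - object$fluid$mu_rheo)) / object$fluid$mu_rheo,
    mu_range = range(object$mu),
    steady_core = object$mu[ceiling(length(object$h_grid) / 2),
                            length(object$x_grid)])
  class(out) <- "summary.viscosity_field"
  out
}

#' @export
print.summary.viscosity_field <- function(x, ...) {
  print(x$field)
  cat(sprintf("  mu range: [%.4g, %.4g] mPa.s; steady mid-gap mu = %.6g mPa.s\n",
              x$mu_range[1] * 1e3, x$mu_range[2] * 1e3, x$steady_core * 1e3))
  invisible(x)
}

#' Export / import a viscosity field as delimited text
#'
#' Long-format CSV (`x_um`, `h_um`, `mu_Pa_s`, `section`) with the model
#' scalars in leading comment lines, round-trippable at full double
#' precision.
#'
#' @param field A [viscosity_field].
#' @param path File path.
#' @return `write_field` returns `path` invisibly; `read_field` a
#'   [viscosity_field] (calibration metadata reduced to the stored scalars).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "viscosity_field"))
  f <- field$fluid
  g <- field$geom
  d <- field$dev
  hdr <- c("# schema: cflvisc/field v1",
           sprintf("# submodel: %s", field$submodel),
           sprintf("# cfl_interpretation: %s", field$cfl_interpretation),
           sprintf("# mu_carrier_Pa_s: %.17g", f$mu_carrier),
           sprintf("# mu_rheo_Pa_s: %.17g", f$mu_rheo),
           sprintf("# phi_bulk: %.17g", f$phi_bulk),
           sprintf("# density_kg_m3: %.17g", f$density),
           sprintf("# label: %s", f$label),
           sprintf("# H_um: %.17g", g$H),
           sprintf("# W_um: %.17g", g$W),
           sprintf("# L_um: %.17g", g$L),
           sprintf("# a: %.17g", d$a),
           sprintf("# x0_um: %.17g", d$x0),
           sprintf("# exponent: %.17g", d$exponent),
           sprintf("# h_cfl_ss_um: %.17g", d$h_cfl_ss))
  long <- data.frame(
    x_um = rep(field$x_grid, each = length(field$h_grid)),
    h_um = rep(field$h_grid, times = length(field$x_grid)),
    mu_Pa_s = as.vector(field$mu),
    section = rep(field$section, each = length(field$h_grid)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(x_um = sprintf("%.17g", long$x_um),
               h_um = sprintf("%.17g", long$h_um),
               mu_Pa_s = sprintf("%.17g", long$mu_Pa_s),
               section = long$section),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s:\\s*", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  num <- function(key) as.numeric(get(key))
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("numeric", "numeric", "numeric",
                                       "character"))
  x_grid <- unique(df$x_um)
  h_grid <- unique(df$h_um)
  mu <- matrix(df$mu_Pa_s, nrow = length(h_grid))
  section <- df$section[match(x_grid, df$x_um)]
  fluid <- fluid_spec(num("mu_carrier_Pa_s"), num("mu_rheo_Pa_s"),
                      min(num("phi_bulk"), 0.05), num("density_kg_m3"),
                      label = get("label"))
  fluid$phi_bulk <- num("phi_bulk")
  geom <- channel_geometry(num("H_um"), num("W_um"), num("L_um"))
  dev <- cfl_development(num("a"), num("x0_um"),
                         h_cfl_ss = if (num("a") > 0) num("h_cfl_ss_um"),
                         exponent = num("exponent"))
  structure(
    list(x_grid = x_grid, h_grid = h_grid, mu = mu, section = section,
         submodel = get("submodel"), fluid = fluid, geom = geom, dev = dev,
         cfl_interpretation = get("cfl_interpretation"), fit = NULL),
    class = "viscosity_field")
}
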