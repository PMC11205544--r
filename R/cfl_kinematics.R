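# Streamwise kinematics of the cell-free layer: tilted-parabola growth,
# two-plane calibration, completion criterion, and CFL detection from
# wall-normal particle-distribution profiles. Lengths in micrometres.

#' Cell-free layer development law
#'
#' Describes the streamwise growth of the per-wall cell-free layer height as a
#' tilted parabola: `H_CFL(x) = a * (x - x0)^exponent` beyond a short
#' homogeneous inlet section of length `x0`, clamped at the steady-state
#' height once development is complete. The default exponent 1/2 puts the
#' parabola axis along the flow direction, the standard description of
#' migration-driven layer growth; other exponents are accepted for
#' sensitivity studies.
#'
#' The completion station `x_star` is either implied by a prescribed
#' steady-state height `h_cfl_ss` (the station where the parabola reaches it)
#' or, when no steady height is known, computed from the completion criterion:
#' growth of less than `rel_tol` (default 0.1%) relative change per `delta_x`
#' (default 1 um) in the flow direction.
#'
#' @param a Parabola widening coefficient (um^(1-exponent) scaling), >= 0.
#' @param x0 Homogeneous inlet section length in um (default 1).
#' @param h_cfl_ss Optional steady-state per-wall CFL height in um.
#' @param H Optional gap height in um; if given, validates
#'   `h_cfl_ss < H / 2`.
#' @param exponent Growth exponent (default 0.5).
#' @param delta_x,rel_tol Completion-criterion step (um) and relative change
#'   threshold, used only when `h_cfl_ss` is not prescribed.
#' @return An object of class `cfl_development` with elements `a`, `x0`,
#'   `x_star`, `h_cfl_ss`, `exponent`.
#' @examples
#' dev <- cfl_development(a = 0.5, h_cfl_ss = 20)
#' hcfl_profile(c(1, 401, 1601, 5000), dev)
#' @export
cfl_development <- function(a, x0 = 1, h_cfl_ss = NULL, H = NULL,
                            exponent = 0.5, delta_x = 1, rel_tol = 0.001) {
  stopifnot(.is_number(a), .is_number(x0), .is_number(exponent))
  if (a < 0) .stopf("parabola coefficient a must be >= 0")
  if (exponent <= 0 || exponent > 1) .stopf("exponent must lie in (0, 1]")
  dev <- structure(
    list(a = a, x0 = x0, x_star = x0, h_cfl_ss = 0, exponent = exponent,
         delta_x = delta_x, rel_tol = rel_tol, calibration = NULL),
    class = "cfl_development")
  if (a == 0) {
    if (!is.null(h_cfl_ss) && h_cfl_ss > 0)
      .stopf("a = 0 is inconsistent with a positive steady CFL height")
    return(dev)
  }
  if (!is.null(h_cfl_ss)) {
    stopifnot(.is_number(h_cfl_ss), h_cfl_ss >= 0)
    dev$h_cfl_ss <- h_cfl_ss
    dev$x_star <- x0 + (h_cfl_ss / a)^(1 / exponent)
  } else {
    dev$x_star <- completion_station(dev, delta_x = delta_x,
                                     rel_tol = rel_tol)
    dev$h_cfl_ss <- a * (dev$x_star - x0)^exponent
  }
  if (!is.null(H) && dev$h_cfl_ss >= H / 2)
    .stopf("steady CFL height %.3g um must be below H/2 = %.3g um",
           dev$h_cfl_ss, H / 2)
  dev
}

#' @export
print.cfl_development <- function(x, ...) {
  cat("CFL development (tilted parabola)\n")
  cat(sprintf("  a = %.6g, exponent = %g, x0 = %g um\n", x$a, x$exponent,
              x$x0))
  cat(sprintf("  completion x* = %.6g um, steady height = %.6g um per wall\n",
              x$x_star, x$h_cfl_ss))
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated from %d plane(s), residual RMS %.3g um\n",
                nrow(x$calibration$planes), x$calibration$rms_residual))
  invisible(x)
}

#' Per-wall cell-free layer height along the channel
#'
#' Evaluates the development law: zero in the homogeneous inlet section
#' (`x <= x0`), parabolic growth in the development section, and the constant
#' steady-state height beyond the completion station. Continuous and
#' non-decreasing in `x`.
#'
#' @param x Streamwise position(s) in um, >= 0.
#' @param dev A [cfl_development] object.
#' @return Per-wall CFL height(s) in um.
#' @export
hcfl_profile <- function(x, dev) {
  stopifnot(inherits(dev, "cfl_development"), is.numeric(x))
  if (any(x < 0)) .stopf("x must be >= 0")
  h <- numeric(length(x))
  grow <- x > dev$x0 & x < dev$x_star
  h[grow] <- dev$a * (x[grow] - dev$x0)^dev$exponent
  h[x >= dev$x_star] <- dev$h_cfl_ss
  h
}

#' Calibrate the development parabola from measurement planes
#'
#' Least-squares fit of the widening coefficient `a` from two (or more)
#' measurement planes `(x, H_CFL)` inside the development section, mirroring
#' the calibration of the growth law against two optical (APTV) measuring
#' planes. For two mutually consistent planes the fit is exact; otherwise the
#' least-squares `a` and the residuals are reported.
#'
#' @param planes A two-column matrix or data frame (`x` um, `h_cfl` um), or a
#'   list of length-2 numeric vectors. At least two planes with distinct
#'   stations.
#' @param x0 Homogeneous section length in um (held fixed, default 1).
#' @param exponent Growth exponent (default 0.5).
#' @param h_cfl_ss,H Passed on to [cfl_development()].
#' @return A [cfl_development] with a `calibration` element (planes, fitted
#'   heights, residuals, RMS residual).
#' @examples
#' dev <- calibrate_parabola(rbind(c(401, 10), c(1601, 20)))
#' coef_a <- dev$a  # 0.5
#' @export
calibrate_parabola <- function(planes, x0 = 1, exponent = 0.5,
                               h_cfl_ss = NULL, H = NULL) {
  if (is.list(planes) && !is.data.frame(planes))
    planes <- do.call(rbind, planes)
  planes <- as.matrix(planes)
  if (ncol(planes) != 2 || nrow(planes) < 2)
    .stopf("planes must provide at least two (x, h_cfl) pairs")
  colnames(planes) <- c("x", "h_cfl")
  xs <- planes[, 1]
  hs <- planes[, 2]
  if (anyDuplicated(xs)) {
    dup <- duplicated(cbind(xs, hs))
    if (anyDuplicated(xs[!dup])) .stopf("coincident measurement stations")
    planes <- planes[!dup, , drop = FALSE]
    xs <- planes[, 1]
    hs <- planes[, 2]
    if (nrow(planes) < 2) {
      planes <- rbind(planes, planes)
      xs <- planes[, 1]
      hs <- planes[, 2]
    }
  }
  if (any(xs <= x0)) .stopf("all stations must lie beyond x0 = %g um", x0)
  if (any(hs < 0)) .stopf("CFL heights must be >= 0")
  if (!is.null(H) && any(hs >= H / 2))
    .stopf("measured CFL height >= H/2: no particle-laden core")
  s <- (xs - x0)^exponent
  a <- sum(hs * s) / sum(s^2)
  if (a < 0) a <- 0
  fitted <- a * s
  res <- hs - fitted
  dev <- cfl_development(a = a, x0 = x0, h_cfl_ss = h_cfl_ss, H = H,
                         exponent = exponent)
  dev$calibration <- list(planes = planes, fitted = fitted, residuals = res,
                          rms_residual = sqrt(mean(res^2)))
  dev
}

#' Completion station of the CFL development
#'
#' Smallest streamwise position at which the relative growth of the CFL
#' height over a step `delta_x` falls below `rel_tol` (default 0.1% per
#' micrometre). For the square-root growth law this has the closed form
#' `x0 + delta_x / ((1 + rel_tol)^(1/exponent) - 1)`, which the brute-force
#' definition approaches as the scanning step shrinks.
#'
#' @param dev A [cfl_development] (its clamping is ignored; only `a`, `x0`,
#'   `exponent` matter).
#' @param delta_x Streamwise increment in um over which growth is assessed.
#' @param rel_tol Relative-change threshold (default 0.001).
#' @return Completion station in um; `x0` when `a = 0` (immediately
#'   complete).
#' @export
completion_station <- function(dev, delta_x = 1, rel_tol = 0.001) {
  stopifnot(inherits(dev, "cfl_development"), .is_number(delta_x),
            delta_x > 0, .is_number(rel_tol), rel_tol > 0)
  if (dev$a == 0) return(dev$x0)
  # (((x - x0) + dx) / (x - x0))^p < 1 + tol  <=>  x - x0 > dx / ((1+tol)^(1/p) - 1)
  dev$x0 + delta_x / ((1 + rel_tol)^(1 / dev$exponent) - 1)
}

#' Wall-normal particle-distribution profile
#'
#' Container for a measured or synthetic local volume-fraction profile
#' `phi_loc(h)` at one streamwise station, the quantity an APTV measurement
#' delivers: wall-normal bin coordinates covering the full gap and a local
#' volume fraction per bin.
#'
#' @param h Ascending wall-normal coordinates in um, from the bottom wall
#'   (first value 0) to the top wall.
#' @param phi Local volume fractions, one per coordinate, all >= 0.
#' @param x_station Streamwise station of the profile in um (NA if unknown).
#' @param n_samples Optional per-bin particle counts.
#' @return An object of class `particle_profile` (a data frame with
#'   attributes `x_station`).
#' @export
particle_profile <- function(h, phi, x_station = NA_real_, n_samples = NULL) {
  stopifnot(is.numeric(h), is.numeric(phi), length(h) == length(phi))
  if (length(h) < 2) .stopf("profile needs at least two bins")
  if (any(diff(h) <= 0)) .stopf("h must be strictly increasing")
  if (any(phi < 0)) .stopf("phi must be >= 0 everywhere")
  if (!is.null(n_samples)) stopifnot(length(n_samples) == length(h))
  out <- data.frame(h = h, phi = phi)
  if (!is.null(n_samples)) out$count <- n_samples
  attr(out, "x_station") <- x_station
  class(out) <- c("particle_profile", "data.frame")
  out
}

#' Detect per-wall cell-free layer heights in a profile
#'
#' The bottom CFL height is the largest `h` such that the volume fraction is
#' at or below `epsilon` everywhere between the bottom wall and `h`; the top
#' height is defined symmetrically from the opposite wall. When the first
#' particle-laden bin carries less concentration than its core-side
#' neighbour it is treated as a partial edge bin (the layer edge crosses its
#' control cell) and the edge position is refined by inverting the bin
#' average, which recovers a sharp-edged (plateau-core) layer to well within
#' one bin width; with `refine = FALSE` the estimate stays quantised to the
#' grid. Returns zero for a wall whose first bin already carries particles.
#'
#' @param profile A [particle_profile].
#' @param epsilon Absolute volume-fraction threshold (default `1e-4`, well
#'   below any particle-laden core at bulk fractions of 1% or more; raise it
#'   above the noise floor for noisy profiles).
#' @param refine Refine the edge inside partial bins (default `TRUE`).
#' @return Named numeric vector `c(bottom, top)` in um.
#' @export
detect_cfl_height <- function(profile, epsilon = 1e-4, refine = TRUE) {
  stopifnot(inherits(profile, "particle_profile"), .is_number(epsilon),
            epsilon >= 0)
  h <- profile$h
  phi <- profile$phi
  n <- length(h)
  laden <- which(phi > epsilon)
  if (length(laden) == 0)
    .stopf("no particle-laden core: profile is empty at epsilon = %g",
           epsilon)
  ce <- .cell_edges(h)
  j <- laden[1]
  bottom <- if (j == 1) 0 else h[j - 1] - h[1]
  if (refine && j > 1 && j < n && phi[j] < phi[j + 1]) {
    edge <- ce$hi[j] - (ce$hi[j] - ce$lo[j]) * phi[j] / phi[j + 1]
    bottom <- min(max(edge, h[j - 1]), ce$hi[j]) - h[1]
  }
  k <- laden[length(laden)]
  top <- if (k == n) 0 else h[n] - h[k + 1]
  if (refine && k < n && k > 1 && phi[k] < phi[k - 1]) {
    edge <- ce$lo[k] + (ce$hi[k] - ce$lo[k]) * phi[k] / phi[k - 1]
    top <- h[n] - min(max(edge, ce$lo[k]), h[k + 1])
  }
  c(bottom = bottom, top = top)
}

#' Read / write particle profiles as delimited text
#'
#' Profiles are exchanged as CSV with columns `h_um`, `phi` (and optionally
#' `count`), preceded by comment lines carrying the station metadata and the
#' schema tag.
#'
#' @param profile A [particle_profile].
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns a
#'   [particle_profile].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "particle_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# schema: cflvisc/profile v1",
               sprintf("# x_station_um: %.17g", attr(profile, "x_station"))),
             con)
  df <- as.data.frame(profile)
  names(df)[1:2] <- c("h_um", "phi")
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- grep("^# x_station_um:", lines, value = TRUE)
  x_station <- if (length(meta))
    as.numeric(sub("^# x_station_um:\\s*", "", meta[1])) else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  particle_profile(df$h_um, df$phi, x_station = x_station,
                   n_samples = df$count)
}
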