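# Independent oracles and fixture builders shared across the suite. These
# deliberately avoid the code paths they check: closed forms, hand
# arithmetic, and pracma quadrature.

# Effective viscosity of a symmetric two-layer plane-channel profile
# (carrier bands of per-wall thickness h_cfl, constant core), closed form:
#   1/mu_eff = (b/a)^3 / mu_core + (1 - (b/a)^3) / mu_cfl
# with a = H/2, b = H/2 - h_cfl.
oracle_two_layer_mu_eff <- function(H, h_cfl, mu_cfl, mu_core) {
  a <- H / 2
  b <- a - h_cfl
  r3 <- (b / a)^3
  1 / (r3 / mu_core + (1 - r3) / mu_cfl)
}

# Core viscosity of the conservative step profile (hand arithmetic of the
# mixing rule, independent of the package helper).
oracle_step_core <- function(H, h_cfl_total, mu_rheo, mu_carrier) {
  (H * mu_rheo - h_cfl_total * mu_carrier) / (H - h_cfl_total)
}

# Two-layer viscosity profile with the jumps represented exactly by
# repeated nodes; n interior points per band.
make_two_layer_profile <- function(H, h_cfl, mu_cfl, mu_core, n = 64) {
  h <- c(seq(0, h_cfl, length.out = n), h_cfl,
         seq(h_cfl, H - h_cfl, length.out = 4 * n), H - h_cfl,
         seq(H - h_cfl, H, length.out = n))
  mu <- c(rep(mu_cfl, n), mu_core, rep(mu_core, 4 * n), mu_cfl,
          rep(mu_cfl, n))
  list(h = h, mu = mu)
}

# Clean step particle-distribution fixture: nodes at multiples of `bin`,
# zero up to and including the band edges, plateau inside.
make_step_particle_profile <- function(H = 150, h_cfl = 20, plateau = 0.04,
                                       bin = 10, x_station = NA_real_) {
  h <- seq(0, H, by = bin)
  phi <- ifelse(h > h_cfl & h < H - h_cfl, plateau, 0)
  particle_profile(h, phi, x_station = x_station)
}

reference_fluids <- function() fluid_presets()$fluids
reference_geometry <- function() fluid_presets()$geometry
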