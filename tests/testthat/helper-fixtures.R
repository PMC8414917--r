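# Small in-code fixtures and independent oracles shared across tests.

# A minimal fast phenotype: primary (+ optional seminals), no nodal whorls,
# laterals switched off unless asked for.
tiny_phenotype <- function(srn = 0L, laterals = FALSE, primary_rate = 2,
                           seed_mass = 300, planting_depth = 2) {
  bf <- if (laterals) c(1, 1) else c(0, 0)
  rc <- function(cls, emerg, rate, ang, freq, d, maxlen = Inf)
    root_class_params(cls, emerg, rate_function(0, rate), ang, freq, d,
                      tissue_density = 0.05, respiration_rate = 0.002,
                      max_length = maxlen)
  plant_phenotype(
    name = "tiny", seed_mass = seed_mass, carbohydrate_fraction = 0.7,
    seed_nitrogen = 5, seed_phosphorus = 0.3,
    seminal_root_number = srn,
    nodal_whorls = data.frame(emergence_day = numeric(0),
                              roots_per_whorl = integer(0)),
    mesocotyl_rate = 2, mesocotyl_diameter = 0.1,
    planting_depth = planting_depth,
    leaf_area_expansion_rate = rate_function(0.4, 0),
    root_classes = list(
      primary = rc("primary", 0, primary_rate, 0, bf, 0.08),
      seminal = rc("seminal", 1, 1.5, 45, bf, 0.05),
      nodal = rc("nodal", 7, 2, 40, bf, 0.09),
      lateral_primary = rc("lateral_primary", 0, 0.5, 70, c(0, 0), 0.02, 3),
      lateral_seminal = rc("lateral_seminal", 0, 0.5, 70, c(0, 0), 0.02, 3),
      lateral_nodal = rc("lateral_nodal", 0, 0.5, 70, c(0, 0), 0.02, 3)),
    allocation_coefficients = c(roots = 0.4, stem = 0.2, leaves = 0.4),
    optimal_tissue_conc = list(root = c(n = 1000, p = 40),
                               shoot = c(n = 2000, p = 60)))
}

# A small flat-profile environment (no rain by default).
tiny_environment <- function(n_layers = 30, nitrate = 2, organic = 0.5,
                             p = 0.001, rain = rep(0, 30)) {
  tx <- soil_texture("silt_loam", bulk_density = 1.3, field_capacity = 0.3,
                     wilting_point = 0.1, saturated_conductivity = 50,
                     dispersivity = 1, p_buffer_power = 100,
                     p_diffusion_coefficient = 0.1)
  soil_environment(
    texture = tx, rainfall = rain,
    initial_nitrate_profile = rep(nitrate, n_layers),
    organic_matter_n_profile = rep(organic, n_layers),
    initial_p_profile = rep(p, n_layers),
    prism = c(width = 20, length = 20, depth = n_layers),
    row_spacing = 40, in_row_spacing = 20, evaporation_rate = 0)
}

fast_control <- function(...) sim_control(bc_nodes = 10, ...)

# ---- independent oracles ------------------------------------------------

# Quadratic least squares via the normal equations, solved directly.
quad_fit_oracle <- function(t, y) {
  X <- cbind(1, t, t^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]  # c, b, a
}

# Final position of a billiard path in an axis-aligned box via coordinate
# folding (independent of the step-wise reflection code). z-bottom contact
# is excluded by construction of the test cases.
fold_oracle <- function(start, heading, length, lims) {
  fold1 <- function(x, w) {
    y <- x %% (2 * w)
    if (y > w) 2 * w - y else y
  }
  p <- start + heading * length
  c(fold1(p[1], lims[1]), fold1(p[2], lims[2]), fold1(p[3], lims[3]))
}

# Explicit fine-grid Barber-Cushman oracle: uniform radial grid, forward
# Euler, flux-conservative; independent of the package solver.
bc_explicit_oracle <- function(params, c0, total_t, nr = 140) {
  r <- seq(params$r0, params$rx, length.out = nr)
  dr <- r[2] - r[1]
  rf <- c(r[1], (r[-1] + r[-nr]) / 2, r[nr])
  vol <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2)
  af <- 2 * pi * rf
  C <- rep(c0, nr)
  cond <- params$de * params$b * af[2:nr] / dr
  dt <- 0.2 * min(params$b * vol) / max(cond)
  nt <- ceiling(total_t / dt)
  dt <- total_t / nt
  taken <- 0
  q <- 2 * pi * params$r0 * params$water_flux_at_root
  for (s in seq_len(nt)) {
    flux <- cond * (C[2:nr] - C[1:(nr - 1)])     # inward positive
    dC <- numeric(nr)
    dC[1:(nr - 1)] <- dC[1:(nr - 1)] + flux / (params$b * vol[1:(nr - 1)])
    dC[2:nr] <- dC[2:nr] - flux / (params$b * vol[2:nr])
    if (q > 0) {
      conv <- q * C[2:nr]
      dC[1:(nr - 1)] <- dC[1:(nr - 1)] + conv / (params$b * vol[1:(nr - 1)])
      dC[2:nr] <- dC[2:nr] - conv / (params$b * vol[2:nr])
    }
    excess <- C[1] - params$c_min
    if (excess > 0) {
      F <- params$i_max * excess / (params$k_m + excess)
      U <- 2 * pi * params$r0 * F
      dC[1] <- dC[1] - U / (params$b * vol[1])
      taken <- taken + U * dt
    }
    C <- C + dC * dt
  }
  list(uptake = taken, profile = C)
}

# Waterfall allocation oracle: repeated proportional offers, written as a
# direct (slow) loop.
allocate_oracle <- function(available, coefficients, demands) {
  got <- setNames(rep(0, length(coefficients)), names(coefficients))
  pool <- available
  for (iter in 1:1000) {
    open <- names(which(got < demands[names(coefficients)] - 1e-15))
    if (!length(open) || pool <= 1e-15) break
    w <- coefficients[open] / sum(coefficients[open])
    offer <- pool * w
    take <- pmin(offer, demands[open] - got[open])
    got[open] <- got[open] + take
    pool <- pool - sum(take)
  }
  got
}

# Brute-force optimum: round, scan every entry.
select_optimum_oracle <- function(cell_means) {
  r <- round(cell_means, 6)
  srn <- as.integer(names(cell_means))
  best <- -Inf
  pick <- NA_integer_
  for (i in order(srn)) {
    if (r[i] > best + 1e-15) {
      best <- r[i]
      pick <- srn[i]
    }
  }
  pick
}

# Standard study environments (shared by engine and acceptance tests).
study_environments <- function() {
  list(low_n = make_environment_fixture("silt_loam", n_target = 50,
                                        p_target = 100)$environment,
       low_p = make_environment_fixture("silt_loam", n_target = 400,
                                        p_target = 2)$environment)
}

unstressed_environment <- function() {
  scale_environment_nutrients(
    make_environment_fixture("silt_loam", 50, 100)$environment, 50, 5)
}
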