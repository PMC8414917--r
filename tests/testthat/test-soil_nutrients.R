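# Water balance, nitrate transport, mineralization and nutrient uptake.

test_that("the tipping-bucket water step is exactly conservative", {
  env <- tiny_environment(n_layers = 10)
  col <- soil_column(env)

  out <- step_water(col, 0, 0)
  expect_equal(out$fluxes, rep(0, 10))
  expect_identical(out$column$water, col$water)

  # column at field capacity: all rain passes straight through
  out2 <- step_water(col, 0.8, 0)
  expect_equal(out2$drainage, 0.8)
  expect_equal(out2$fluxes, rep(0.8, 10))

  # dry column, rain below the top-layer deficit: all retained in layer 1
  dry <- col
  dry$water <- rep(0.12, 10)            # deficit 0.18 cm per layer
  out3 <- step_water(dry, 0.1, 0)
  expect_equal(out3$column$water[1], 0.22)
  expect_equal(out3$drainage, 0)

  # general conservation: rain = storage change + drainage + evaporation
  set.seed(14)
  wet <- col
  wet$water <- runif(10, 0.12, 0.3)
  rain <- 0.6
  out4 <- step_water(wet, rain, 0.15)
  delta <- sum(out4$column$water - wet$water)
  expect_equal(rain, delta + out4$drainage + out4$evaporated,
               tolerance = 1e-9)
})

test_that("nitrate advection moves a pulse at flux/theta and conserves mass
          exactly", {
  env <- tiny_environment(n_layers = 30, nitrate = 0)
  env$texture$dispersivity <- 0
  col <- soil_column(env)
  col$nitrate[10] <- 100
  theta <- col$water[1]
  flux <- rep(0.06, 30)                 # cm per step
  centroid <- function(x) sum(seq_along(x) * x) / sum(x)
  c0 <- centroid(col$nitrate)
  steps <- 20
  leached <- 0
  for (i in seq_len(steps)) {
    out <- transport_nitrate(col, flux)
    col <- out$column
    leached <- leached + out$leachate
  }
  expect_equal(centroid(col$nitrate), c0 + steps * 0.06 / theta,
               tolerance = 1e-6)
  expect_equal(sum(col$nitrate) + leached, 100, tolerance = 1e-9)

  # zero flux: nothing moves
  out0 <- transport_nitrate(col, rep(0, 30))
  expect_identical(out0$column$nitrate, col$nitrate)
  expect_equal(out0$leachate, 0)
})

test_that("dispersion conserves mass and prolonged drainage leaches
          everything", {
  env <- tiny_environment(n_layers = 15, nitrate = 1)
  env$texture$dispersivity <- 2
  col <- soil_column(env)
  m0 <- sum(col$nitrate)
  tot_leach <- 0
  for (i in 1:400) {
    out <- transport_nitrate(col, rep(0.15, 15))
    col <- out$column
    tot_leach <- tot_leach + out$leachate
  }
  expect_equal(sum(col$nitrate) + tot_leach, m0, tolerance = 1e-6 * m0)
  expect_gt(tot_leach, 0.99 * m0)      # asymptotically fully leached
  expect_true(all(col$nitrate >= 0))
})

test_that("mineralization follows the aging first-order law and is bounded
          by the pool", {
  env <- tiny_environment(n_layers = 5, organic = 10)
  col <- soil_column(env)
  expect_identical(mineralize(col, 1, 0.1, k0 = 0)$column$organic_n,
                   col$organic_n)

  # s = 0: plain exponential pool decay against the closed form
  col2 <- soil_column(env)
  k0 <- 0.05
  pool0 <- sum(col2$organic_n)
  for (i in 1:250) col2 <- mineralize(col2, i * 0.1, 0.1, k0 = k0,
                                      s = 0)$column
  expect_equal(sum(col2$organic_n), pool0 * exp(-k0 * 25),
               tolerance = 1e-3 * pool0)

  # aging (s > 0): cumulative release over 25 d never exceeds the pool and
  # the released N shows up as nitrate
  col3 <- soil_column(env)
  n0 <- sum(col3$nitrate)
  for (i in 1:100) col3 <- mineralize(col3, i * 0.25, 0.25, k0 = 0.02,
                                      s = 0.5)$column
  expect_lte(col3$mineralized_n, pool0)
  expect_equal(sum(col3$nitrate) - n0, col3$mineralized_n,
               tolerance = 1e-9)
})

test_that("nitrate uptake saturates at i_max, rations within layers and
          respects the demand cap", {
  env <- tiny_environment(n_layers = 4, nitrate = 0)
  col <- soil_column(env)
  sa <- rep(10, 4)
  out <- uptake_nitrate(sa, col, kinetics = c(2, 0.05), dt = 1)
  expect_equal(sum(out$uptake), 0)

  # concentration far above k_m: uptake within 1% of surface x i_max x dt
  env2 <- tiny_environment(n_layers = 4, nitrate = 50)
  col2 <- soil_column(env2)
  out2 <- uptake_nitrate(sa, col2, kinetics = c(2, 0.05), dt = 1)
  expect_lt(abs(sum(out2$uptake) - 4 * 10 * 2) / (4 * 10 * 2), 0.01)

  # two classes in one nearly-empty layer: proportional rationing empties it
  col3 <- soil_column(tiny_environment(n_layers = 2, nitrate = 50))
  col3$nitrate <- c(0.5, 0)
  SA <- matrix(0, 2, 2)
  SA[1, 1] <- 30
  SA[2, 1] <- 10
  out3 <- uptake_nitrate(SA, col3, kinetics = c(2, 0.05), dt = 1)
  expect_equal(sum(out3$uptake), 0.5, tolerance = 1e-9)
  expect_equal(out3$uptake[1, 1] / out3$uptake[2, 1], 3, tolerance = 1e-9)
  expect_equal(out3$column$nitrate[1], 0, tolerance = 1e-12)

  # plant-level demand cap scales everything down
  out4 <- uptake_nitrate(sa, col2, kinetics = c(2, 0.05), demand_cap = 5,
                         dt = 1)
  expect_equal(sum(out4$uptake), 5, tolerance = 1e-9)
})

test_that("the radial phosphorus solver obeys its limits", {
  p <- bc_params(i_max = 0, k_m = 0.02, c_min = 0, de = 0.1, b = 100,
                 r0 = 0.03, rx = 0.5)
  out <- uptake_p_barber_cushman(10, p, c_initial = 0.002, dt = 1)
  expect_equal(out$uptake, 0)
  expect_equal(range(out$state$profile), c(0.002, 0.002), tolerance = 1e-12)

  # huge buffer power, short time: undepleted Michaelis-Menten limit
  p2 <- bc_params(i_max = 0.5, k_m = 0.02, c_min = 0, de = 0.1, b = 1e6,
                  r0 = 0.03, rx = 0.5)
  out2 <- uptake_p_barber_cushman(1, p2, c_initial = 0.002, dt = 0.05,
                                  nsub = 4)
  want <- 2 * pi * 0.03 * 0.5 * 0.002 / (0.02 + 0.002) * 0.05
  expect_equal(out2$uptake, want, tolerance = 0.01)

  # concentrations stay within [c_min-bounded floor, c_initial] and uptake
  # is monotone in i_max and c_initial
  run_tot <- function(imax, c0) {
    pp <- bc_params(i_max = imax, k_m = 0.02, c_min = 1e-5, de = 0.05,
                    b = 100, r0 = 0.03, rx = 0.5)
    st <- NULL
    tot <- 0
    for (i in 1:20) {
      o <- uptake_p_barber_cushman(1, pp, c0, dt = 0.25, state = st)
      st <- o$state
      tot <- tot + o$uptake
    }
    expect_true(all(st$profile >= 1e-5 - 1e-12))
    expect_true(all(st$profile <= c0 + 1e-12))
    tot
  }
  u <- vapply(c(0.2, 0.5, 1), run_tot, 0, c0 = 0.002)
  expect_true(all(diff(u) > 0))
  u2 <- vapply(c(0.001, 0.002, 0.004), function(c0) run_tot(0.5, c0), 0)
  expect_true(all(diff(u2) > 0))
})

test_that("the implicit solver agrees with a fine-grid explicit oracle", {
  p <- bc_params(i_max = 0.5, k_m = 0.02, c_min = 1e-5, de = 0.08, b = 100,
                 r0 = 0.03, rx = 0.3, water_flux_at_root = 0.02)
  total_t <- 0.25
  st <- NULL
  tot <- 0
  for (i in 1:1) {
    o <- uptake_p_barber_cushman(1, p, 0.002, dt = 0.25, state = st,
                                 n_nodes = 14, nsub = 8)
    st <- o$state
    tot <- tot + o$uptake
  }
  want <- bc_explicit_oracle(p, 0.002, total_t)$uptake
  expect_lt(abs(tot - want) / want, 0.02)
})
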