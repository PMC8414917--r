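# The coupled simulation loop, class accounting, sweeps and the
# seminal-root optimization machinery.

test_that("runs are bit-identical under one seed and differ across seeds", {
  ph <- tiny_phenotype(srn = 2L, laterals = TRUE)
  env <- tiny_environment(n_layers = 40, rain = rep(3, 30))
  a <- run_simulation(ph, env, seed = 7, days = 8, control = fast_control())
  b <- run_simulation(ph, env, seed = 7, days = 8, control = fast_control())
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(segment_table(a$root_system),
                   segment_table(b$root_system))
  expect_identical(a$uptake_n, b$uptake_n)

  c <- run_simulation(ph, env, seed = 8, days = 8, control = fast_control())
  expect_false(identical(segment_table(a$root_system),
                         segment_table(c$root_system)))
  expect_false(identical(a$shoot_dry_weight, c$shoot_dry_weight))
})

test_that("a zero-resource seed in a zero-nutrient soil produces no growth", {
  ph <- tiny_phenotype(seed_mass = 1e-3)
  ph$seed_nitrogen <- 0
  ph$seed_phosphorus <- 0
  env <- tiny_environment(n_layers = 20, nitrate = 0, organic = 0, p = 0)
  res <- run_simulation(ph, env, seed = 1, days = 6,
                        control = fast_control())
  expect_lt(res$shoot_dry_weight, 1e-4)
  expect_lt(res$total_root_length, 0.5)
  expect_true(res$budget$germination_failed)
})

test_that("class contributions sum to one, separate laterals and are
          order-invariant", {
  ph <- tiny_phenotype(srn = 3L, laterals = TRUE)
  env <- tiny_environment(n_layers = 40, nitrate = 5, p = 0.002)
  res <- run_simulation(ph, env, seed = 3, days = 10,
                        control = fast_control())
  cc <- class_contribution(res)
  last <- ncol(cc$n)
  expect_equal(sum(cc$n[, last]), 1, tolerance = 1e-9)
  expect_equal(sum(cc$p[, last]), 1, tolerance = 1e-9)
  expect_true(all(rownames(cc$n) == c("primary", "seminal", "nodal",
                                      "lateral_primary", "lateral_seminal",
                                      "lateral_nodal")))
  # cumulative class shares derive from non-decreasing cumulative uptake
  cum_n <- apply(apply(res$uptake_n, c(1, 3), sum), 1, cumsum)
  expect_true(all(diff(rowSums(cum_n)) >= -1e-12))

  # by-depth accounting conserves the array totals
  bd <- by_depth_contribution(res, day = 10, "n")
  expect_equal(sum(bd), sum(res$uptake_n), tolerance = 1e-9)
  bd5 <- by_depth_contribution(res, day = 5, "n")
  expect_lte(sum(bd5), sum(bd) + 1e-12)

  # single-class system: the primary stratum carries share 1 early on
  ph1 <- tiny_phenotype(srn = 0L, laterals = FALSE)
  res1 <- run_simulation(ph1, env, seed = 3, days = 5,
                         control = fast_control())
  cc1 <- class_contribution(res1)
  expect_equal(unname(cc1$n["primary", 5]), 1, tolerance = 1e-9)
})

test_that("nitrogen and phosphorus mass balances close on coupled runs", {
  ph <- tiny_phenotype(srn = 2L, laterals = TRUE)
  env <- tiny_environment(n_layers = 40, nitrate = 3, p = 0.002,
                          rain = rep(8, 30))
  for (sd in c(2, 9)) {
    res <- run_simulation(ph, env, seed = sd, days = 10,
                          control = fast_control())
    b <- res$balance
    expect_equal(b$n_initial + b$n_mineralized,
                 b$n_remaining + b$n_leached + b$n_uptake,
                 tolerance = 1e-5 * b$n_initial)
    expect_equal(b$p_initial, b$p_remaining + b$p_uptake,
                 tolerance = 1e-5 * b$p_initial)
  }
})

test_that("leaching rises with rainfall and plant N rises with the nitrate
          multiplier", {
  ph <- tiny_phenotype(srn = 1L, laterals = TRUE)
  env <- tiny_environment(n_layers = 30, nitrate = 2, rain = rep(6, 30))
  leach <- vapply(c(0.5, 1, 2), function(m) {
    run_simulation(ph, scale_rainfall(env, m), seed = 5, days = 8,
                   control = fast_control())$balance$n_leached
  }, 0)
  expect_true(all(diff(leach) > 0))

  upt <- vapply(c(0.3, 1, 3), function(m) {
    e <- scale_environment_nutrients(tiny_environment(n_layers = 30,
                                                      nitrate = 0.4), m, 1)
    r <- run_simulation(ph, e, seed = 5, days = 8, control = fast_control())
    r$balance$n_uptake
  }, 0)
  expect_true(all(diff(upt) >= 0))
})

test_that("select_optimum applies rounding and the lowest-SRN tie-break,
          matching brute force on random tables", {
  expect_equal(select_optimum(c(`0` = 1.0000000, `4` = 1.0000004)), 0)
  expect_equal(select_optimum(c(`0` = 0.9, `3` = 1.1, `8` = 1.0)), 3)
  expect_equal(select_optimum(c(`0` = 0.77)), 0)
  expect_error(select_optimum(numeric(0)), "empty")

  set.seed(17)
  for (i in 1:1000) {
    n <- sample(2:9, 1)
    srn <- sort(sample(0:8, n))
    vals <- round(runif(n, 0, 2), sample(4:8, 1))
    if (runif(1) < 0.5) vals[sample(n, 2)] <- vals[1]  # force ties
    tab <- setNames(vals, srn)
    expect_identical(select_optimum(tab), select_optimum_oracle(tab))
  }
})

test_that("optimize_srn recovers a planted concave optimum for every seed
          mass", {
  k_star <- 3L
  stub <- function(phenotype, environment, seed, days, control) {
    list(shoot_dry_weight =
           1 - 0.01 * (phenotype$seminal_root_number - k_star)^2 +
           phenotype$seed_mass * 1e-6)
  }
  ph <- tiny_phenotype()
  env <- tiny_environment()
  out <- optimize_srn(ph, env, srn_range = 0:8,
                      seed_masses = seq(10, 150, by = 2.5), reps = 2,
                      sim_fn = stub)
  expect_equal(nrow(out$grid), 9 * 57)
  expect_equal(nrow(out$optimum), 57)
  expect_true(all(out$optimum$optimal_srn == k_star))
  expect_equal(out$optimum$carbohydrate_reserve,
               out$optimum$seed_mass * 0.7112)

  # a response flat in SRN collapses to zero by the tie-break
  flat <- function(phenotype, environment, seed, days, control)
    list(shoot_dry_weight = 1)
  out2 <- optimize_srn(ph, env, srn_range = 0:4, seed_masses = c(50, 100),
                       reps = 1, sim_fn = flat)
  expect_true(all(out2$optimum$optimal_srn == 0))
  expect_true(is.na(reserve_threshold(out2$optimum)))
})

test_that("sweep runners produce the full factorial with seeded replicates
          and stable cell means", {
  ph <- tiny_phenotype(srn = 1L, laterals = TRUE)
  env <- tiny_environment(n_layers = 30, nitrate = 1, rain = rep(4, 30))
  sw <- run_env_grid(ph, env, n_multipliers = c(0.5, 2),
                     rain_multipliers = 1, textures = "silt_loam",
                     reps = 3, base_seed = 5, days = 8,
                     control = fast_control())
  expect_equal(nrow(sw$cells), 2 * 3)
  expect_equal(nrow(sw$means), 2)
  expect_false(any(duplicated(sw$cells$rng_seed)))
  m <- sw$means[order(sw$means$n_multiplier), ]
  expect_lte(m$net_n_uptake[1], m$net_n_uptake[2] + 1e-9)

  # replicate stochasticity is real but cell means are stable between two
  # independent batches (a nitrate-poor soil so stress feeds the geometry
  # noise back into shoot growth)
  envs <- tiny_environment(n_layers = 30, nitrate = 0.15, rain = rep(4, 30))
  s1 <- run_srn_sweep(ph, envs, srn_levels = 1, reps = 6, base_seed = 100,
                      days = 10, control = fast_control())
  s2 <- run_srn_sweep(ph, envs, srn_levels = 1, reps = 6, base_seed = 5000,
                      days = 10, control = fast_control())
  expect_gt(stats::sd(s1$cells$shoot_dry_weight), 0)
  expect_lt(abs(s1$means$shoot_dry_weight - s2$means$shoot_dry_weight) /
              s1$means$shoot_dry_weight, 0.05)
})

test_that("the density sweep reduces to replication at one density and the
          seminal-root CDF dominates the no-seminal CDF", {
  land <- make_phenotype_fixture("landrace")$phenotype
  env <- study_environments()$low_n
  sw <- run_density_sweep(land, env, densities = 74100, reps = 2,
                          base_seed = 3, days = 12,
                          control = fast_control(), cdf_samples = 150)
  expect_equal(nrow(sw$cells), 2)
  expect_equal(sw$cells$in_row_spacing,
               rep(density_to_spacing(74100), 2), tolerance = 1e-9)
  # with seminal roots the neighbouring plant's nearest root is closer:
  # the with-seminal CDF lies on or above the without-seminal CDF
  q <- seq(0.1, 0.9, by = 0.1)
  dw <- stats::quantile(sw$cdf_with$distances, q)
  dn <- stats::quantile(sw$cdf_without$distances, q)
  expect_lte(mean(dw), mean(dn))
  expect_gte(mean(sw$cdf_with$cdf(seq(1, 15))),
             mean(sw$cdf_without$cdf(seq(1, 15))))
})

test_that("teosinte germinates without seminal roots but fails with two or
          more", {
  teo <- make_phenotype_fixture("teosinte")$phenotype
  env <- study_environments()$low_n
  r0 <- run_simulation(teo, env, seed = 2, days = 25,
                       control = sim_control(), keep_geometry = FALSE)
  expect_false(r0$budget$germination_failed)
  expect_gt(r0$shoot_dry_weight, 0.02)
  teo2 <- rhizoseed:::override_phenotype(teo, seminal_root_number = 2L)
  r2 <- run_simulation(teo2, env, seed = 2, days = 25,
                       control = sim_control(), keep_geometry = FALSE)
  expect_true(r2$budget$germination_failed)
  expect_lt(r2$shoot_dry_weight, 0.02)
})

test_that("the landrace outgrows and outroots teosinte without nutrient
          stress", {
  land <- make_phenotype_fixture("landrace")$phenotype
  teo <- make_phenotype_fixture("teosinte")$phenotype
  env <- unstressed_environment()
  rl <- run_simulation(land, env, seed = 11, days = 25)
  rt <- run_simulation(teo, env, seed = 11, days = 25)
  expect_gt(rl$total_root_length, rt$total_root_length)
  expect_gt(rl$max_rooting_depth, rt$max_rooting_depth)
  expect_gt(rl$shoot_dry_weight, rt$shoot_dry_weight)
})
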